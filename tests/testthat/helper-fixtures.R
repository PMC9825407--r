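# Shared small-cohort fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- cohort_spec(n_patients = 8, n_batches = 3, cells_per_sample = 400,
                        reference_cells = 3001, seed = 11)
    .fixture_env$small <- generate_cohort(spec)
  }
  .fixture_env$small
}

# transformed + normalized version of the small cohort
small_normalized <- function() {
  if (is.null(.fixture_env$small_norm)) {
    co <- small_cohort()
    tr <- lapply(co$cell_tables, arcsinh_transform)
    refs <- tr[co$manifest$sample_id[co$manifest$sample_role == "batch_reference"]]
    names(refs) <- vapply(refs, function(r) r$metadata$batch_id, character(1))
    maps <- fit_quantile_maps(refs, "B3")
    .fixture_env$small_norm <- list(
      cohort = co,
      normalized = lapply(tr, apply_quantile_maps, maps = maps),
      maps = maps, refs = refs)
  }
  .fixture_env$small_norm
}

# three well-separated Gaussian clouds in 4 dimensions
gaussian_clouds <- function(n_per = 200, sep = 10, sd = 1, seed = 5) {
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0, 0, 0), c(sep, 0, 0, 0), c(0, sep, 0, 0))
    data <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n_per * 4, sd = sd), n_per, 4) +
        matrix(centers[k, ], n_per, 4, byrow = TRUE)
    }))
    colnames(data) <- paste0("ch", 1:4)
    list(data = data, labels = rep(1:3, each = n_per), centers = centers)
  })
}
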