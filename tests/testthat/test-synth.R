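test_that("cohort layout matches the sampling design", {
  co <- small_cohort()
  # 8 patients x 3 timepoints + 3 references + 3 healthy donors
  expect_equal(nrow(co$manifest), 8 * 3 + 3 + 3)
  expect_equal(sum(co$manifest$sample_role == "patient"), 24)
  expect_equal(sum(co$manifest$sample_role == "batch_reference"), 3)
  expect_equal(sum(co$manifest$sample_role == "healthy_donor"), 3)
  expect_setequal(co$manifest$sample_id, names(co$cell_tables))
  expect_equal(nrow(co$clinical), 8)
  expect_true(all(co$clinical$os_days >= 0))
  expect_true(all(co$clinical$os_event %in% 0:1))
  # every cell labeled, all raw intensities non-negative
  for (sid in head(names(co$cell_tables), 5)) {
    tab <- co$cell_tables[[sid]]
    expect_true(min(tab$data) >= 0)
    expect_equal(length(co$truth$labels[[sid]]), nrow(tab$data))
  }
})

test_that("generation is deterministic given spec and seed", {
  spec <- cohort_spec(n_patients = 3, n_batches = 2, cells_per_sample = 150,
                      reference_cells = 500, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  # and a different seed changes the data
  c <- generate_cohort(cohort_spec(n_patients = 3, n_batches = 2,
                                   cells_per_sample = 150,
                                   reference_cells = 500, seed = 100))
  expect_false(identical(a$cell_tables[[1]]$data, c$cell_tables[[1]]$data))
})

test_that("healthy donors resemble a normal differential blood count", {
  spec <- cohort_spec(n_patients = 2, n_batches = 6, cells_per_sample = 2000,
                      reference_cells = 500, seed = 21)
  co <- generate_cohort(spec)
  hd <- co$manifest$sample_id[co$manifest$sample_role == "healthy_donor"]
  comp <- sapply(hd, function(s) {
    tabulate(co$truth$labels[[s]], nbins = 10) / length(co$truth$labels[[s]])
  })
  mean_comp <- rowMeans(comp)
  names(mean_comp) <- co$truth$population_names
  expect_lt(abs(mean_comp[["granulocytes"]] - 0.60), 0.05)
  lymph <- sum(mean_comp[c("b_cells", "t_cd4", "t_cd8", "nk")])
  expect_lt(abs(lymph - 0.30), 0.05)
  expect_lt(abs(mean_comp[["monocytes"]] - 0.03), 0.05)
})

test_that("invalid cohort specs fail naming the offending field", {
  expect_error(cohort_spec(timepoints = c(0, 4)), "timepoints")
  expect_error(cohort_spec(cells_per_sample = 50), "cells_per_sample")
  expect_error(cohort_spec(dirichlet_alpha = rep(-1, 10)), "dirichlet_alpha")
  pops <- default_populations()
  pops$myeloid_mc$is_target <- FALSE
  expect_error(cohort_spec(populations = pops), "populations")
  expect_error(
    cohort_spec(survival_model = list(baseline_hazard = 0, beta = 1,
                                      censor_horizon_days = 100)),
    "survival_model")
})

test_that("batch distortion is affine on the transformed scale", {
  co <- small_cohort()
  tab <- co$cell_tables[[1]]
  # identity
  same <- apply_batch_effect(tab, slope = 1, offset = 0)
  expect_equal(same$data, tab$data, tolerance = 1e-12)
  # pure offset: every transformed value rises by exactly 0.3
  shifted <- apply_batch_effect(tab, slope = 1, offset = 0.3)
  expect_equal(asinh(shifted$data / 5), asinh(tab$data / 5) + 0.3,
               tolerance = 1e-9)
  expect_error(apply_batch_effect(tab, slope = -1, offset = 0), "slope")
  # quantile equivariance: the distorted 101 empirical quantiles equal
  # a*q + b of the undistorted ones (monotone map, no flooring for b > 0)
  probs <- seq(0, 1, length.out = 101)
  dist2 <- apply_batch_effect(tab, slope = 1.1, offset = 0.25)
  for (ch in c("CD45", "pERK")) {
    q0 <- quantile(asinh(tab$data[, ch] / 5), probs, type = 7)
    q1 <- quantile(asinh(dist2$data[, ch] / 5), probs, type = 7)
    expect_equal(unname(q1), unname(1.1 * q0 + 0.25), tolerance = 1e-9)
  }
  # rank preservation
  ord0 <- order(tab$data[, "CD34"])
  ord1 <- order(dist2$data[, "CD34"])
  expect_equal(ord0, ord1)
})

test_that("per-patient composition matches realized cell-count ratios", {
  co <- small_cohort()
  sid <- co$manifest$sample_id[co$manifest$sample_role == "patient"][1]
  counts <- tabulate(co$truth$labels[[sid]], nbins = 10)
  expect_equal(sum(counts / sum(counts)), 1, tolerance = 1e-12)
})

test_that("survival simulation honors its hazard model", {
  model <- list(baseline_hazard = log(2) / 1500, beta = 0,
                censor_horizon_days = 1e6)
  z <- withr::with_seed(1, rnorm(1000))
  names(z) <- paste0("P", 1:1000)
  surv <- simulate_survival(z, model, seed = 2)
  # beta = 0: no association between latent and event time
  expect_lt(abs(cor(z, surv$event_time)), 0.07)

  # censor horizon 0: all censored at 0, with a degenerate-cohort warning
  model0 <- list(baseline_hazard = 0.001, beta = 1, censor_horizon_days = 0)
  expect_warning(s0 <- simulate_survival(z[1:10], model0, seed = 1),
                 "degenerate")
  expect_true(all(s0$os_days == 0))
  expect_true(all(s0$os_event == 0))

  expect_error(simulate_survival(z, list(baseline_hazard = -1, beta = 1,
                                         censor_horizon_days = 100), 1),
               "baseline_hazard")

  # stronger beta shortens event times of the high-latent group
  m1 <- list(baseline_hazard = log(2) / 1500, beta = 1, censor_horizon_days = 1e6)
  m2 <- list(baseline_hazard = log(2) / 1500, beta = 2, censor_horizon_days = 1e6)
  s1 <- simulate_survival(z, m1, seed = 7)
  s2 <- simulate_survival(z, m2, seed = 7)
  top <- z >= quantile(z, 0.75)
  expect_lt(mean(s2$event_time[top]), mean(s1$event_time[top]))
})

test_that("a univariate Cox fit on the true latent recovers beta", {
  model <- list(baseline_hazard = log(2) / 1500, beta = 1.0,
                censor_horizon_days = 1826)
  z <- withr::with_seed(3, rnorm(1000))
  names(z) <- paste0("P", 1:1000)
  surv <- simulate_survival(z, model, seed = 4)
  fit <- survival::coxph(survival::Surv(surv$os_days, surv$os_event) ~ z,
                         ties = "breslow")
  expect_lt(abs(unname(coef(fit)) - 1.0), 0.15)
})

test_that("two-timepoint patients lack only their 4 h samples", {
  spec <- cohort_spec(n_patients = 4, n_batches = 2, cells_per_sample = 120,
                      reference_cells = 300, drop_4h_patients = 2, seed = 13)
  co <- generate_cohort(spec)
  pat <- co$manifest[co$manifest$sample_role == "patient", ]
  for (p in c("P01", "P02")) {
    expect_setequal(pat$timepoint_h[pat$patient_id == p], c(0, 24))
  }
  for (p in c("P03", "P04")) {
    expect_setequal(pat$timepoint_h[pat$patient_id == p], c(0, 4, 24))
  }
  v <- validate_inputs(co$manifest, co$panel, co$clinical)
  expect_length(v$errors, 0)
  expect_length(v$warnings, 2)
})

test_that("written cohorts round-trip through the plain-text formats", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 2, n_batches = 2, cells_per_sample = 120,
                      reference_cells = 300, seed = 17)
  co <- generate_cohort(spec)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$manifest), nrow(co$manifest))
  sid <- co$manifest$sample_id[1]
  expect_equal(back$cell_tables[[sid]]$data, co$cell_tables[[sid]]$data,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$clinical$os_days, co$clinical$os_days, tolerance = 1e-9)
})
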