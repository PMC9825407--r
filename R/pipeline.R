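# End-to-end orchestration: simulate (or load) -> transform -> standardize
# -> cluster -> features -> survival, with a machine-readable report.

#' Validate manifest / panel / clinical consistency
#'
#' Cross-checks sample roles, channel coverage, timepoint completeness
#' (0 h and 24 h are mandatory; a missing 4 h sample is only a warning) and
#' patient overlap between manifest and clinical table.
#'
#' @param manifest manifest data frame (`sample_id`, `patient_id`,
#'   `timepoint_h`, `batch_id`, `sample_role`).
#' @param panel a [panel_config()].
#' @param clinical clinical data frame (`patient_id`, `os_days`,
#'   `os_event`, ...).
#' @return list with `errors` and `warnings` (character vectors); invisibly
#'   stops nothing -- callers decide.
#' @export
validate_inputs <- function(manifest, panel, clinical) {
  errors <- character(0)
  warns <- character(0)
  need <- c("sample_id", "patient_id", "timepoint_h", "batch_id", "sample_role")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0) {
    errors <- c(errors, sprintf("manifest lacks column(s): %s",
                                paste(miss, collapse = ", ")))
    return(list(errors = errors, warnings = warns))
  }
  bad_role <- !manifest$sample_role %in% c("patient", "healthy_donor", "batch_reference")
  if (any(bad_role)) {
    errors <- c(errors, sprintf("manifest row(s) %s: unknown sample_role",
                                paste(which(bad_role), collapse = ", ")))
  }
  batches <- unique(manifest$batch_id)
  for (b in batches) {
    if (!any(manifest$batch_id == b & manifest$sample_role == "batch_reference")) {
      errors <- c(errors, sprintf("batch %s has no reference aliquot", b))
    }
  }
  pts <- unique(manifest$patient_id[manifest$sample_role == "patient"])
  for (p in pts) {
    tps <- manifest$timepoint_h[manifest$patient_id == p &
                                  manifest$sample_role == "patient"]
    for (tp in c(0, 24)) {
      if (!tp %in% tps) {
        errors <- c(errors, sprintf("patient %s lacks the mandatory %d h sample", p, tp))
      }
    }
    if (!4 %in% tps) {
      warns <- c(warns, sprintf("patient %s has no 4 h sample (two-timepoint patient)", p))
    }
  }
  extra <- setdiff(clinical$patient_id, pts)
  if (length(extra) > 0) {
    errors <- c(errors, sprintf("patient(s) in clinical but not in manifest: %s",
                                paste(extra, collapse = ", ")))
  }
  no_clin <- setdiff(pts, clinical$patient_id)
  if (length(no_clin) > 0) {
    errors <- c(errors, sprintf("patient(s) in manifest but not in clinical: %s",
                                paste(no_clin, collapse = ", ")))
  }
  list(errors = errors, warnings = warns)
}

#' Run the full early-response analysis pipeline
#'
#' Stages: (synthetic) cohort generation, arcsinh transform, anchored
#' quantile standardization towards a target batch, SOM training on pooled
#' baseline + healthy cells, consensus metaclustering, nearest-node
#' assignment of every sample, percentile feature engineering,
#' administrative censoring, nested leave-one-out LASSO-Cox selection, and
#' median-split Kaplan-Meier / log-rank analysis of the top feature.
#'
#' @param spec a [cohort_spec()] (synthetic input), or a cohort list as
#'   returned by [generate_cohort()].
#' @param target_batch batch to standardize towards (default: last batch).
#' @param k metaclusters (default 10).
#' @param grid SOM grid (default 5x5).
#' @param q percentile for signaling features (default 0.90).
#' @param horizon `"2y"`, `"5y"` or days for administrative censoring.
#' @param transforms feature transforms (see [build_feature_matrix()]).
#' @param epochs SOM training epochs.
#' @param min_cells minimum cells per percentile feature.
#' @param seed master seed for the analysis stages (SOM init/order,
#'   consensus resampling); the cohort's own seed governs data generation.
#' @param split_feature optionally force the median-split feature (column
#'   name); default: the final model's most significant selected feature,
#'   falling back to the highest selection frequency.
#' @return object of class `cytoresponse_run`: all intermediates plus a
#'   `report` list (selected features, split feature, group labels,
#'   log-rank summary, seeds).
#' @export
run_pipeline <- function(spec, target_batch = NULL, k = 10, grid = c(5, 5),
                         q = 0.90, horizon = "5y", transforms = "ratio24h",
                         epochs = 10, min_cells = 10, seed = 1,
                         split_feature = NULL) {
  cohort <- if (inherits(spec, "cohort_spec")) generate_cohort(spec) else spec
  panel <- cohort$panel
  val <- validate_inputs(cohort$manifest, panel, cohort$clinical)
  if (length(val$errors) > 0) {
    stop(paste(c("invalid inputs:", val$errors), collapse = "\n  "), call. = FALSE)
  }

  # transform + standardize
  transformed <- lapply(cohort$cell_tables, arcsinh_transform,
                        cofactor = panel$cofactor)
  refs <- transformed[cohort$manifest$sample_id[
    cohort$manifest$sample_role == "batch_reference"]]
  names(refs) <- vapply(refs, function(r) r$metadata$batch_id, character(1))
  if (is.null(target_batch)) target_batch <- names(refs)[length(refs)]
  norm_channels <- c(panel_channels(panel, "clustering"),
                     panel_channels(panel, "functional"))
  maps <- fit_quantile_maps(refs, target_batch, channels = norm_channels)
  normalized <- lapply(transformed, apply_quantile_maps, maps = maps)

  # cluster on pooled baseline + healthy cells
  train_ids <- cohort$manifest$sample_id[
    (cohort$manifest$sample_role == "patient" & cohort$manifest$timepoint_h == 0) |
      cohort$manifest$sample_role == "healthy_donor"]
  clust_ch <- panel_channels(panel, "clustering")
  pooled <- do.call(rbind, lapply(normalized[train_ids],
                                  function(t) t$data[, clust_ch, drop = FALSE]))
  model <- train_som(pooled, som_config(grid = grid, epochs = epochs,
                                        seed = stream_seed(seed, 11)))
  model <- metacluster(model, k = k, seed = stream_seed(seed, 12))

  patient_ids_all <- cohort$manifest$sample_id[cohort$manifest$sample_role == "patient"]
  assignments <- lapply(normalized[patient_ids_all], function(t) {
    assign_cells(model, t$data[, clust_ch, drop = FALSE])
  })

  # features
  sf <- extract_sample_features(normalized[patient_ids_all], assignments,
                                panel, k = k, q = q, min_cells = min_cells)
  X <- build_feature_matrix(sf, cohort$clinical, transforms = transforms)

  # survival
  cl <- cohort$clinical[match(rownames(X), cohort$clinical$patient_id), ]
  cens <- censor_at_horizon(cl$os_days, cl$os_event, horizon)
  sel <- nested_loocv_select(X, cens$time, cens$event)

  if (is.null(split_feature)) {
    split_feature <- if (nrow(sel$selected) > 0) {
      sel$selected$feature[1]
    } else {
      names(which.max(sel$selection_frequency))
    }
  }
  groups <- median_split(setNames(X[, split_feature], rownames(X)))
  lr <- logrank_test(cens$time, cens$event, groups)
  km <- km_estimate(cens$time, cens$event, groups)

  report <- list(
    n_patients = nrow(X), n_features = ncol(X),
    target_batch = target_batch, horizon = horizon,
    selected = sel$selected, split_feature = split_feature,
    group_sizes = as.vector(table(groups)),
    logrank = list(chisq = lr$chisq, p = lr$p, hr = lr$hr, hr_ci = lr$hr_ci),
    seeds = list(master = seed, cohort = if (!is.null(cohort$spec)) cohort$spec$seed else NA))
  structure(list(cohort = cohort, maps = maps, model = model,
                 assignments = assignments, features = X,
                 selection = sel, groups = groups, logrank = lr, km = km,
                 report = report),
            class = "cytoresponse_run")
}

#' @export
print.cytoresponse_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<cytoresponse_run> %d patients, %d features, horizon %s\n",
              r$n_patients, r$n_features, r$horizon))
  cat(sprintf("  split feature: %s (groups %s)\n", r$split_feature,
              paste(r$group_sizes, collapse = "/")))
  cat(sprintf("  log-rank p = %.4g, HR low/high = %.4g (95%% CI %.4g-%.4g)\n",
              r$logrank$p, r$logrank$hr, r$logrank$hr_ci[1], r$logrank$hr_ci[2]))
  if (nrow(r$selected) > 0) {
    cat("  selected features:\n")
    print(head(r$selected, 5), digits = 3)
  }
  invisible(x)
}

#' Write the machine-readable run report as JSON
#' @param run a [run_pipeline()] result.
#' @param path output file.
#' @export
write_report <- function(run, path) {
  stopifnot(inherits(run, "cytoresponse_run"))
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.tsv`, `clinical.tsv` and the
#'   per-sample CSV cell tables.
#' @param panel a [panel_config()].
#' @return a cohort list usable by [run_pipeline()] (without ground truth).
#' @export
read_cohort <- function(dir, panel = default_panel()) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  clinical <- utils::read.delim(file.path(dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    dat <- as.matrix(read.csv(m$path, check.names = FALSE))
    cell_table(dat, m$sample_id, scale = "raw", patient_id = m$patient_id,
               timepoint_h = m$timepoint_h, batch_id = m$batch_id,
               sample_role = m$sample_role)
  })
  names(tables) <- manifest$sample_id
  list(cell_tables = tables, manifest = manifest, clinical = clinical,
       truth = NULL, panel = panel, spec = NULL)
}

#' Metacluster holding the generator's target population
#'
#' For synthetic runs with ground truth: the metacluster label that the
#' majority of true target-population cells (24 h patient samples) were
#' assigned to, with its purity.
#'
#' @param run a [run_pipeline()] result on a synthetic cohort.
#' @return list with `metacluster` and `purity`.
#' @export
target_metacluster <- function(run) {
  stopifnot(inherits(run, "cytoresponse_run"))
  co <- run$cohort
  if (is.null(co$truth)) stop("run has no ground truth", call. = FALSE)
  ids <- co$manifest$sample_id[co$manifest$sample_role == "patient" &
                                 co$manifest$timepoint_h == 24]
  tpop <- which(co$truth$population_names == co$truth$target_population)
  mcs <- unlist(lapply(ids, function(s) {
    run$assignments[[s]]$metacluster[co$truth$labels[[s]] == tpop]
  }))
  tab <- table(mcs)
  list(metacluster = as.integer(names(which.max(tab))),
       purity = max(tab) / length(mcs))
}
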