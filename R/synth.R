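# Synthetic mass cytometry cohort generator with known ground truth.
#
# Cells are drawn per population as Gaussians on the arcsinh-transformed
# scale (per-channel zero-inflation applied first, values floored at 0,
# matching non-negative raw dual counts), then back-transformed with sinh.
# Batch effects are affine maps a*v + b (a > 0, b >= 0 by default) on the
# transformed scale: monotone, zero-preserving and exactly correctable by
# anchored quantile normalization. Every acquisition batch carries an
# identical aliquot of one pooled reference sample.

#' Population template for the synthetic cohort
#'
#' @param name population label.
#' @param surface_means named numeric vector of surface-marker means on the
#'   transformed scale (missing channels default to `baseline`).
#' @param functional_means named numeric vector of functional-marker means.
#' @param zero_inflation per-channel probability of a structural zero raw
#'   count (scalar or named vector), in \[0, 1\].
#' @param dispersion per-channel s.d. on the transformed scale (> 0).
#' @param is_target marks the myeloid-like population whose 24 h functional
#'   response drives survival; exactly one population may carry it.
#' @param baseline mean used for channels not listed explicitly.
#' @return object of class `population_template`.
#' @export
population_template <- function(name, surface_means, functional_means,
                                zero_inflation = 0.03, dispersion = 0.35,
                                is_target = FALSE, baseline = 0.3) {
  validate_that(all(zero_inflation >= 0 & zero_inflation <= 1),
                "zero_inflation", "must be in [0, 1]")
  validate_that(all(dispersion > 0), "dispersion", "must be positive")
  structure(list(name = name, surface_means = surface_means,
                 functional_means = functional_means,
                 zero_inflation = zero_inflation, dispersion = dispersion,
                 is_target = isTRUE(is_target), baseline = baseline),
            class = "population_template")
}

#' Default population templates
#'
#' Ten populations emulating the major immunophenotypic subsets seen in AML
#' peripheral blood: two CD34+ blast populations, granulocytes, monocytes,
#' B cells, CD4/CD8 T cells, NK cells, a heterogeneous CD45-dim myeloid
#' population (the target population whose 24 h signaling response carries
#' the survival signal), and hematopoietic stem cells.
#'
#' @return named list of [population_template()]s.
#' @export
default_populations <- function() {
  f_base <- 1.2
  pops <- list(
    blast_cd34 = population_template(
      "blast_cd34",
      c(CD34 = 4.0, CD117 = 3.5, CD38 = 2.5, CD123 = 1.5, HLADR = 1.5,
        CD33 = 1.5, CD45 = 1.5),
      c(pERK = f_base, pp38 = f_base)),
    blast_hladr = population_template(
      "blast_hladr",
      c(CD34 = 4.0, CD117 = 3.0, HLADR = 3.5, CD33 = 3.0, CD123 = 3.0,
        CD38 = 2.5, CD45 = 1.5),
      c(pERK = f_base, pp38 = f_base)),
    granulocytes = population_template(
      "granulocytes",
      c(CD66b = 4.0, CD16 = 3.5, CD45 = 3.2, CD33 = 2.0, CD11b = 3.5),
      c(pS6 = 1.6)),
    monocytes = population_template(
      "monocytes",
      c(CD14 = 4.5, CD33 = 3.5, CD64 = 3.5, HLADR = 3.0, CD45 = 4.2,
        CD11b = 3.0),
      c(pNFkB = 1.6)),
    b_cells = population_template(
      "b_cells",
      c(CD20 = 4.0, HLADR = 3.5, CD45 = 4.5),
      c(pSTAT5 = 1.4)),
    t_cd4 = population_template(
      "t_cd4",
      c(CD3 = 4.2, CD4 = 3.8, CD45 = 4.5, CD7 = 3.0, CD25 = 1.0),
      numeric(0)),
    t_cd8 = population_template(
      "t_cd8",
      c(CD3 = 4.2, CD8a = 3.8, CD45 = 4.5, CD7 = 3.0),
      numeric(0)),
    nk = population_template(
      "nk",
      c(CD56 = 3.8, CD16 = 3.0, CD7 = 3.5, CD45 = 4.3),
      numeric(0)),
    myeloid_mc = population_template(
      "myeloid_mc",
      c(CD33 = 2.0, CD64 = 2.0, HLADR = 1.8, CD45 = 2.2, CD14 = 1.0),
      c(pERK = 2.0, pp38 = 1.8),
      is_target = TRUE),
    hsc = population_template(
      "hsc",
      c(CD34 = 4.0, CD90 = 3.0, CD38 = 0.8, CD117 = 2.0, CD45 = 1.5),
      numeric(0))
  )
  pops
}

#' Default per-population mean composition
#'
#' Healthy donors resemble a normal differential blood count (about 60%
#' granulocytes, 30% lymphocytes, 3% monocytes); patients carry expanded
#' blast and immature myeloid compartments.
#'
#' @param role `"patient"` or `"healthy"`.
#' @return named proportion vector summing to 1.
#' @export
default_composition <- function(role = c("patient", "healthy")) {
  role <- match.arg(role)
  if (role == "healthy") {
    c(blast_cd34 = 0.005, blast_hladr = 0.005, granulocytes = 0.60,
      monocytes = 0.03, b_cells = 0.05, t_cd4 = 0.12, t_cd8 = 0.08,
      nk = 0.05, myeloid_mc = 0.05, hsc = 0.005)
  } else {
    c(blast_cd34 = 0.15, blast_hladr = 0.05, granulocytes = 0.15,
      monocytes = 0.02, b_cells = 0.03, t_cd4 = 0.08, t_cd8 = 0.05,
      nk = 0.03, myeloid_mc = 0.40, hsc = 0.04)
  }
}

#' Cohort specification for the synthetic generator
#'
#' @param n_patients number of patients.
#' @param timepoints sampling timepoints in hours; must include 0 and 24.
#' @param n_batches number of acquisition batches (barcode pools); each
#'   carries one reference aliquot and one healthy donor.
#' @param populations list of [population_template()]s (exactly one target).
#' @param dirichlet_alpha positive Dirichlet parameters governing per-patient
#'   composition variability (default: patient mean composition times 40).
#' @param healthy_proportions fixed mean composition of healthy donors.
#' @param batch_effect either `list(slope_range=, offset_range=)` from which
#'   per-batch per-channel affine parameters are drawn, or explicit
#'   `list(slope=, offset=)` matrices (batches x channels). Slopes must be
#'   positive (monotone distortions).
#' @param response_model list: `responder_fraction`, `responder_shift`
#'   (negative 24 h shift of the target marker in responders),
#'   `nonresponder_shift` (non-negative), `shift_4h` (common early
#'   transient), `patient_sd` (patient-level noise), `target_marker`.
#' @param survival_model list: `baseline_hazard` (events/day),
#'   `beta` (log hazard ratio per s.d. of the latent 24 h value),
#'   `censor_horizon_days`.
#' @param cells_per_sample cells per patient/healthy sample (>= 100).
#' @param reference_cells cells in the pooled reference aliquot.
#' @param drop_4h_patients number of patients generated without a 4 h sample
#'   (emulating patients sampled at two timepoints only; default 0).
#' @param seed integer master seed; all randomness derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 32,
                        timepoints = c(0, 4, 24),
                        n_batches = 7,
                        populations = default_populations(),
                        dirichlet_alpha = NULL,
                        healthy_proportions = default_composition("healthy"),
                        batch_effect = list(slope_range = c(0.9, 1.15),
                                            offset_range = c(0.05, 0.5)),
                        response_model = list(responder_fraction = 0.5,
                                              responder_shift = -1.2,
                                              nonresponder_shift = 0.4,
                                              shift_4h = 0.2,
                                              patient_sd = 0.3,
                                              target_marker = "pERK"),
                        survival_model = list(baseline_hazard = log(2) / 1500,
                                              beta = 1.0,
                                              censor_horizon_days = 1826),
                        cells_per_sample = 1000,
                        reference_cells = 10000,
                        drop_4h_patients = 0,
                        seed = 1) {
  validate_that(n_patients >= 1, "n_patients", "need at least one patient")
  validate_that(all(c(0, 24) %in% timepoints), "timepoints",
                "must include 0 and 24 h")
  validate_that(cells_per_sample >= 100, "cells_per_sample",
                "need at least 100 cells per sample")
  validate_that(sum(vapply(populations, function(p) p$is_target, logical(1))) == 1,
                "populations", "exactly one population must have is_target = TRUE")
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- default_composition("patient") * 40
  }
  validate_that(all(dirichlet_alpha > 0), "dirichlet_alpha", "must be positive")
  validate_that(length(dirichlet_alpha) == length(populations),
                "dirichlet_alpha", "one parameter per population")
  if (!is.null(batch_effect$slope)) {
    validate_that(all(batch_effect$slope > 0), "batch_effect",
                  "slopes must be positive")
  } else {
    validate_that(all(batch_effect$slope_range > 0), "batch_effect",
                  "slope range must be positive")
  }
  validate_that(response_model$responder_shift <= 0, "response_model",
                "responder 24 h shift must be non-positive")
  validate_that(response_model$nonresponder_shift >= 0, "response_model",
                "non-responder 24 h shift must be non-negative")
  validate_that(survival_model$baseline_hazard > 0, "survival_model",
                "baseline hazard must be positive")
  structure(list(n_patients = n_patients, timepoints = sort(timepoints),
                 n_batches = n_batches, populations = populations,
                 dirichlet_alpha = dirichlet_alpha,
                 healthy_proportions = healthy_proportions,
                 batch_effect = batch_effect,
                 response_model = response_model,
                 survival_model = survival_model,
                 cells_per_sample = cells_per_sample,
                 reference_cells = reference_cells,
                 drop_4h_patients = drop_4h_patients,
                 seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients x %s h, %d batches, %d populations, %d cells/sample, seed %d\n",
              x$n_patients, paste(x$timepoints, collapse = "/"), x$n_batches,
              length(x$populations), x$cells_per_sample, x$seed))
  invisible(x)
}

# full mean/zi/dispersion vectors over the panel for one population
#' @noRd
population_channel_params <- function(pop, panel) {
  chs <- panel$channels$name
  mu <- setNames(rep(pop$baseline, length(chs)), chs)
  mu[names(pop$surface_means)] <- pop$surface_means
  mu[names(pop$functional_means)] <- pop$functional_means
  zi <- setNames(rep_len(pop$zero_inflation, length(chs)), chs)
  if (!is.null(names(pop$zero_inflation))) zi[names(pop$zero_inflation)] <- pop$zero_inflation
  disp <- setNames(rep_len(pop$dispersion, length(chs)), chs)
  if (!is.null(names(pop$dispersion))) disp[names(pop$dispersion)] <- pop$dispersion
  list(mu = mu, zi = zi, disp = disp)
}

# draw a cells x channels matrix on the transformed scale for one mixture
#' @noRd
draw_mixture <- function(n, proportions, populations, panel,
                         marker_shift = NULL) {
  counts <- as.vector(stats::rmultinom(1, n, proportions))
  chs <- panel$channels$name
  out <- matrix(0, n, length(chs), dimnames = list(NULL, chs))
  labels <- integer(n)
  at <- 0
  for (k in seq_along(populations)) {
    nk <- counts[k]
    if (nk == 0) next
    pp <- population_channel_params(populations[[k]], panel)
    mu <- pp$mu
    if (!is.null(marker_shift) && populations[[k]]$is_target) {
      mu[names(marker_shift)] <- mu[names(marker_shift)] + marker_shift
    }
    vals <- matrix(rnorm(nk * length(chs)), nk, length(chs))
    vals <- sweep(vals, 2, pp$disp, `*`)
    vals <- sweep(vals, 2, mu, `+`)
    zi_mask <- matrix(runif(nk * length(chs)), nk, length(chs)) <
      matrix(pp$zi, nk, length(chs), byrow = TRUE)
    vals[zi_mask] <- 0
    vals[vals < 0] <- 0
    idx <- (at + 1):(at + nk)
    out[idx, ] <- vals
    labels[idx] <- k
    at <- at + nk
  }
  list(values = out, labels = labels, counts = counts)
}

#' Apply an affine batch distortion to a raw-scale cell table
#'
#' On the transformed (arcsinh) scale every channel value v is mapped to
#' `a*v + b`, then back-transformed to the raw scale. Negative transformed
#' results (possible when b < 0) are floored at 0 so raw intensities stay
#' non-negative; with the default non-negative offsets no flooring occurs
#' and the distortion is exactly invertible. Within-channel cell ranking is
#' preserved (a > 0).
#'
#' @param table raw-scale [cell_table()].
#' @param slope,offset named numeric vectors per channel (or scalars).
#' @param cofactor arcsinh cofactor used for the round trip.
#' @return distorted raw-scale `cell_table`.
#' @export
apply_batch_effect <- function(table, slope, offset, cofactor = 5) {
  stopifnot(inherits(table, "cell_table"))
  validate_that(all(slope > 0), "slope", "must be positive (monotone distortion)")
  stopifnot(table$scale == "raw")
  chs <- colnames(table$data)
  slope <- if (length(slope) == 1) setNames(rep(slope, length(chs)), chs) else slope[chs]
  offset <- if (length(offset) == 1) setNames(rep(offset, length(chs)), chs) else offset[chs]
  v <- asinh(table$data / cofactor)
  v <- sweep(sweep(v, 2, slope, `*`), 2, offset, `+`)
  v[v < 0] <- 0
  table$data <- inverse_arcsinh(v, cofactor)
  table
}

#' Simulate survival outcomes from latent patient values
#'
#' Event times are exponential with rate `h0 * exp(beta * z)`, where z is
#' the latent value standardized across patients; observation is censored
#' administratively at the horizon.
#'
#' @param latent named numeric vector of per-patient latent values.
#' @param model list with `baseline_hazard`, `beta`, `censor_horizon_days`.
#' @param seed integer seed.
#' @return data frame with `patient_id`, `os_days`, `os_event`.
#' @export
simulate_survival <- function(latent, model, seed) {
  validate_that(all(is.finite(latent)), "latent", "values must be finite")
  validate_that(model$baseline_hazard > 0, "baseline_hazard", "must be positive")
  z <- if (sd(latent) > 0) (latent - mean(latent)) / sd(latent) else latent * 0
  horizon <- model$censor_horizon_days
  if (horizon <= 0) {
    warning("censoring horizon is 0: degenerate cohort, all records censored at 0")
  }
  withr::with_seed(seed, {
    rate <- model$baseline_hazard * exp(model$beta * z)
    event_time <- rexp(length(z), rate)
    data.frame(patient_id = names(latent) %||% paste0("P", seq_along(latent)),
               os_days = pmin(event_time, horizon),
               os_event = as.integer(event_time <= horizon),
               event_time = event_time,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' Emits one raw-scale cell table per patient sample (patient x timepoint),
#' one identical-aliquot batch reference per batch (distorted per batch),
#' and one healthy donor per batch, together with a manifest, a clinical
#' table, and the full ground truth (population labels, batch distortion
#' parameters, responder status, latent 24 h values, survival generation
#' record).
#'
#' @param spec a [cohort_spec()].
#' @param panel a [panel_config()] (default [default_panel()]).
#' @return list with `cell_tables` (named list of [cell_table()]s),
#'   `manifest`, `clinical`, `truth`, `panel`, `spec`.
#' @export
generate_cohort <- function(spec, panel = default_panel()) {
  stopifnot(inherits(spec, "cohort_spec"))
  chs <- panel$channels$name
  n_ch <- length(chs)
  pops <- spec$populations
  pop_names <- names(pops)
  target_idx <- which(vapply(pops, function(p) p$is_target, logical(1)))
  target_marker <- spec$response_model$target_marker
  validate_that(target_marker %in% chs, "response_model",
                sprintf("target marker '%s' not in panel", target_marker))
  cofactor <- panel$cofactor

  # --- batch distortion parameters (stream 1) ---
  be <- spec$batch_effect
  if (!is.null(be[["slope"]])) {
    slope <- be[["slope"]]; offset <- be[["offset"]]
  } else {
    withr::with_seed(stream_seed(spec$seed, 1), {
      slope <- matrix(runif(spec$n_batches * n_ch, be$slope_range[1], be$slope_range[2]),
                      spec$n_batches, n_ch, dimnames = list(NULL, chs))
      offset <- matrix(runif(spec$n_batches * n_ch, be$offset_range[1], be$offset_range[2]),
                       spec$n_batches, n_ch, dimnames = list(NULL, chs))
    })
  }
  batch_ids <- paste0("B", seq_len(spec$n_batches))
  rownames(slope) <- rownames(offset) <- batch_ids

  # --- per-patient composition, responder status, shifts (stream 2) ---
  rm_ <- spec$response_model
  withr::with_seed(stream_seed(spec$seed, 2), {
    gam <- matrix(rgamma(spec$n_patients * length(pops),
                         shape = rep(spec$dirichlet_alpha, each = spec$n_patients)),
                  spec$n_patients, length(pops))
    props <- gam / rowSums(gam)
    colnames(props) <- pop_names
    responder <- rbinom(spec$n_patients, 1, rm_$responder_fraction) == 1
    shift24 <- ifelse(responder, rm_$responder_shift, rm_$nonresponder_shift) +
      rnorm(spec$n_patients, 0, rm_$patient_sd)
  })
  patient_ids <- sprintf("P%02d", seq_len(spec$n_patients))
  rownames(props) <- patient_ids
  patient_batch <- batch_ids[(seq_len(spec$n_patients) - 1) %% spec$n_batches + 1]

  # latent value: the patient's true 90th percentile of the target marker
  # in the target population at 24 h (transformed scale)
  tpar <- population_channel_params(pops[[target_idx]], panel)
  latent <- tpar$mu[target_marker] + shift24 +
    stats::qnorm(0.9) * tpar$disp[target_marker]
  latent <- setNames(as.numeric(latent), patient_ids)

  # --- shared reference pool (stream 3), aliquoted identically per batch ---
  pool <- withr::with_seed(stream_seed(spec$seed, 3), {
    draw_mixture(spec$reference_cells, spec$healthy_proportions, pops, panel)
  })

  drop4 <- if (spec$drop_4h_patients > 0) patient_ids[seq_len(spec$drop_4h_patients)] else character(0)

  cell_tables <- list()
  manifest <- list()
  truth_labels <- list()
  add_sample <- function(tab, labels) {
    cell_tables[[tab$sample_id]] <<- tab
    m <- tab$metadata
    manifest[[length(manifest) + 1]] <<- data.frame(
      sample_id = tab$sample_id, patient_id = m$patient_id,
      timepoint_h = m$timepoint_h, batch_id = m$batch_id,
      sample_role = m$sample_role, stringsAsFactors = FALSE)
    truth_labels[[tab$sample_id]] <<- labels
  }

  distort_raw <- function(values_transformed, batch) {
    v <- sweep(sweep(values_transformed, 2, slope[batch, ], `*`),
               2, offset[batch, ], `+`)
    v[v < 0] <- 0
    inverse_arcsinh(v, cofactor)
  }

  # --- patient samples (stream 4 + sample index) ---
  sample_counter <- 0L
  for (i in seq_len(spec$n_patients)) {
    tps <- spec$timepoints
    if (patient_ids[i] %in% drop4) tps <- setdiff(tps, 4)
    for (tp in tps) {
      sample_counter <- sample_counter + 1L
      shift <- if (tp == 0) NULL else if (tp == 24) {
        setNames(shift24[i], target_marker)
      } else {
        setNames(rm_$shift_4h, target_marker)
      }
      mix <- withr::with_seed(stream_seed(spec$seed, 100 + sample_counter), {
        draw_mixture(spec$cells_per_sample, props[i, ], pops, panel,
                     marker_shift = shift)
      })
      sid <- sprintf("%s_T%02d", patient_ids[i], tp)
      tab <- cell_table(distort_raw(mix$values, patient_batch[i]), sid,
                        scale = "raw", patient_id = patient_ids[i],
                        timepoint_h = tp, batch_id = patient_batch[i],
                        sample_role = "patient")
      add_sample(tab, mix$labels)
    }
  }

  # --- healthy donors, one per batch (stream 5 + batch) ---
  for (b in seq_len(spec$n_batches)) {
    mix <- withr::with_seed(stream_seed(spec$seed, 5000 + b), {
      draw_mixture(spec$cells_per_sample, spec$healthy_proportions, pops, panel)
    })
    sid <- sprintf("HD%02d", b)
    tab <- cell_table(distort_raw(mix$values, batch_ids[b]), sid,
                      scale = "raw", patient_id = sid, timepoint_h = 0,
                      batch_id = batch_ids[b], sample_role = "healthy_donor")
    add_sample(tab, mix$labels)
  }

  # --- reference aliquots: identical pool, per-batch distortion ---
  for (b in seq_len(spec$n_batches)) {
    sid <- sprintf("REF%02d", b)
    tab <- cell_table(distort_raw(pool$values, batch_ids[b]), sid,
                      scale = "raw", patient_id = NA_character_,
                      timepoint_h = NA_real_, batch_id = batch_ids[b],
                      sample_role = "batch_reference")
    add_sample(tab, pool$labels)
  }

  # --- survival + clinical (streams 6, 7) ---
  surv <- simulate_survival(latent, spec$survival_model,
                            stream_seed(spec$seed, 6))
  clinical <- withr::with_seed(stream_seed(spec$seed, 7), {
    age <- pmin(pmax(round(rnorm(spec$n_patients, 55, 12)), 18), 85)
    sex <- rbinom(spec$n_patients, 1, 0.5)
    cr <- rbinom(spec$n_patients, 1, ifelse(responder, 0.85, 0.45))
    tx_ok <- surv$os_days > 100
    tx_hi <- pmax(61, pmin(surv$os_days - 1, 365))
    tx <- ifelse(tx_ok & runif(spec$n_patients) < 0.4,
                 round(runif(spec$n_patients, 60, tx_hi)),
                 NA_real_)
    data.frame(patient_id = patient_ids, age = age, sex = sex,
               os_days = surv$os_days, os_event = surv$os_event,
               transplant_day = tx, cr_status = cr, stringsAsFactors = FALSE)
  })

  manifest <- do.call(rbind, manifest)
  truth <- list(labels = truth_labels,
                population_names = pop_names,
                target_population = pop_names[target_idx],
                target_marker = target_marker,
                proportions = props,
                responder = setNames(responder, patient_ids),
                shift24 = setNames(shift24, patient_ids),
                latent = latent,
                beta = spec$survival_model$beta,
                batch_slope = slope, batch_offset = offset,
                survival = surv)
  list(cell_tables = cell_tables, manifest = manifest, clinical = clinical,
       truth = truth, panel = panel, spec = spec)
}

#' Write a generated cohort to disk as plain-text files
#'
#' Per-sample cell tables as CSV (header = channel names), the manifest and
#' clinical tables as TSV, and the ground truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest with a `path` column, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    sid <- cohort$manifest$sample_id[i]
    paths[i] <- file.path(dir, paste0(sid, ".csv"))
    write.csv(as.data.frame(cohort$cell_tables[[sid]]$data),
              paths[i], row.names = FALSE)
  }
  manifest <- cbind(cohort$manifest, path = paths)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(responder = as.list(cohort$truth$responder),
         latent = as.list(cohort$truth$latent),
         beta = cohort$truth$beta,
         target_population = cohort$truth$target_population,
         target_marker = cohort$truth$target_marker),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
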