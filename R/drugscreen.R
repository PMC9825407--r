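# Ex vivo drug-sensitivity scoring: plate control normalization, monotone
# dose-response summarization, drug sensitivity score (DSS), selective DSS
# against healthy controls, and top-target tallies.

#' Normalize a plate to its controls
#'
#' Percent inhibition per well:
#' `100 * (neg_median - readout) / (neg_median - pos_median)`, where the
#' negative controls (DMSO) define 0% and the positive controls (a cytotoxic
#' control such as benzethonium chloride) define 100%.
#'
#' @param plate data frame with columns `drug`, `conc_nM`, `readout`,
#'   `control_type` (`""`/`NA` for drug wells, `"positive"`, `"negative"`).
#' @return the drug wells with an added `inhibition` column.
#' @export
normalize_plate <- function(plate) {
  ct <- plate$control_type %||% rep(NA, nrow(plate))
  pos <- plate$readout[!is.na(ct) & ct == "positive"]
  neg <- plate$readout[!is.na(ct) & ct == "negative"]
  validate_that(length(pos) >= 1 && length(neg) >= 1, "plate",
                "need at least one positive and one negative control")
  pm <- median(pos); nm <- median(neg)
  if (nm <= pm) {
    stop("plate quality error: negative-control median not above positive-control median",
         call. = FALSE)
  }
  wells <- plate[is.na(ct) | ct %in% c("", "none"), , drop = FALSE]
  wells$inhibition <- 100 * (nm - wells$readout) / (nm - pm)
  wells
}

#' Drug sensitivity score from a dose-inhibition series
#'
#' Normalized thresholded area under the inhibition / log10-concentration
#' curve: inhibition values are clipped to \[-10, 110\], smoothed to be
#' monotone non-decreasing in dose (isotonic regression -- robust and
#' deterministic at a handful of dose points), and integrated
#' trapezoidally above the activity threshold `t`:
#' `DSS = 100 * integral(max(0, y - t)) / ((100 - t) * (xmax - xmin))`.
#' A fully inactive drug scores 0, full inhibition over the whole range
#' scores 100.
#'
#' @param inhibition percent inhibition per dose.
#' @param conc_nM positive concentrations (nM), e.g. a 5-point 10-fold
#'   series from 1 nM to 10 uM.
#' @param activity_threshold inhibition floor `t` (default 10).
#' @return DSS in \[0, 100\].
#' @export
compute_dss <- function(inhibition, conc_nM, activity_threshold = 10) {
  validate_that(length(inhibition) >= 2, "inhibition",
                "need at least 2 dose points")
  validate_that(all(conc_nM > 0), "conc_nM", "concentrations must be positive")
  o <- order(conc_nM)
  x <- log10(conc_nM[o])
  y <- pmin(pmax(inhibition[o], -10), 110)
  y <- isoreg(x, y)$yf
  t <- activity_threshold
  h <- pmax(0, pmin(y, 100) - t)
  auc <- sum(diff(x) * (head(h, -1) + h[-1]) / 2)
  100 * auc / ((100 - t) * (max(x) - min(x)))
}

#' Selective DSS against healthy controls
#'
#' `sDSS = DSS - mean(healthy DSS for the same drug)`; may be negative.
#'
#' @param patient_dss data frame with `sample_id`, `drug`, `dss`.
#' @param healthy_dss data frame with `drug`, `dss` (one row per healthy
#'   control per drug).
#' @return `patient_dss` with an `sdss` column; drugs absent from the
#'   healthy table get `NA` with a warning.
#' @export
compute_sdss <- function(patient_dss, healthy_dss) {
  hm <- tapply(healthy_dss$dss, healthy_dss$drug, mean)
  missing <- setdiff(unique(patient_dss$drug), names(hm))
  if (length(missing) > 0) {
    warning(sprintf("no healthy-control DSS for drug(s): %s",
                    paste(missing, collapse = ", ")))
  }
  patient_dss$sdss <- patient_dss$dss - as.numeric(hm[patient_dss$drug])
  patient_dss
}

#' Top drug-target tally per patient group
#'
#' For each sample the top-n drugs by sDSS (descending; ties broken
#' lexicographically by drug name) are mapped to their targets; target
#' frequencies are tallied across the group.
#'
#' @param sdss data frame with `sample_id`, `drug`, `sdss`.
#' @param targets named character vector or data frame (`drug`, `target`)
#'   mapping drugs to targets.
#' @param n top drugs per sample (default 10; all used with a warning when
#'   fewer are scored).
#' @return named integer vector: target -> number of samples carrying it in
#'   their top n.
#' @export
top_targets <- function(sdss, targets, n = 10) {
  if (is.data.frame(targets)) {
    targets <- setNames(targets$target, targets$drug)
  }
  if (length(targets) == 0) stop("empty target map", call. = FALSE)
  tallies <- lapply(split(sdss, sdss$sample_id), function(s) {
    s <- s[!is.na(s$sdss), ]
    if (nrow(s) < n) {
      warning(sprintf("sample %s has only %d scored drugs (top %d requested)",
                      s$sample_id[1], nrow(s), n))
    }
    s <- s[order(-s$sdss, s$drug), ]
    top <- head(s$drug, n)
    unique(unname(targets[top[top %in% names(targets)]]))
  })
  tab <- sort(table(unlist(tallies)), decreasing = TRUE)
  setNames(as.integer(tab), names(tab))
}

#' Simulate drug-screen plates for the synthetic cohort
#'
#' One plate per sample: `n_drugs` drugs at a 5-point 10-fold dilution
#' series (1 nM - 10 uM) with 8 positive and 8 negative control wells.
#' Half the drugs are "active" with logistic dose-response whose potency is
#' sample-specific; readouts are viability-scale with multiplicative noise.
#'
#' @param sample_ids character vector of sample names.
#' @param n_drugs drugs per plate (default 24).
#' @param seed integer seed.
#' @param potency_shift optional named per-sample shift of log10-IC50
#'   (positive = more resistant).
#' @return named list of plate data frames (see [normalize_plate()]).
#' @export
simulate_plates <- function(sample_ids, n_drugs = 24, seed = 1,
                            potency_shift = NULL) {
  conc <- 10^(0:4)            # 1 nM .. 10 uM
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  withr::with_seed(seed, {
    active <- rbinom(n_drugs, 1, 0.5) == 1
    ic50 <- runif(n_drugs, 0.5, 3.5)   # log10 nM
    out <- lapply(sample_ids, function(sid) {
      shift <- if (!is.null(potency_shift)) potency_shift[[sid]] %||% 0 else 0
      wells <- do.call(rbind, lapply(seq_len(n_drugs), function(d) {
        inh <- if (active[d]) {
          100 / (1 + 10^((ic50[d] + shift - log10(conc)) * 1.5))
        } else rep(0, length(conc))
        viability <- (100 - inh) * exp(rnorm(length(conc), 0, 0.03))
        data.frame(drug = drugs[d], conc_nM = conc, readout = viability,
                   control_type = NA_character_, stringsAsFactors = FALSE)
      }))
      ctrl <- data.frame(
        drug = NA_character_, conc_nM = NA_real_,
        readout = c(exp(rnorm(8, 0, 0.05)),          # positive: ~0 viability
                    100 * exp(rnorm(8, 0, 0.03))),   # negative: ~100
        control_type = rep(c("positive", "negative"), each = 8),
        stringsAsFactors = FALSE)
      rbind(wells, ctrl)
    })
    names(out) <- sample_ids
    out
  })
}
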