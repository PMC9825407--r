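# Patient x feature matrix engineering: per-metacluster per-marker
# 90th-percentile signaling at each timepoint, 24 h ratio/delta features,
# metacluster size percentages, and clinical covariates.

#' Metacluster abundance of one sample
#'
#' @param assignment an [assign_cells()] result (non-empty).
#' @param k total number of metaclusters (so empty metaclusters report 0%).
#' @return named percentage vector summing to 100.
#' @export
cluster_abundance <- function(assignment, k = max(assignment$metacluster)) {
  if (nrow(assignment) == 0) stop("empty sample", call. = FALSE)
  counts <- tabulate(assignment$metacluster, nbins = k)
  setNames(100 * counts / sum(counts), paste0("MC", seq_len(k)))
}

#' Percentile signaling feature of one marker in one metacluster
#'
#' The q-th empirical quantile (linear interpolation of order statistics,
#' "type 7") of the transformed marker values; `NA` with a missing flag when
#' fewer than `min_cells` cells support it (a high percentile of a handful
#' of cells is noise).
#'
#' @param values transformed intensities of one marker for the cells of one
#'   metacluster in one sample.
#' @param q percentile as a fraction in (0, 1) (default 0.90).
#' @param min_cells minimum cells required (default 10).
#' @return the quantile, or `NA_real_` when undersupported.
#' @export
percentile_feature <- function(values, q = 0.90, min_cells = 10) {
  validate_that(q > 0 && q < 1, "q", "must be in (0, 1)")
  values <- values[is.finite(values)]
  if (length(values) < min_cells) return(NA_real_)
  unname(quantile(values, probs = q, type = 7))
}

#' Per-sample feature extraction
#'
#' For every metacluster and functional marker of each sample, computes the
#' percentile feature plus the metacluster size percentages.
#'
#' @param tables named list of normalized transformed-scale [cell_table()]s.
#' @param assignments named list of [assign_cells()] results (same names).
#' @param panel a [panel_config()].
#' @param k number of metaclusters.
#' @param q percentile fraction.
#' @param min_cells minimum cells per (metacluster, sample) feature.
#' @return long data frame: sample_id, patient_id, timepoint_h, metacluster,
#'   marker, value (rows with marker `".size"` carry abundance percentages).
#' @export
extract_sample_features <- function(tables, assignments, panel, k = 10,
                                    q = 0.90, min_cells = 10) {
  func <- panel_channels(panel, "functional")
  rows <- lapply(names(tables), function(sid) {
    tab <- tables[[sid]]
    asn <- assignments[[sid]]
    stopifnot(nrow(tab$data) == nrow(asn))
    ab <- cluster_abundance(asn, k = k)
    per_mc <- lapply(seq_len(k), function(mc) {
      idx <- which(asn$metacluster == mc)
      vals <- vapply(func, function(m) {
        percentile_feature(tab$data[idx, m], q = q, min_cells = min_cells)
      }, numeric(1))
      data.frame(sample_id = sid, patient_id = tab$metadata$patient_id,
                 timepoint_h = tab$metadata$timepoint_h,
                 metacluster = mc,
                 marker = c(func, ".size"),
                 value = c(vals, unname(ab[mc])),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_mc)
  })
  do.call(rbind, rows)
}

#' Build the patient x feature matrix
#'
#' Columns are per-metacluster per-functional-marker percentile levels at
#' each timepoint, the 24h/0h ratio (and optionally the 24h - 0h delta) per
#' metacluster x marker, the metacluster size percentages at baseline, and
#' age and sex from the clinical table. Ratio denominators at or below
#' `ratio_floor` yield a missing value rather than an explosive ratio.
#' Missing entries (undersupported percentiles, patients lacking a 4 h
#' sample, floored ratios) are mean-imputed per column; the missingness
#' pattern is retained in the `missing` attribute.
#'
#' @param sample_features an [extract_sample_features()] result restricted
#'   to patient samples.
#' @param clinical clinical table with `patient_id`, `age`, `sex`.
#' @param timepoints level timepoints to include (default 0, 4, 24).
#' @param transforms subset of `c("ratio24h", "delta24h")`.
#' @param ratio_floor denominator floor for ratio24h (transformed scale).
#' @return numeric matrix (patients x features) with attributes `missing`
#'   (logical matrix pre-imputation) and `provenance` (per-column data
#'   frame: metacluster, marker, timepoint, transform).
#' @export
build_feature_matrix <- function(sample_features, clinical,
                                 timepoints = c(0, 4, 24),
                                 transforms = "ratio24h",
                                 ratio_floor = 1e-6) {
  sf <- sample_features[sample_features$marker != ".size", ]
  sizes <- sample_features[sample_features$marker == ".size" &
                             sample_features$timepoint_h == 0, ]
  patients <- sort(unique(sf$patient_id))
  has_tp <- function(p, tp) any(sf$patient_id == p & sf$timepoint_h == tp)
  for (p in patients) {
    if (!has_tp(p, 0) || !has_tp(p, 24)) {
      stop(sprintf("patient %s lacks a mandatory 0 h or 24 h sample", p),
           call. = FALSE)
    }
  }
  mcs <- sort(unique(sf$metacluster))
  markers <- unique(sf$marker)

  key <- function(mc, m, tp) paste0("MC", mc, "_", m, "_", tp, "h")
  cols <- list()
  prov <- list()
  add_col <- function(name, values, mc, marker, tp, transform) {
    cols[[name]] <<- values
    prov[[name]] <<- data.frame(column = name, metacluster = mc,
                                marker = marker, timepoint = tp,
                                transform = transform,
                                stringsAsFactors = FALSE)
  }
  lookup <- function(mc, m, tp) {
    sub <- sf[sf$metacluster == mc & sf$marker == m & sf$timepoint_h == tp, ]
    setNames(sub$value, sub$patient_id)[patients]
  }
  for (mc in mcs) for (m in markers) {
    lv <- lapply(timepoints, function(tp) lookup(mc, m, tp))
    names(lv) <- as.character(timepoints)
    for (tp in timepoints) {
      add_col(key(mc, m, tp), lv[[as.character(tp)]], mc, m, tp, "level")
    }
    if ("ratio24h" %in% transforms) {
      den <- lv[["0"]]
      num <- lv[["24"]]
      r <- ifelse(!is.na(den) & abs(den) > ratio_floor, num / den, NA_real_)
      add_col(paste0("MC", mc, "_", m, "_ratio24h"), r, mc, m, NA, "ratio24h")
    }
    if ("delta24h" %in% transforms) {
      add_col(paste0("MC", mc, "_", m, "_delta24h"), lv[["24"]] - lv[["0"]],
              mc, m, NA, "delta24h")
    }
  }
  for (mc in mcs) {
    sub <- sizes[sizes$metacluster == mc, ]
    add_col(paste0("MC", mc, "_size"),
            setNames(sub$value, sub$patient_id)[patients],
            mc, NA, 0, "size")
  }
  cl <- clinical[match(patients, clinical$patient_id), ]
  add_col("age", setNames(cl$age, patients), NA, NA, NA, "clinical")
  add_col("sex", setNames(cl$sex, patients), NA, NA, NA, "clinical")

  X <- do.call(cbind, lapply(cols, unname))
  rownames(X) <- patients
  colnames(X) <- names(cols)
  miss <- is.na(X)
  if (any(miss)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    for (j in which(colSums(miss) > 0)) X[miss[, j], j] <- mu[j]
  }
  attr(X, "missing") <- miss
  attr(X, "provenance") <- do.call(rbind, unname(prov))
  X
}
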