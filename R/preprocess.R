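#' Arcsinh variance-stabilizing transform
#'
#' Replaces every raw intensity x by `asinh(x / cofactor)`. The transform is
#' strictly monotone, so per-channel cell rankings (and hence empirical
#' quantiles' rank positions) are preserved.
#'
#' @param table a raw-scale [cell_table()].
#' @param cofactor positive cofactor (5 for mass cytometry).
#' @param allow_negative permit negative input values (raw dual counts are
#'   non-negative; the flag exists for already-compensated data).
#' @return the transformed `cell_table` (scale flag `"transformed"`).
#' @export
arcsinh_transform <- function(table, cofactor = 5, allow_negative = FALSE) {
  stopifnot(inherits(table, "cell_table"))
  validate_that(cofactor > 0, "cofactor", "must be positive")
  if (table$scale != "raw") {
    stop("input is already on the transformed scale", call. = FALSE)
  }
  if (!allow_negative && nrow(table$data) > 0 && min(table$data) < 0) {
    stop("negative raw intensities; set allow_negative = TRUE if intended",
         call. = FALSE)
  }
  table$data <- asinh(table$data / cofactor)
  table$scale <- "transformed"
  table
}

#' Invert the arcsinh transform
#' @noRd
inverse_arcsinh <- function(x, cofactor = 5) cofactor * sinh(x)

# ---- anchored quantile normalization ---------------------------------------

#' Fit per-batch quantile maps against a target batch's reference aliquot
#'
#' Each acquisition batch carries an aliquot of the same pooled reference
#' sample. For every non-target batch and channel the map's source knots are
#' that batch's reference empirical quantiles on an evenly spaced probability
#' grid (default 0%, 1%, ..., 100%) and the target knots are the target
#' batch's reference quantiles at the same grid; samples are then corrected
#' by piecewise-linear interpolation between the knots. The target batch's
#' own map is the identity.
#'
#' Quantiles use linear interpolation of order statistics (the "type 7"
#' convention), recorded in the returned object. Consecutive duplicate
#' source knots (tied values on zero-inflated channels) are collapsed to a
#' single knot whose target is the mean of their targets, so ties map to one
#' well-defined value. A channel whose reference is constant is marked
#' pass-through with a warning.
#'
#' @param references named list of transformed-scale [cell_table()]s with
#'   `sample_role = "batch_reference"`, one per batch (names = batch ids).
#' @param target_batch batch id to standardize towards (must be explicit:
#'   picking the cleanest batch is an analyst decision).
#' @param grid_size number of probability knots (default 101).
#' @param channels channels to normalize; default all shared channels.
#' @return object of class `quantile_maps`: per batch, per channel, source
#'   and target knot vectors.
#' @export
fit_quantile_maps <- function(references, target_batch, grid_size = 101,
                              channels = NULL) {
  validate_that(length(references) >= 1 && !is.null(names(references)),
                "references", "need a named list of batch references")
  for (r in references) {
    stopifnot(inherits(r, "cell_table"))
    if (r$scale != "transformed") {
      stop("references must be on the transformed scale", call. = FALSE)
    }
  }
  validate_that(target_batch %in% names(references), "target_batch",
                sprintf("batch '%s' has no reference aliquot", target_batch))
  channels <- channels %||% colnames(references[[1]]$data)
  probs <- seq(0, 1, length.out = grid_size)
  target_ref <- references[[target_batch]]$data
  small <- vapply(references, function(r) nrow(r$data) < grid_size, logical(1))
  if (any(small)) {
    warning(sprintf("reference(s) %s have fewer than %d cells; effective grid reduced",
                    paste(names(references)[small], collapse = ", "), grid_size))
  }
  maps <- lapply(names(references), function(b) {
    ref <- references[[b]]$data
    per_channel <- lapply(channels, function(ch) {
      validate_that(ch %in% colnames(ref) && ch %in% colnames(target_ref),
                    "channels", sprintf("channel '%s' missing from a reference", ch))
      src <- unname(quantile(ref[, ch], probs = probs, type = 7))
      tgt <- unname(quantile(target_ref[, ch], probs = probs, type = 7))
      if (b == target_batch) tgt <- src  # identity by construction
      if (max(src) - min(src) <= 0) {
        warning(sprintf("batch %s channel %s: constant reference, pass-through", b, ch))
        return(list(source = src[1], target = src[1], passthrough = TRUE))
      }
      # collapse runs of tied source knots; target = mean of their targets
      grp <- cumsum(c(TRUE, diff(src) > 0))
      src_u <- vapply(split(src, grp), `[`, numeric(1), 1L)
      tgt_u <- vapply(split(tgt, grp), mean, numeric(1))
      list(source = unname(src_u), target = unname(tgt_u), passthrough = FALSE)
    })
    names(per_channel) <- channels
    per_channel
  })
  names(maps) <- names(references)
  structure(list(maps = maps, target_batch = target_batch,
                 grid_size = grid_size, channels = channels,
                 quantile_type = 7L),
            class = "quantile_maps")
}

#' @export
print.quantile_maps <- function(x, ...) {
  cat(sprintf("<quantile_maps> %d batches -> target '%s', %d channels, %d-point grid (type %d quantiles)\n",
              length(x$maps), x$target_batch, length(x$channels),
              x$grid_size, x$quantile_type))
  invisible(x)
}

#' Evaluate one piecewise-linear knot map
#'
#' Linear interpolation between knots; outside the knot range the terminal
#' segment is extended linearly. A single-knot (pass-through or degenerate)
#' map returns its input shifted by the knot offset.
#' @noRd
eval_knot_map <- function(x, source, target) {
  n <- length(source)
  if (n == 1L) return(x - source + target)
  y <- approx(source, target, xout = x, rule = 2, ties = "ordered")$y
  lo <- x < source[1]
  if (any(lo)) {
    s <- (target[2] - target[1]) / (source[2] - source[1])
    y[lo] <- target[1] + s * (x[lo] - source[1])
  }
  hi <- x > source[n]
  if (any(hi)) {
    s <- (target[n] - target[n - 1]) / (source[n] - source[n - 1])
    y[hi] <- target[n] + s * (x[hi] - source[n])
  }
  y
}

#' Apply a batch's quantile map to a sample
#'
#' @param sample transformed-scale [cell_table()]; its `batch_id` selects the
#'   map. Channels not covered by the maps pass through untouched.
#' @param maps a [fit_quantile_maps()] result.
#' @return the standardized `cell_table`.
#' @export
apply_quantile_maps <- function(sample, maps) {
  stopifnot(inherits(sample, "cell_table"), inherits(maps, "quantile_maps"))
  if (sample$scale != "transformed") {
    stop("sample must be on the transformed scale", call. = FALSE)
  }
  b <- sample$metadata$batch_id
  validate_that(b %in% names(maps$maps), "batch_id",
                sprintf("no quantile map fitted for batch '%s'", b))
  bm <- maps$maps[[b]]
  for (ch in maps$channels) {
    if (!ch %in% colnames(sample$data)) {
      stop(sprintf("channel '%s' in map but missing from sample", ch),
           call. = FALSE)
    }
    m <- bm[[ch]]
    if (isTRUE(m$passthrough)) next
    if (nrow(sample$data) > 0) {
      sample$data[, ch] <- eval_knot_map(sample$data[, ch], m$source, m$target)
    }
  }
  sample
}

#' Serialize quantile maps to JSON
#' @param maps a `quantile_maps` object.
#' @param path file path.
#' @export
write_quantile_maps <- function(maps, path) {
  stopifnot(inherits(maps, "quantile_maps"))
  jsonlite::write_json(unclass(maps), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
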