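#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one integer master seed. Each
#' logically independent random stage (composition draws, cell intensities,
#' batch distortion parameters, survival times, ...) consumes its own
#' sub-seed, derived deterministically so that no stage perturbs another and
#' no global random state is left behind.
#'
#' The scheme is `(seed * 7919 + stream) mod (2^31 - 2) + 1`, i.e. a fixed
#' prime multiplier with a per-stage stream offset, kept inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param seed integer master seed.
#' @param stream non-negative integer identifying the consuming stage.
#' @return an integer seed.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.numeric(seed)) * 7919 + as.numeric(stream)) %% 2147483646
  as.integer(s) + 1L
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a validation error naming the offending field
#' @noRd
validate_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}
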