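#' Single-sample cell table
#'
#' A `cell_table` holds one sample's cells-by-channels intensity matrix
#' together with its metadata and a scale flag. Raw mass cytometry
#' intensities ("dual counts") are non-negative; after the variance
#' stabilizing transform (see [arcsinh_transform()]) the scale flag switches
#' to `"transformed"`.
#'
#' @param data numeric matrix, cells in rows, channels in columns (named).
#' @param sample_id character scalar.
#' @param scale `"raw"` or `"transformed"`.
#' @param patient_id,timepoint_h,batch_id,sample_role sample metadata;
#'   `sample_role` is one of `"patient"`, `"healthy_donor"`,
#'   `"batch_reference"`.
#' @return an object of class `cell_table`.
#' @export
cell_table <- function(data, sample_id, scale = c("raw", "transformed"),
                       patient_id = NA_character_, timepoint_h = NA_real_,
                       batch_id = NA_character_, sample_role = "patient") {
  scale <- match.arg(scale)
  data <- as.matrix(data)
  validate_that(is.numeric(data), "data", "must be a numeric matrix")
  validate_that(!is.null(colnames(data)), "data", "channels must be named")
  if (scale == "raw" && nrow(data) > 0) {
    validate_that(min(data) >= 0, "data", "raw intensities must be non-negative")
  }
  structure(
    list(data = data, sample_id = as.character(sample_id), scale = scale,
         metadata = list(patient_id = patient_id, timepoint_h = timepoint_h,
                         batch_id = batch_id, sample_role = sample_role)),
    class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %s: %d cells x %d channels [%s scale]\n",
              x$sample_id, nrow(x$data), ncol(x$data), x$scale))
  m <- x$metadata
  cat(sprintf("  patient=%s t=%sh batch=%s role=%s\n",
              m$patient_id, m$timepoint_h, m$batch_id, m$sample_role))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$data)

#' Panel configuration: channel roles and transform cofactor
#'
#' Declares which channels drive clustering (surface markers), which are
#' functional (signaling) readouts, and which are excluded from clustering,
#' plus the arcsinh cofactor (5 is the mass cytometry standard).
#'
#' @param channels data frame with columns `name` and
#'   `role` (`"clustering"`, `"functional"` or `"excluded"`).
#' @param cofactor positive arcsinh cofactor.
#' @return object of class `panel_config`.
#' @seealso [default_panel()]
#' @export
panel_config <- function(channels, cofactor = 5) {
  validate_that(is.data.frame(channels) &&
                  all(c("name", "role") %in% names(channels)),
                "channels", "needs columns name, role")
  validate_that(all(channels$role %in% c("clustering", "functional", "excluded")),
                "channels", "roles must be clustering/functional/excluded")
  validate_that(!anyDuplicated(channels$name), "channels", "duplicate channel names")
  validate_that(is.numeric(cofactor) && length(cofactor) == 1 && cofactor > 0,
                "cofactor", "must be a positive number")
  structure(list(channels = channels, cofactor = cofactor),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  tab <- table(x$channels$role)
  cat(sprintf("<panel_config> %d channels (%s), cofactor %g\n",
              nrow(x$channels),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$cofactor))
  invisible(x)
}

#' Channels of a given role
#' @param panel a [panel_config()].
#' @param role one of `"clustering"`, `"functional"`, `"excluded"`,
#'   or `"surface"` (clustering plus excluded surface markers, as used by
#'   within-metacluster sub-clustering).
#' @return character vector of channel names.
#' @export
panel_channels <- function(panel, role) {
  stopifnot(inherits(panel, "panel_config"))
  if (role == "surface") {
    panel$channels$name[panel$channels$role %in% c("clustering", "excluded")]
  } else {
    panel$channels$name[panel$channels$role == role]
  }
}

#' Default antibody panel
#'
#' 19 surface markers used for clustering, 2 surface markers excluded from
#' clustering (CD25 and CD11b, which are kept for sub-clustering), and 15
#' functional (phospho-signaling / cell-state) markers.
#'
#' @param cofactor arcsinh cofactor (default 5).
#' @return a [panel_config()].
#' @export
default_panel <- function(cofactor = 5) {
  clustering <- c("AXL", "CD117", "CD123", "CD14", "CD16", "CD20", "CD3",
                  "CD33", "CD34", "CD38", "CD4", "CD45", "CD56", "CD64",
                  "CD66b", "CD7", "CD8a", "CD90", "HLADR")
  excluded <- c("CD25", "CD11b")
  functional <- c("cCaspase3", "CyclinB1", "p4EBP1", "pAKT", "pAXL", "pCREB",
                  "pERK", "pHistone3", "pNFkB", "pp38", "pRb", "pS6",
                  "pSTAT1", "pSTAT3", "pSTAT5")
  panel_config(
    data.frame(name = c(clustering, excluded, functional),
               role = rep(c("clustering", "excluded", "functional"),
                          c(length(clustering), length(excluded),
                            length(functional))),
               stringsAsFactors = FALSE),
    cofactor = cofactor)
}
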