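#' Load an atlas table of region labels and centroids
#'
#' Returns the node table used for network reporting and BrainNet Viewer
#' export: one row per region with a unique label and finite 3-D centroid
#' coordinates (mm, MNI axis convention). The packaged default covers the
#' 90 cortical and subcortical regions of the AAL parcellation; its
#' coordinates are synthetic approximations suitable for visualisation
#' only (see `inst/extdata/aal90_synthetic_centroids.tsv`). Users can
#' supply their own atlas file with the same columns.
#'
#' @param path Optional path to a tab-separated file with columns
#'   `region` (1-based index), `label`, `x`, `y`, `z`.
#'
#' @return A tibble with columns `region`, `label`, `x`, `y`, `z`.
#' @export
#' @examples
#' head(load_atlas())
load_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal90_synthetic_centroids.tsv",
                        package = "phasenet", mustWork = TRUE)
  }
  atlas <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("region", "label", "x", "y", "z") %in% names(atlas)))
  if (anyDuplicated(atlas$label)) {
    stop("atlas labels must be unique", call. = FALSE)
  }
  if (!all(is.finite(atlas$x) & is.finite(atlas$y) & is.finite(atlas$z))) {
    stop("atlas coordinates must be finite", call. = FALSE)
  }
  atlas
}
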