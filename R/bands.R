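#' Define a frequency band
#'
#' A band is a half-open interval of frequencies used for FIR band-pass
#' filtering and subsequent analytic-signal (Hilbert) decomposition.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low Lower band edge in Hz; must satisfy `0 < low < high`.
#' @param high Upper band edge in Hz.
#'
#' @return A one-row tibble with columns `name`, `low`, `high`.
#' @export
#' @examples
#' band_definition("alpha", 8, 14)
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || !is.finite(low) || !is.finite(high)) {
    stop("band edges must be single finite numbers", call. = FALSE)
  }
  if (!(0 < low && low < high)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  tibble::tibble(name = name, low = as.numeric(low), high = as.numeric(high))
}

#' Canonical oscillatory frequency bands
#'
#' The five canonical bands used throughout: theta 4-7 Hz, alpha 8-14 Hz,
#' beta 15-29 Hz, low gamma 30-55 Hz and gamma 65-80 Hz. Note that some of
#' the literature defines alpha as 8-12 Hz; the 8-14 Hz convention is used
#' here (see the methods vignette).
#'
#' @return A tibble with columns `name`, `low`, `high`, one row per band.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  tibble::tibble(
    name = c("theta", "alpha", "beta", "low_gamma", "gamma"),
    low  = c(4, 8, 15, 30, 65),
    high = c(7, 14, 29, 55, 80)
  )
}

# Coerce a band given as tibble row, list or name into a 1-row band tibble.
as_band <- function(band) {
  if (is.character(band) && length(band) == 1L) {
    bands <- canonical_bands()
    hit <- bands[bands$name == band, ]
    if (nrow(hit) == 0L) {
      stop("unknown canonical band: ", band, call. = FALSE)
    }
    return(hit)
  }
  if (is.data.frame(band)) {
    stopifnot(all(c("name", "low", "high") %in% names(band)), nrow(band) == 1L)
    return(band_definition(band$name, band$low, band$high))
  }
  if (is.list(band)) {
    return(band_definition(band$name, band$low, band$high))
  }
  stop("cannot interpret band", call. = FALSE)
}

band_centre <- function(band) {
  band <- as_band(band)
  (band$low + band$high) / 2
}
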