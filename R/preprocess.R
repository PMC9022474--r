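#' Broadband cleaning of continuous region time series
#'
#' Applies the standard broadband cleaning used before epoching: a
#' fourth-order two-pass (zero-phase) Butterworth band-pass at 1-150 Hz and
#' notch filters at 60 and 120 Hz to attenuate line noise (each notch is
#' applied only when it lies below the Nyquist frequency). When the
#' sampling rate cannot support the 150 Hz edge, the upper edge is clipped
#' to `0.45 * rate` with a warning.
#'
#' @param x Numeric matrix, regions x samples, of continuous data.
#' @param rate Sampling rate in Hz.
#' @param high Upper band-pass edge in Hz (default 150).
#'
#' @return Cleaned matrix of the same shape.
#' @export
preclean <- function(x, rate, high = 150) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("preclean requires finite input samples", call. = FALSE)
  }
  nyq <- rate / 2
  if (high >= 0.45 * rate) {
    high <- 0.45 * rate
    warning("upper band edge clipped to ", high, " Hz for rate ", rate, " Hz",
            call. = FALSE)
  }
  bp <- signal::butter(4, c(1, high) / nyq, type = "pass")
  out <- t(apply(x, 1, function(row) signal::filtfilt(bp, row)))
  for (f0 in c(60, 120)) {
    if (f0 + 2 < nyq) {
      notch <- signal::butter(2, c(f0 - 2, f0 + 2) / nyq, type = "stop")
      out <- t(apply(out, 1, function(row) signal::filtfilt(notch, row)))
    }
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Divide a continuous recording into fixed-length epochs
#'
#' Cuts a regions-x-samples matrix into consecutive non-overlapping epochs
#' of `epoch_length` seconds; a trailing remainder shorter than one epoch is
#' discarded.
#'
#' @param x Numeric matrix, regions x samples.
#' @param rate Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds (default 10).
#' @param subject_id Optional subject identifier carried on the result.
#'
#' @return An `epoched_series`: list with `subject_id`, `epochs` (list of
#'   regions x samples matrices), `sampling_rate`, `epoch_length` and a
#'   per-epoch `qc_log` tibble.
#' @export
#' @examples
#' es <- segment_epochs(matrix(rnorm(2 * 3000), 2), rate = 300,
#'                      epoch_length = 1)
#' length(es$epochs)
segment_epochs <- function(x, rate, epoch_length = 10, subject_id = NA_character_) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  spe <- as.integer(round(epoch_length * rate))
  n_ep <- ncol(x) %/% spe
  if (n_ep < 1L) {
    stop("recording (", ncol(x) / rate, " s) is shorter than one epoch of ",
         epoch_length, " s", call. = FALSE)
  }
  epochs <- lapply(seq_len(n_ep), function(k) {
    x[, ((k - 1L) * spe + 1L):(k * spe), drop = FALSE]
  })
  structure(
    list(subject_id = subject_id, epochs = epochs, sampling_rate = rate,
         epoch_length = epoch_length,
         qc_log = tibble::tibble(epoch = seq_len(n_ep), kept = TRUE,
                                 reason = NA_character_)),
    class = "epoched_series"
  )
}

#' @export
print.epoched_series <- function(x, ...) {
  cat("<epoched_series> subject ", x$subject_id, ": ", length(x$epochs),
      " epochs of ", nrow(x$epochs[[1]]), " regions x ",
      ncol(x$epochs[[1]]), " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Quality-control exclusion of epochs
#'
#' Drops epochs whose head-motion deviation exceeds `motion_limit` mm
#' (strictly greater; an epoch exactly at the limit is retained) or that
#' contain any sample whose absolute amplitude exceeds `amplitude_limit`
#' (again strictly). Missing motion values are treated as exclusions. Every
#' input epoch is accounted for exactly once in the updated `qc_log`;
#' surviving epochs keep their order. The operation is idempotent.
#'
#' @param series An `epoched_series`.
#' @param motion_trace Numeric vector of per-epoch head-position deviations
#'   (mm) from the recording median position, aligned with the epochs.
#'   `NULL` skips the motion rule.
#' @param motion_limit Motion exclusion limit in mm (default 5).
#' @param amplitude_limit Absolute amplitude limit in the data's field
#'   units (default 2; for sensor-space MEG this corresponds to the
#'   conventional +/- 2 pT rule, for source-space or simulated data supply
#'   a limit on the working amplitude scale).
#'
#' @return The `epoched_series` with excluded epochs removed and `qc_log`
#'   recording each original epoch's fate.
#' @export
exclude_epochs <- function(series, motion_trace = NULL, motion_limit = 5,
                           amplitude_limit = 2) {
  stopifnot(inherits(series, "epoched_series"))
  n <- length(series$epochs)
  if (!is.null(motion_trace) && length(motion_trace) != n) {
    stop("motion_trace length (", length(motion_trace),
         ") must match epoch count (", n, ")", call. = FALSE)
  }
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    if (!is.null(motion_trace)) {
      if (is.na(motion_trace[k])) {
        reason[k] <- "motion_missing"
        next
      }
      if (motion_trace[k] > motion_limit) {
        reason[k] <- "motion"
        next
      }
    }
    if (any(abs(series$epochs[[k]]) > amplitude_limit)) {
      reason[k] <- "amplitude"
    }
  }
  keep <- is.na(reason)
  prior <- series$qc_log[series$qc_log$kept, ]
  log_new <- tibble::tibble(epoch = prior$epoch, kept = keep, reason = reason)
  dropped_before <- series$qc_log[!series$qc_log$kept, ]
  series$qc_log <- dplyr::arrange(dplyr::bind_rows(dropped_before, log_new),
                                  .data$epoch)
  series$epochs <- series$epochs[keep]
  series
}

#' Minimum-data inclusion rule
#'
#' A subject is included in group analyses only with at least `minimum`
#' artefact-free epochs (the default of 6 ten-second epochs corresponds to
#' 1 min of usable resting-state data).
#'
#' @param series An `epoched_series` after QC.
#' @param minimum Minimum surviving epoch count (default 6).
#'
#' @return A one-row tibble: `subject_id`, `n_epochs`, `include`.
#' @export
enforce_minimum <- function(series, minimum = 6) {
  stopifnot(inherits(series, "epoched_series"))
  n <- length(series$epochs)
  tibble::tibble(subject_id = series$subject_id, n_epochs = n,
                 include = n >= minimum)
}

#' Band-limited analytic signal per epoch
#'
#' Filters each epoch of each region into the requested band with a
#' two-pass (zero-phase) windowed-sinc FIR filter, then forms the analytic
#' signal via the Hilbert transform. The filter order is at least three
#' cycles of the band's low edge at the working rate. A configurable number
#' of edge samples (default: the filter order) is trimmed from both ends of
#' every epoch to suppress filter and Hilbert edge transients.
#'
#' @param series An `epoched_series`.
#' @param band A band (name of a canonical band, or a [band_definition()]).
#' @param trim Samples to trim from each end (default: filter order).
#'
#' @return An `analytic_epochs` object: `subject_id`, `band`, `epochs`
#'   (list of complex regions x samples matrices), `sampling_rate`.
#' @export
band_analytic <- function(series, band, trim = NULL) {
  stopifnot(inherits(series, "epoched_series"))
  band <- as_band(band)
  rate <- series$sampling_rate
  if (band$high >= rate / 2) {
    stop("band ", band$name, " upper edge ", band$high,
         " Hz is not below the Nyquist frequency ", rate / 2, " Hz",
         call. = FALSE)
  }
  ord <- fir_order(band, rate)
  spe <- ncol(series$epochs[[1]])
  if (spe < 3L * ord) {
    stop("epochs of ", spe, " samples are shorter than 3x the filter order (",
         ord, ")", call. = FALSE)
  }
  if (is.null(trim)) trim <- ord
  if (2L * trim >= spe) stop("trim leaves no samples", call. = FALSE)
  kern <- fir_two_pass_kernel(band, rate)
  keep <- if (trim > 0) (trim + 1L):(spe - trim) else seq_len(spe)
  epochs <- lapply(series$epochs, function(ep) {
    filt <- filter_zero_phase(ep, kern$h, kern$L)
    analytic_signal_matrix(filt)[, keep, drop = FALSE]
  })
  structure(
    list(subject_id = series$subject_id, band = band, epochs = epochs,
         sampling_rate = rate, trim = trim),
    class = "analytic_epochs"
  )
}

#' @export
print.analytic_epochs <- function(x, ...) {
  cat("<analytic_epochs> subject ", x$subject_id, ", band ", x$band$name,
      " (", x$band$low, "-", x$band$high, " Hz): ", length(x$epochs),
      " epochs of ", nrow(x$epochs[[1]]), " regions x ", ncol(x$epochs[[1]]),
      " samples\n", sep = "")
  invisible(x)
}
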