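#' Weighted phase lag index of two analytic signals
#'
#' For analytic samples `z_i(t)`, `z_j(t)` with cross-spectrum
#' `X_t = z_i(t) * Conj(z_j(t))`, the weighted phase lag index is
#' `|sum(Im(X_t))| / sum(|Im(X_t)|)`. Phase differences are weighted by the
#' magnitude of the imaginary component of the cross-spectrum, so 90-degree
#' lags carry maximal weight and purely instantaneous (zero-lag) coupling —
#' the signature of field spread — contributes nothing. Values range from 0
#' (no consistent phase lag) to 1 (perfectly consistent lag sign). When the
#' denominator is zero (pure zero-lag or silent input) the value is 0 by
#' convention.
#'
#' @param z_i,z_j Equal-length complex vectors of analytic samples.
#'
#' @return wPLI scalar in `[0, 1]`.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 200)
#' z <- exp(2i * pi * 10 * t)
#' epoch_wpli(z, z * exp(1i * pi / 2)) # consistent 90-degree lag -> 1
epoch_wpli <- function(z_i, z_j) {
  if (length(z_i) != length(z_j)) {
    stop("signals must have equal length", call. = FALSE)
  }
  if (length(z_i) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(z_i) || anyNA(z_j) ||
      any(!is.finite(Re(z_i)) | !is.finite(Im(z_i))) ||
      any(!is.finite(Re(z_j)) | !is.finite(Im(z_j)))) {
    stop("non-finite input", call. = FALSE)
  }
  imx <- Im(z_i * Conj(z_j))
  den <- sum(abs(imx))
  if (den == 0) return(0)
  abs(sum(imx)) / den
}

# Full wPLI matrix for one epoch: complex regions x samples matrix in,
# symmetric regions x regions matrix out (diagonal 0).
wpli_epoch_matrix <- function(z) {
  n <- nrow(z)
  at <- t(Re(z))  # samples x regions
  bt <- t(Im(z))
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    imx <- bt[, i] * at[, jj, drop = FALSE] - at[, i] * bt[, jj, drop = FALSE]
    den <- colSums(abs(imx))
    num <- abs(colSums(imx))
    v <- ifelse(den > 0, num / den, 0)
    w[i, jj] <- v
    w[jj, i] <- v
  }
  w
}

#' Subject-level wPLI connectivity matrix
#'
#' Computes the wPLI for every region pair within each epoch and averages
#' across epochs, yielding one symmetric connectivity matrix per subject
#' and band. The estimator is applied within epochs (over time samples)
#' first and then averaged — samples are never pooled across epochs before
#' the ratio is taken.
#'
#' @param analytic An `analytic_epochs` object from [band_analytic()].
#'
#' @return A `connectivity_matrix`: list with `subject_id`, `band`,
#'   `values` (symmetric matrix in `[0, 1]`, zero diagonal) and
#'   `n_epochs_used`.
#' @export
subject_connectivity <- function(analytic) {
  stopifnot(inherits(analytic, "analytic_epochs"))
  if (length(analytic$epochs) < 1L) stop("no epochs", call. = FALSE)
  mats <- lapply(analytic$epochs, wpli_epoch_matrix)
  values <- Reduce(`+`, mats) / length(mats)
  structure(
    list(subject_id = analytic$subject_id, band = analytic$band,
         values = values, n_epochs_used = length(mats)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> subject ", x$subject_id, ", band ",
      x$band$name, ": ", nrow(x$values), " x ", ncol(x$values),
      ", mean off-diagonal wPLI = ",
      signif(mean(x$values[upper.tri(x$values)]), 3),
      " (", x$n_epochs_used, " epochs)\n", sep = "")
  invisible(x)
}

validate_connectivity_values <- function(values, context = "connectivity") {
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(context, ": non-finite value at cell (", bad[1, 1], ", ",
         bad[1, 2], ")", call. = FALSE)
  }
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(context, ": value ", values[bad[1, 1], bad[1, 2]],
         " outside [0, 1] at cell (", bad[1, 1], ", ", bad[1, 2], ")",
         call. = FALSE)
  }
  asym <- abs(values - t(values))
  if (max(asym) > 1e-8) {
    bad <- which(asym == max(asym), arr.ind = TRUE)
    stop(context, ": matrix not symmetric at cell (", bad[1, 1], ", ",
         bad[1, 2], ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write connectivity matrices as delimited text
#'
#' The format is plain text: `#`-prefixed header lines carrying
#' `subject_id`, band (name and edges in Hz) and `n_epochs_used`, followed
#' by the full square matrix, one row per line, tab-delimited, at full
#' floating precision. `read_connectivity()` validates symmetry, range and
#' finiteness and names the offending cell on failure.
#'
#' @param cm A `connectivity_matrix`.
#' @param path File path.
#'
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns a `connectivity_matrix`.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  validate_connectivity_values(cm$values, "write_connectivity")
  header <- c(
    paste0("# subject_id: ", cm$subject_id),
    paste0("# band: ", cm$band$name, " ",
           format(cm$band$low, digits = 17), " ",
           format(cm$band$high, digits = 17)),
    paste0("# n_epochs_used: ", cm$n_epochs_used)
  )
  rows <- apply(cm$values, 1, function(r) {
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("missing header field: ", key, call. = FALSE)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  subject_id <- get_field("subject_id")
  band_parts <- strsplit(get_field("band"), "\\s+")[[1]]
  band <- band_definition(band_parts[1], as.numeric(band_parts[2]),
                          as.numeric(band_parts[3]))
  n_epochs <- as.integer(get_field("n_epochs_used"))
  values <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (nrow(values) != ncol(values)) {
    stop("matrix is not square: ", nrow(values), " x ", ncol(values),
         call. = FALSE)
  }
  validate_connectivity_values(values, paste0("read_connectivity(", path, ")"))
  structure(
    list(subject_id = subject_id, band = band, values = values,
         n_epochs_used = n_epochs),
    class = "connectivity_matrix"
  )
}
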