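# Internal helpers shared across modules.

# Analytic signal via frequency-domain Hilbert transform.
# Real vector in, complex vector out: Re = input, Im = Hilbert transform,
# Mod = instantaneous amplitude, Arg = instantaneous phase.
analytic_signal <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("analytic_signal requires finite numeric input", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Analytic signal of every row of a real matrix (batched over columns of
# the transposed data with mvfft).
analytic_signal_matrix <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  xt <- t(x)
  zt <- stats::mvfft(stats::mvfft(xt) * h, inverse = TRUE) / n
  t(zt)
}

# Two-pass FIR filtering as a single symmetric (zero-phase) kernel applied
# by FFT convolution to every row of a regions x samples matrix. Identical
# to forward-backward filtering away from the epoch edges; the edges are
# handled by zero padding and are trimmed downstream.
filter_zero_phase <- function(x, h, L) {
  n <- ncol(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1L, c(2, 3, 5))
  hf <- stats::fft(c(h, numeric(nfft - m)))
  xt <- rbind(t(x), matrix(0, nfft - n, nrow(x)))
  yt <- Re(stats::mvfft(stats::mvfft(xt) * hf, inverse = TRUE)) / nfft
  t(yt[(L + 1L):(L + n), , drop = FALSE])
}

# Symmetric two-pass kernel for a windowed-sinc band-pass FIR.
fir_two_pass_kernel <- function(band, rate) {
  b <- fir_bandpass(band, rate)
  list(h = stats::convolve(b, b, type = "open"), L = length(b) - 1L)
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-subject seed stream derived from a master seed.
subject_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

# Upper-triangle index pairs (i < j) for an n x n symmetric matrix.
edge_index <- function(n_regions) {
  idx <- which(upper.tri(diag(n_regions)), arr.ind = TRUE)
  tibble::tibble(i = idx[, "row"], j = idx[, "col"])
}
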