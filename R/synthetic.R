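#' Specify a synthetic resting-state cohort
#'
#' Builds the full generative recipe for a two-group cohort of region-level
#' oscillatory time series with known phase-lag coupling, plus subject
#' metadata (sex, age, outcome scores, daily macronutrient intakes). The
#' planted coupling structure gives every downstream stage — band-limited
#' analytic decomposition, wPLI connectivity, network-based statistics — a
#' ground truth to recover.
#'
#' Coupling: for each planted edge `(i, j, band)`, region `j`'s component in
#' that band is `kappa * delay(x_i) + sqrt(1 - kappa^2) * e_j`, where `x_i`
#' is region `i`'s unit-variance band-limited carrier, the delay realises
#' `phase_lag` radians at the band centre frequency, `e_j` is an independent
#' band-limited carrier, and `kappa` is `coupling_a` or `coupling_b`
#' depending on the subject's group.
#'
#' @param n_group_a,n_group_b Number of subjects per group.
#' @param n_regions Number of atlas regions (default 90).
#' @param sampling_rate Sampling rate in Hz (default 300).
#' @param epoch_length Epoch length in seconds (default 10).
#' @param n_epochs Epochs per subject (default 30, i.e. a 5-min recording).
#' @param bands Tibble of band definitions (default [canonical_bands()]).
#' @param planted_edges Tibble with columns `i`, `j`, `band` naming directed
#'   coupling edges (region `j` receives the lagged copy of region `i`).
#' @param coupling_a,coupling_b Coupling strength kappa in `[0, 1]` for
#'   groups A and B.
#' @param phase_lag Phase lag in radians at the band centre (default `pi/2`,
#'   the lag wPLI weights most heavily).
#' @param noise_sd SD of broadband white measurement noise added to every
#'   region (carriers have unit SD; default 0.5).
#' @param fieldspread_strength Zero-lag spatial mixing coefficient in
#'   `[0, 1)` applied by [generate_cohort()] (default 0, no mixing).
#' @param outcome_model List of outcome recipes; each element is a list with
#'   `intercept`, `effect` (outcome units per unit kappa), `age_coef`,
#'   `sex_coef`, and `residual_sd`. Defaults to an IQ-like score
#'   (mean 100, SD 15) and a BASC-like T-score (mean 50, SD 10), both with
#'   zero planted effect.
#' @param intake_model Tibble with columns `nutrient`, `mean`, `sd`,
#'   `kappa_link` describing daily intake draws for postnatal days 1-29
#'   (g/kg/day; energy in kcal/kg/day). Defaults to protein 3.6 (0.5),
#'   lipid 4.9 (1.1), carbohydrate 11.9 (1.3), energy 105.6 (14.9) with no
#'   kappa linkage.
#' @param age_mean,age_sd Age-at-scan distribution in years (drawn
#'   independently of group by default; length-2 vectors give per-group
#'   values in order A, B).
#' @param sex_prob Probability of male sex (independent of group).
#' @param motion_mean,motion_sd Per-epoch head-motion deviation distribution
#'   (mm, folded normal).
#' @param seed Master RNG seed; all cohort randomness derives from it.
#'
#' @return A `cohort_spec` object (list with the fields above, validated).
#' @export
#' @examples
#' spec <- cohort_spec(5, 5, n_regions = 12, n_epochs = 2, seed = 1)
cohort_spec <- function(n_group_a,
                        n_group_b,
                        n_regions = 90,
                        sampling_rate = 300,
                        epoch_length = 10,
                        n_epochs = 30,
                        bands = canonical_bands(),
                        planted_edges = NULL,
                        coupling_a = 0,
                        coupling_b = 0,
                        phase_lag = pi / 2,
                        noise_sd = 0.5,
                        fieldspread_strength = 0,
                        outcome_model = default_outcome_model(),
                        intake_model = default_intake_model(),
                        age_mean = 5.8,
                        age_sd = 0.3,
                        sex_prob = 0.5,
                        motion_mean = 2,
                        motion_sd = 1,
                        seed = 1L) {
  stopifnot(n_group_a >= 1, n_group_b >= 1, n_regions >= 2, n_epochs >= 1,
            sampling_rate > 0, epoch_length > 0)
  bands <- dplyr::bind_rows(lapply(seq_len(nrow(bands)), function(k) {
    band_definition(bands$name[k], bands$low[k], bands$high[k])
  }))
  if (sampling_rate <= 2 * max(bands$high)) {
    stop("sampling_rate must exceed twice the highest band edge (",
         max(bands$high), " Hz)", call. = FALSE)
  }
  if (!all(c(coupling_a, coupling_b) >= 0 & c(coupling_a, coupling_b) <= 1)) {
    stop("coupling strengths must lie in [0, 1]", call. = FALSE)
  }
  if (fieldspread_strength < 0 || fieldspread_strength >= 1) {
    stop("fieldspread_strength must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(planted_edges)) {
    planted_edges <- tibble::tibble(i = integer(), j = integer(),
                                    band = character())
  }
  planted_edges <- tibble::as_tibble(planted_edges)
  if (nrow(planted_edges)) {
    stopifnot(all(c("i", "j", "band") %in% names(planted_edges)))
    ok <- planted_edges$i != planted_edges$j &
      planted_edges$i >= 1 & planted_edges$i <= n_regions &
      planted_edges$j >= 1 & planted_edges$j <= n_regions
    if (!all(ok)) stop("planted edges must join distinct valid regions",
                       call. = FALSE)
    if (!all(planted_edges$band %in% bands$name)) {
      stop("planted edge bands must appear in the band set", call. = FALSE)
    }
    if (anyDuplicated(planted_edges[, c("j", "band")])) {
      stop("each region can receive at most one planted edge per band",
           call. = FALSE)
    }
    # lag must be representable as >= 1 sample at each planted band's centre
    for (bn in unique(planted_edges$band)) {
      ctr <- band_centre(bands[bands$name == bn, ])
      d <- round(sampling_rate * (phase_lag / (2 * pi)) / ctr)
      if (d < 1) {
        stop("phase_lag of ", signif(phase_lag, 3), " rad is not representable",
             " at ", sampling_rate, " Hz for band ", bn, call. = FALSE)
      }
    }
  }
  spec <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_regions = as.integer(n_regions), sampling_rate = sampling_rate,
    epoch_length = epoch_length, n_epochs = as.integer(n_epochs),
    bands = bands, planted_edges = planted_edges,
    coupling_a = coupling_a, coupling_b = coupling_b,
    phase_lag = phase_lag, noise_sd = noise_sd,
    fieldspread_strength = fieldspread_strength,
    outcome_model = outcome_model, intake_model = intake_model,
    age_mean = age_mean, age_sd = age_sd, sex_prob = sex_prob,
    motion_mean = motion_mean, motion_sd = motion_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @rdname cohort_spec
#' @export
default_outcome_model <- function() {
  list(
    iq   = list(intercept = 100, effect = 0, age_coef = 0, sex_coef = 0,
                residual_sd = 15),
    basc = list(intercept = 50, effect = 0, age_coef = 0, sex_coef = 0,
                residual_sd = 10)
  )
}

#' @rdname cohort_spec
#' @export
default_intake_model <- function() {
  tibble::tibble(
    nutrient   = c("protein", "lipid", "carbohydrate", "energy"),
    mean       = c(3.6, 4.9, 11.9, 105.6),
    sd         = c(0.5, 1.1, 1.3, 14.9),
    kappa_link = 0
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_group_a, "+", x$n_group_b, " subjects, ",
      x$n_regions, " regions, ", x$n_epochs, " x ", x$epoch_length,
      " s epochs @ ", x$sampling_rate, " Hz\n", sep = "")
  cat("  bands: ", paste0(x$bands$name, " (", x$bands$low, "-", x$bands$high,
                          " Hz)", collapse = ", "), "\n", sep = "")
  cat("  planted edges: ", nrow(x$planted_edges),
      "; kappa A/B = ", x$coupling_a, "/", x$coupling_b,
      "; phase lag = ", signif(x$phase_lag, 3), " rad\n", sep = "")
  invisible(x)
}

# Unit-variance band-limited carriers, one per row: white noise two-pass
# FIR filtered (batched FFT convolution).
band_carriers <- function(n_rows, n_samples, band, rate) {
  kern <- fir_two_pass_kernel(band, rate)
  noise <- matrix(stats::rnorm(n_rows * n_samples), nrow = n_rows,
                  byrow = TRUE)
  x <- filter_zero_phase(noise, kern$h, kern$L)
  sds <- apply(x, 1, stats::sd)
  sds[sds == 0] <- 1
  x / sds
}

# Windowed-sinc FIR coefficients; order >= 3 cycles of the low edge, even.
fir_bandpass <- function(band, rate) {
  band <- as_band(band)
  if (band$high >= rate / 2) {
    stop("band ", band$name, " (", band$low, "-", band$high,
         " Hz) is at or above the Nyquist frequency of ", rate / 2, " Hz",
         call. = FALSE)
  }
  ord <- ceiling(3 * rate / band$low)
  if (ord %% 2L == 1L) ord <- ord + 1L
  signal::fir1(ord, c(band$low, band$high) / (rate / 2), type = "pass")
}

fir_order <- function(band, rate) {
  band <- as_band(band)
  ord <- ceiling(3 * rate / band$low)
  if (ord %% 2L == 1L) ord <- ord + 1L
  ord
}

#' Generate one subject's region time series
#'
#' Simulates continuous multi-band oscillatory activity for all regions of a
#' single subject and cuts it into epochs. Each region carries one
#' independent unit-variance band-limited stochastic carrier per band; for
#' each planted edge the receiving region's carrier in that band is replaced
#' by the kappa-weighted, phase-delayed copy of the source region's carrier
#' (see [cohort_spec()]). Broadband Gaussian noise with SD `noise_sd` is
#' added. Deterministic given the spec seed and subject id.
#'
#' @param spec A [cohort_spec()].
#' @param subject A one-row tibble (or list) with at least `subject_id`,
#'   `group` (`"A"` or `"B"`) and `seed`; rows of the cohort table returned
#'   by [generate_cohort()] qualify.
#'
#' @return An `epoched_series` object (see [segment_epochs()]).
#' @export
generate_region_timeseries <- function(spec, subject) {
  stopifnot(inherits(spec, "cohort_spec"))
  kappa <- if (identical(as.character(subject$group), "A")) spec$coupling_a
           else spec$coupling_b
  rate <- spec$sampling_rate
  n_samp <- as.integer(round(spec$n_epochs * spec$epoch_length * rate))
  # generate with headroom so delayed copies stay inside the carrier
  delays <- integer(nrow(spec$bands))
  names(delays) <- spec$bands$name
  for (k in seq_len(nrow(spec$bands))) {
    ctr <- (spec$bands$low[k] + spec$bands$high[k]) / 2
    delays[k] <- as.integer(round(rate * (spec$phase_lag / (2 * pi)) / ctr))
  }
  pad <- max(0L, delays)
  total <- n_samp + pad
  x <- with_seed(subject$seed, {
    out <- matrix(0, nrow = spec$n_regions, ncol = total)
    for (k in seq_len(nrow(spec$bands))) {
      bn <- spec$bands$name[k]
      band <- spec$bands[k, ]
      carriers <- band_carriers(spec$n_regions, total, band, rate)
      planted <- spec$planted_edges[spec$planted_edges$band == bn, ]
      comp <- carriers
      if (nrow(planted)) {
        d <- delays[bn]
        if (d < 1L) {
          stop("phase_lag delay is not representable at ", rate,
               " Hz for band ", bn, call. = FALSE)
        }
        for (e in seq_len(nrow(planted))) {
          i <- planted$i[e]; j <- planted$j[e]
          lagged <- c(rep(0, d), carriers[i, seq_len(total - d)])
          comp[j, ] <- kappa * lagged + sqrt(1 - kappa^2) * carriers[j, ]
        }
      }
      out <- out + comp
    }
    if (spec$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = spec$noise_sd),
                          nrow = spec$n_regions)
    }
    out[, (pad + 1L):total, drop = FALSE]
  })
  segment_epochs(x, rate = rate, epoch_length = spec$epoch_length,
                 subject_id = as.character(subject$subject_id))
}

#' Apply instantaneous field-spread mixing
#'
#' Emulates volume conduction / field spread: each region's signal is
#' replaced by `(1 - strength) * own + strength * smoothed`, where
#' `smoothed` is the zero-lag average of the two neighbouring regions in
#' atlas order (wrapped). The mixing is purely instantaneous, so it inflates
#' zero-lag synchrony but adds no consistent phase lag — precisely the
#' artefact the wPLI is designed to ignore.
#'
#' @param series An `epoched_series`.
#' @param strength Mixing coefficient in `[0, 1)`.
#'
#' @return An `epoched_series` with mixed signals.
#' @export
apply_field_spread <- function(series, strength) {
  stopifnot(inherits(series, "epoched_series"))
  if (!is.numeric(strength) || length(strength) != 1L ||
      strength < 0 || strength >= 1) {
    stop("strength must lie in [0, 1)", call. = FALSE)
  }
  if (strength == 0) return(series)
  n <- nrow(series$epochs[[1]])
  prev <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n - 1L) + 1L, 1L)
  series$epochs <- lapply(series$epochs, function(ep) {
    (1 - strength) * ep + strength * (ep[prev, , drop = FALSE] +
                                        ep[nxt, , drop = FALSE]) / 2
  })
  series
}

#' Generate a full synthetic cohort
#'
#' Draws subject metadata (group, sex, age at scan, per-epoch head-motion
#' deviations, outcome scores, daily nutrient intakes for postnatal days
#' 1-29) and per-subject epoched region time series according to a
#' [cohort_spec()]. Outcome scores follow
#' `intercept + effect * kappa + age_coef * age + sex_coef * male + noise`,
#' so a nonzero `effect` plants an outcome-connectivity association.
#' Field-spread mixing is applied when `fieldspread_strength > 0`.
#'
#' @param spec A [cohort_spec()].
#' @param series Logical; set `FALSE` to draw metadata only (fast).
#'
#' @return A list with elements:
#' \describe{
#'   \item{cohort}{tibble, one row per subject: `subject_id`, `group`,
#'     `sex`, `age_at_scan`, one column per outcome, and `seed`.}
#'   \item{intakes}{long tibble: `subject_id`, `postnatal_day`, `nutrient`,
#'     `value`.}
#'   \item{motion}{tibble: `subject_id`, `epoch`, `motion_mm`.}
#'   \item{series}{list of `epoched_series`, one per subject (or `NULL`).}
#'   \item{ground_truth}{tibble of planted edges with band and kappa per
#'     group, for test harnesses.}
#'   \item{spec}{the generating spec.}
#' }
#' @export
#' @examples
#' gc <- generate_cohort(cohort_spec(3, 3, n_regions = 8, n_epochs = 1,
#'                                   sampling_rate = 200,
#'                                   bands = canonical_bands()[2, ],
#'                                   epoch_length = 2, seed = 7))
#' gc$cohort
generate_cohort <- function(spec, series = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_group_a + spec$n_group_b
  seeds <- subject_seeds(spec$seed, n + 1L)
  group <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  kappa <- ifelse(group == "A", spec$coupling_a, spec$coupling_b)
  cohort <- with_seed(seeds[n + 1L], {
    age_mean <- rep_len(spec$age_mean, 2L)
    age_sd <- rep_len(spec$age_sd, 2L)
    gi <- ifelse(group == "A", 1L, 2L)
    age <- stats::rnorm(n, age_mean[gi], age_sd[gi])
    sex <- ifelse(stats::runif(n) < spec$sex_prob, "M", "F")
    tab <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group, sex = sex, age_at_scan = round(age, 2)
    )
    for (nm in names(spec$outcome_model)) {
      om <- spec$outcome_model[[nm]]
      tab[[nm]] <- om$intercept + om$effect * kappa +
        om$age_coef * age + om$sex_coef * (sex == "M") +
        stats::rnorm(n, sd = om$residual_sd)
    }
    tab$seed <- seeds[seq_len(n)]
    tab
  })
  intakes <- with_seed(seeds[n + 1L] + 1L, {
    im <- spec$intake_model
    grid <- tidyr::expand_grid(
      subject_id = cohort$subject_id,
      postnatal_day = 1:29,
      nutrient = im$nutrient
    )
    grid <- dplyr::left_join(grid, im, by = "nutrient")
    ksub <- stats::setNames(kappa, cohort$subject_id)
    mu <- grid$mean + grid$kappa_link * ksub[grid$subject_id]
    grid$value <- pmax(0, stats::rnorm(nrow(grid), mu, grid$sd))
    grid[, c("subject_id", "postnatal_day", "nutrient", "value")]
  })
  motion <- with_seed(seeds[n + 1L] + 2L, {
    tidyr::expand_grid(subject_id = cohort$subject_id,
                       epoch = seq_len(spec$n_epochs)) |>
      dplyr::mutate(motion_mm = abs(stats::rnorm(dplyr::n(),
                                                 spec$motion_mean,
                                                 spec$motion_sd)))
  })
  ser <- NULL
  if (series) {
    ser <- lapply(seq_len(n), function(s) {
      es <- generate_region_timeseries(spec, cohort[s, ])
      if (spec$fieldspread_strength > 0) {
        es <- apply_field_spread(es, spec$fieldspread_strength)
      }
      es
    })
    names(ser) <- cohort$subject_id
  }
  gt <- spec$planted_edges
  if (nrow(gt)) {
    gt$kappa_a <- spec$coupling_a
    gt$kappa_b <- spec$coupling_b
  }
  list(cohort = cohort, intakes = intakes, motion = motion, series = ser,
       ground_truth = gt, spec = spec)
}
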