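#' Demo pipeline configuration
#'
#' A small end-to-end configuration: a 10+10-subject synthetic cohort with
#' a planted alpha-band subnetwork, theta and alpha analysis bands, QC, a
#' group-contrast NBS and an IQ association, finishing in well under a
#' minute on one CPU.
#'
#' @param seed Master seed.
#' @param output_dir Where result files are written (default: a fresh
#'   temporary directory).
#'
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, output_dir = tempfile("phasenet_demo_")) {
  list(
    mode = "simulate",
    output_dir = output_dir,
    seed = seed,
    simulate = list(
      n_group_a = 10, n_group_b = 10, n_regions = 20,
      sampling_rate = 100, epoch_length = 4, n_epochs = 8,
      bands = canonical_bands()[1:2, ],
      planted_edges = tibble::tibble(i = 1L, j = 2:5, band = "alpha"),
      coupling_a = 0.7, coupling_b = 0.2, noise_sd = 0.5
    ),
    bands = c("theta", "alpha"),
    qc = list(motion_limit = 5, amplitude_limit = Inf, min_epochs = 6),
    designs = list(
      list(mode = "group_contrast", predictor = "group",
           direction = "negative", target_edge_fraction = 0.02,
           n_permutations = 200),
      list(mode = "association", predictor = "iq",
           direction = "positive", target_edge_fraction = 0.02,
           n_permutations = 200)
    )
  )
}

pipeline_log <- function(con, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(line, con)
}

#' Run the full connectivity pipeline
#'
#' Executes every stage end to end: simulate (or ingest matrices from
#' disk), broadband preclean, epoching, QC exclusion, minimum-epoch
#' inclusion, per-band analytic decomposition, wPLI connectivity,
#' edge z-scoring, NBS per design and band, degree/hub reporting and
#' BrainNet export, writing delimited-text summaries and a line-oriented
#' log (with ISO timestamps, seed and QC counts) to `output_dir`.
#'
#' @param config A config list (see [demo_config()]) or the path of a YAML
#'   file with the same structure. Required fields: `mode`
#'   (`"simulate"` or `"matrices"`), `output_dir`, `seed`, `bands`,
#'   `designs`; `simulate` holds [cohort_spec()] arguments, `matrices`
#'   holds `connectivity_files` (vector of paths) and `cohort_csv`.
#'
#' @return Invisibly, a result bundle: list with `cohort`, `qc`,
#'   `connectivity` (per band, list of `connectivity_matrix`), `results`
#'   (per design x band `nbs_result`), `summary` tibble, `components`
#'   tibble, `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), config$mode %in% c("simulate", "matrices"))
  out_dir <- config$output_dir %||% tempfile("phasenet_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  pipeline_log(log_con, "pipeline start; mode=", config$mode,
               "; seed=", seed, "; phasenet ",
               as.character(utils::packageVersion("phasenet")),
               "; R ", as.character(getRversion()))

  qc_cfg <- config$qc %||% list()
  motion_limit <- qc_cfg$motion_limit %||% 5
  amplitude_limit <- qc_cfg$amplitude_limit %||% Inf
  min_epochs <- qc_cfg$min_epochs %||% 6

  if (config$mode == "simulate") {
    sim_args <- config$simulate
    if (is.data.frame(sim_args$planted_edges) ||
        is.list(sim_args$planted_edges)) {
      sim_args$planted_edges <- tibble::as_tibble(sim_args$planted_edges)
    }
    sim_args$seed <- sim_args$seed %||% seed
    spec <- do.call(cohort_spec, sim_args)
    band_names <- config$bands %||% spec$bands$name
    bands <- spec$bands[spec$bands$name %in% band_names, ]
    if (!nrow(bands)) stop("no requested band is in the simulated band set",
                           call. = FALSE)
    # Nyquist guard before any compute
    if (max(bands$high) >= spec$sampling_rate / 2) {
      stop("requested band upper edge ", max(bands$high),
           " Hz is not below Nyquist (", spec$sampling_rate / 2,
           " Hz) — aborting before compute", call. = FALSE)
    }
    pipeline_log(log_con, "stage=simulate; subjects=",
                 spec$n_group_a + spec$n_group_b)
    gc_out <- generate_cohort(spec, series = FALSE)
    cohort <- gc_out$cohort
    rate <- spec$sampling_rate

    qc_rows <- list()
    conn <- stats::setNames(vector("list", nrow(bands)), bands$name)
    for (nm in bands$name) conn[[nm]] <- list()
    included <- character()
    for (s in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[s]
      es <- tryCatch(
        generate_region_timeseries(spec, cohort[s, ]),
        error = function(e) stop("stage=simulate subject=", sid, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      if (spec$fieldspread_strength > 0) {
        es <- apply_field_spread(es, spec$fieldspread_strength)
      }
      cont <- do.call(cbind, es$epochs)
      cont <- suppressWarnings(preclean(cont, rate))
      es <- segment_epochs(cont, rate, spec$epoch_length, subject_id = sid)
      motion <- gc_out$motion$motion_mm[gc_out$motion$subject_id == sid]
      es <- exclude_epochs(es, motion_trace = motion,
                           motion_limit = motion_limit,
                           amplitude_limit = amplitude_limit)
      inc <- enforce_minimum(es, minimum = min_epochs)
      qc_rows[[s]] <- dplyr::mutate(inc,
                                    n_dropped = sum(!es$qc_log$kept))
      pipeline_log(log_con, "stage=qc; subject=", sid, "; kept=",
                   inc$n_epochs, "; include=", inc$include)
      if (!inc$include) next
      included <- c(included, sid)
      for (b in seq_len(nrow(bands))) {
        an <- tryCatch(
          band_analytic(es, bands[b, ]),
          error = function(e) stop("stage=band_analytic subject=", sid, ": ",
                                   conditionMessage(e), call. = FALSE)
        )
        conn[[bands$name[b]]][[sid]] <- subject_connectivity(an)
      }
    }
    qc <- dplyr::bind_rows(qc_rows)
    cohort_used <- cohort[cohort$subject_id %in% included, ]
  } else {
    cohort_used <- readr::read_csv(config$matrices$cohort_csv,
                                   show_col_types = FALSE)
    files <- config$matrices$connectivity_files
    mats <- lapply(files, read_connectivity)
    band_names <- unique(vapply(mats, function(m) m$band$name, ""))
    conn <- lapply(stats::setNames(band_names, band_names), function(bn) {
      ms <- mats[vapply(mats, function(m) m$band$name, "") == bn]
      stats::setNames(ms, vapply(ms, function(m) m$subject_id, ""))
    })
    bands <- dplyr::bind_rows(lapply(conn, function(ms) ms[[1]]$band))
    qc <- tibble::tibble(subject_id = cohort_used$subject_id,
                         n_epochs = NA_integer_, include = TRUE,
                         n_dropped = NA_integer_)
    gc_out <- NULL
  }

  readr::write_csv(cohort_used, file.path(out_dir, "cohort.csv"))
  readr::write_csv(qc, file.path(out_dir, "qc.csv"))
  if (!is.null(gc_out)) {
    readr::write_csv(gc_out$intakes, file.path(out_dir, "intakes.csv"))
    if (nrow(gc_out$ground_truth)) {
      readr::write_csv(gc_out$ground_truth,
                       file.path(out_dir, "ground_truth_edges.csv"))
    }
  }

  atlas <- NULL
  results <- list()
  summary_rows <- list()
  comp_rows <- list()
  for (b in seq_len(nrow(bands))) {
    bn <- bands$name[b]
    mats <- conn[[bn]]
    mats <- mats[cohort_used$subject_id]
    stack <- zscore_edges(unname(mats))
    if (is.null(atlas) && stack$n_regions == 90) atlas <- load_atlas()
    for (d in seq_along(config$designs)) {
      dargs <- config$designs[[d]]
      dargs$seed <- dargs$seed %||% seed
      des <- do.call(design_spec, dargs)
      pipeline_log(log_con, "stage=nbs; band=", bn, "; predictor=",
                   des$predictor, "; direction=", des$direction)
      res <- tryCatch(
        nbs_test(stack, cohort_used, des),
        error = function(e) stop("stage=nbs band=", bn, " predictor=",
                                 des$predictor, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
      key <- paste0(bn, ".", des$predictor, ".", des$direction)
      results[[key]] <- res
      summary_rows[[key]] <- dplyr::mutate(glance(res), band = bn,
                                           .before = 1)
      td <- tidy(res)
      if (nrow(td)) comp_rows[[key]] <- dplyr::mutate(td, band = bn,
                                                      predictor = des$predictor,
                                                      .before = 1)
      sig <- vapply(res$components, function(cp) isTRUE(cp$significant), TRUE)
      if (any(sig)) {
        atl <- atlas %||% tibble::tibble(
          region = seq_len(stack$n_regions),
          label = sprintf("region_%03d", seq_len(stack$n_regions)),
          x = 0, y = 0, z = seq_len(stack$n_regions))
        export_brainnet(res, atl,
                        file.path(out_dir, paste0(key, ".node")),
                        file.path(out_dir, paste0(key, ".edge")))
        pipeline_log(log_con, "stage=export; network=", key)
      }
    }
  }
  summary <- dplyr::bind_rows(summary_rows)
  components <- dplyr::bind_rows(comp_rows)
  readr::write_csv(summary, file.path(out_dir, "summary.csv"))
  readr::write_csv(components, file.path(out_dir, "components.csv"))
  pipeline_log(log_con, "pipeline done")
  invisible(list(cohort = cohort_used, qc = qc, connectivity = conn,
                 results = results, summary = summary,
                 components = components, output_dir = out_dir))
}
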