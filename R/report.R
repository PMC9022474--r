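#' Node degree within a network component
#'
#' Degree is the number of component edges incident to a region; high-degree
#' regions are the network's hubs. The handshake lemma guarantees that the
#' degrees sum to twice the component extent.
#'
#' @param component A component from [extract_components()] or an
#'   `nbs_result` component.
#'
#' @return A tibble with columns `region` and `degree`, sorted by region.
#' @export
node_degree <- function(component) {
  stopifnot(is.list(component), !is.null(component$edges))
  ids <- c(component$edges$i, component$edges$j)
  tab <- table(ids)
  tibble::tibble(region = as.integer(names(tab)),
                 degree = as.integer(tab)) |>
    dplyr::arrange(.data$region)
}

#' Rank network hubs by degree
#'
#' Regions are ranked by degree descending; ties are broken by region label
#' in lexicographic order. Labels come from the atlas table.
#'
#' @param degrees Tibble with columns `region`, `degree` (from
#'   [node_degree()]).
#' @param top_k Number of hubs to return; values beyond the number of
#'   regions return the full ranking.
#' @param atlas Atlas tibble from [load_atlas()]; `NULL` labels regions by
#'   index.
#'
#' @return A tibble `region`, `label`, `degree`, `rank` with `top_k` rows.
#' @export
identify_hubs <- function(degrees, top_k = 10, atlas = NULL) {
  if (nrow(degrees) == 0L) stop("empty degree table", call. = FALSE)
  if (top_k < 1) stop("top_k must be at least 1", call. = FALSE)
  if (is.null(atlas)) {
    degrees$label <- sprintf("region_%03d", degrees$region)
  } else {
    degrees <- dplyr::left_join(degrees, atlas[, c("region", "label")],
                                by = "region")
    if (anyNA(degrees$label)) {
      stop("atlas does not cover region(s): ",
           paste(degrees$region[is.na(degrees$label)], collapse = ", "),
           call. = FALSE)
    }
  }
  out <- degrees |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$label) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("region", "label", "degree", "rank")
  utils::head(out, min(top_k, nrow(out)))
}

#' Export a network in BrainNet Viewer node/edge format
#'
#' Writes the standard whitespace-delimited BrainNet Viewer files: a
#' `.node` file with one row per atlas region (`x y z colour size label`,
#' size = within-component degree, colour = component membership) and an
#' `.edge` file holding the full square adjacency matrix (1/0 membership,
#' or the edge t values when `weights = "t"`).
#'
#' @param result An `nbs_result` (significant components are exported; all
#'   components if none is significant) or a single component list.
#' @param atlas Atlas tibble from [load_atlas()]; must cover every
#'   component region.
#' @param node_path,edge_path Output file paths.
#' @param weights `"binary"` (default) or `"t"` (requires an `nbs_result`).
#'
#' @return Invisibly, a list with the node tibble and edge matrix written.
#' @export
export_brainnet <- function(result, atlas, node_path, edge_path,
                            weights = c("binary", "t")) {
  weights <- match.arg(weights)
  if (inherits(result, "nbs_result")) {
    comps <- result$components
    sig <- vapply(comps, function(cp) isTRUE(cp$significant), TRUE)
    if (any(sig)) comps <- comps[sig]
    tmat <- result$edge_stats$t_matrix
  } else {
    comps <- list(result)
    tmat <- NULL
    if (weights == "t") {
      stop("t-value weights require an nbs_result", call. = FALSE)
    }
  }
  n <- nrow(atlas)
  used <- unique(unlist(lapply(comps, function(cp) cp$nodes)))
  if (length(setdiff(used, atlas$region))) {
    stop("atlas does not cover region(s): ",
         paste(setdiff(used, atlas$region), collapse = ", "), call. = FALSE)
  }
  size <- numeric(n)
  colour <- numeric(n)
  adj <- matrix(0, n, n)
  for (k in seq_along(comps)) {
    cp <- comps[[k]]
    deg <- node_degree(cp)
    size[deg$region] <- deg$degree
    colour[cp$nodes] <- k
    w <- if (weights == "t") tmat[cbind(cp$edges$i, cp$edges$j)] else 1
    adj[cbind(cp$edges$i, cp$edges$j)] <- w
    adj[cbind(cp$edges$j, cp$edges$i)] <- w
  }
  node <- tibble::tibble(x = atlas$x, y = atlas$y, z = atlas$z,
                         colour = colour, size = size, label = atlas$label)
  writeLines(sprintf("%g %g %g %g %g %s", node$x, node$y, node$z,
                     node$colour, node$size, node$label), node_path)
  writeLines(apply(adj, 1, function(r) paste(format(r, trim = TRUE),
                                             collapse = " ")), edge_path)
  invisible(list(node = node, edge = adj))
}

#' Read BrainNet Viewer node/edge files back
#'
#' Round-trip companion to [export_brainnet()]: parses the `.node` and
#' `.edge` files and reconstructs the network.
#'
#' @param node_path,edge_path Paths written by [export_brainnet()].
#'
#' @return A list with `node` (tibble `x`, `y`, `z`, `colour`, `size`,
#'   `label`) and `edge` (square numeric matrix).
#' @export
read_brainnet <- function(node_path, edge_path) {
  nd <- utils::read.table(node_path, header = FALSE,
                          col.names = c("x", "y", "z", "colour", "size",
                                        "label"))
  ed <- as.matrix(utils::read.table(edge_path, header = FALSE))
  dimnames(ed) <- NULL
  storage.mode(ed) <- "double"
  if (nrow(ed) != ncol(ed)) stop("edge matrix is not square", call. = FALSE)
  list(node = tibble::as_tibble(nd), edge = ed)
}

#' Group comparison of demographic and outcome variables
#'
#' Compares each variable between two groups with the conventional
#' dispatch: categorical variables by Pearson chi-square (no continuity
#' correction); continuous variables by a two-tailed pooled-variance
#' t-test when Shapiro-Wilk finds both groups consistent with normality
#' (alpha 0.05), otherwise by a Mann-Whitney U test. Group summaries are
#' formatted mean +/- SD for the t-test branch and median \{IQR\}
#' otherwise.
#'
#' @param cohort Cohort tibble.
#' @param variables Tibble with columns `variable` (column name) and
#'   `type` (`"categorical"` or `"continuous"`).
#' @param group Name of the two-level grouping column (default `"group"`).
#'
#' @return A tibble with one row per variable: `variable`, `type`, `test`,
#'   `statistic`, `df`, `p_value`, `summary_a`, `summary_b`.
#' @export
compare_demographics <- function(cohort, variables, group = "group") {
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2L) stop("need exactly 2 groups", call. = FALSE)
  lv <- levels(g)
  out <- list()
  for (k in seq_len(nrow(variables))) {
    vn <- variables$variable[k]
    ty <- variables$type[k]
    v <- cohort[[vn]]
    ok <- !is.na(v) & !is.na(g)
    va <- v[ok & g == lv[1]]
    vb <- v[ok & g == lv[2]]
    if (ty == "categorical") {
      tab <- table(factor(g[ok]), factor(v[ok]))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      fmt <- function(x) {
        paste(sprintf("%s:%d", colnames(tab), x), collapse = " ")
      }
      out[[k]] <- tibble::tibble(
        variable = vn, type = ty, test = "chi-square",
        statistic = unname(ct$statistic),
        df = as.numeric(unname(ct$parameter)),
        p_value = ct$p.value,
        summary_a = fmt(tab[1, ]), summary_b = fmt(tab[2, ])
      )
    } else {
      if (length(va) < 3L || length(vb) < 3L) {
        warning("skipping '", vn, "': a group has fewer than 3 observations",
                call. = FALSE)
        next
      }
      normal <- stats::shapiro.test(va)$p.value >= 0.05 &&
        stats::shapiro.test(vb)$p.value >= 0.05
      if (normal) {
        tt <- stats::t.test(va, vb, var.equal = TRUE)
        fmt <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
        out[[k]] <- tibble::tibble(
          variable = vn, type = ty, test = "t-test",
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value, summary_a = fmt(va), summary_b = fmt(vb)
        )
      } else {
        mw <- stats::wilcox.test(va, vb, exact = FALSE)
        fmt <- function(x) {
          q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
          sprintf("%.1f {%.1f, %.1f}", q[2], q[1], q[3])
        }
        out[[k]] <- tibble::tibble(
          variable = vn, type = ty, test = "mann-whitney",
          statistic = unname(mw$statistic), df = NA_real_,
          p_value = mw$p.value, summary_a = fmt(va), summary_b = fmt(vb)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Default enteral intake recommendations
#'
#' Daily enteral recommendations for very-low-birth-weight infants:
#' protein 3.5, lipid 4.8, carbohydrate 11.6 g/kg/day and energy
#' 110 kcal/kg/day.
#'
#' @return A tibble `nutrient`, `recommendation`, `unit`.
#' @export
intake_recommendations <- function() {
  tibble::tibble(
    nutrient = c("protein", "lipid", "carbohydrate", "energy"),
    recommendation = c(3.5, 4.8, 11.6, 110),
    unit = c("g/kg/day", "g/kg/day", "g/kg/day", "kcal/kg/day")
  )
}

#' Summarise early macronutrient and energy intakes
#'
#' Averages each subject's daily intakes over a postnatal-day window
#' (default days 9-29 inclusive; the first postnatal week is dominated by
#' parenteral feeding and fluid loss and is excluded) and flags whether
#' the window mean meets or exceeds the enteral recommendation. Days
#' missing from the window are excluded from the mean and counted.
#'
#' @param intakes Long tibble with columns `subject_id`, `postnatal_day`,
#'   `nutrient`, `value` (g/kg/day; energy kcal/kg/day). Values must be
#'   non-negative.
#' @param window Inclusive postnatal-day window (default `c(9, 29)`).
#' @param recommendations Tibble `nutrient`, `recommendation`; defaults to
#'   [intake_recommendations()].
#'
#' @return A list with `subjects` (tibble `subject_id`, `nutrient`,
#'   `mean_intake`, `n_days`, `n_missing_days`, `achieved`) and `summary`
#'   (tibble `nutrient`, `mean`, `sd`, `n_achieved`, `n_subjects`,
#'   `pct_achieved` with percentages rounded half away from zero).
#' @export
summarize_intake <- function(intakes, window = c(9, 29),
                             recommendations = intake_recommendations()) {
  stopifnot(all(c("subject_id", "postnatal_day", "nutrient", "value") %in%
                  names(intakes)))
  if (any(intakes$value < 0, na.rm = TRUE)) {
    stop("negative intake value", call. = FALSE)
  }
  win_days <- window[2] - window[1] + 1
  subjects <- intakes |>
    dplyr::filter(.data$postnatal_day >= window[1],
                  .data$postnatal_day <= window[2],
                  !is.na(.data$value)) |>
    dplyr::group_by(.data$subject_id, .data$nutrient) |>
    dplyr::summarise(mean_intake = mean(.data$value),
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(n_missing_days = as.integer(win_days - .data$n_days)) |>
    dplyr::left_join(recommendations[, c("nutrient", "recommendation")],
                     by = "nutrient") |>
    dplyr::mutate(achieved = .data$mean_intake >= .data$recommendation)
  summary <- subjects |>
    dplyr::group_by(.data$nutrient) |>
    dplyr::summarise(
      mean = mean(.data$mean_intake),
      sd = stats::sd(.data$mean_intake),
      n_achieved = sum(.data$achieved, na.rm = TRUE),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_achieved =
                    round_half_up(100 * .data$n_achieved / .data$n_subjects))
  list(subjects = subjects, summary = summary)
}
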