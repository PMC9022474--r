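#' Specify a network-based-statistic analysis
#'
#' One `design_spec` defines a single NBS analysis: the predictor of
#' interest (a two-level group column or a continuous variable such as an
#' IQ score or a mean nutrient intake), nuisance covariates, the contrast
#' direction, the primary component threshold expressed as a target
#' fraction of edges, and the permutation budget.
#'
#' @param mode `"group_contrast"` (two-level predictor) or `"association"`
#'   (continuous predictor).
#' @param predictor Cohort-table column name of the predictor of interest.
#' @param covariates Character vector of nuisance covariate columns
#'   (default `c("age_at_scan", "sex")`).
#' @param direction `"positive"` tests for edges where the predictor
#'   coefficient is positive (in group mode, where the second factor level
#'   exceeds the first); `"negative"` tests the other tail.
#' @param target_edge_fraction Fraction of unique edges retained by the
#'   primary threshold (default 0.01, i.e. ~40 of the 4,005 edges of a
#'   90-region atlas).
#' @param n_permutations Number of permutations (default 5000).
#' @param alpha Significance level for flagging components (default 0.05).
#' @param seed RNG seed for the permutation draw.
#'
#' @return A `design_spec` object.
#' @export
design_spec <- function(mode = c("group_contrast", "association"),
                        predictor,
                        covariates = c("age_at_scan", "sex"),
                        direction = c("positive", "negative"),
                        target_edge_fraction = 0.01,
                        n_permutations = 5000,
                        alpha = 0.05,
                        seed = 1L) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(is.character(predictor), length(predictor) == 1L)
  if (predictor %in% covariates) {
    stop("predictor must not appear among covariates", call. = FALSE)
  }
  if (!(target_edge_fraction > 0 && target_edge_fraction < 1)) {
    stop("target_edge_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (n_permutations < 100) {
    stop("n_permutations must be at least 100", call. = FALSE)
  }
  structure(
    list(mode = mode, predictor = predictor, covariates = covariates,
         direction = direction, target_edge_fraction = target_edge_fraction,
         n_permutations = as.integer(n_permutations), alpha = alpha,
         seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Z-score connectivity edges across participants
#'
#' Stacks a list of per-subject connectivity matrices (same band, same
#' shape) into a subjects x edges matrix over the unique (upper-triangle)
#' edges and standardises each edge across participants to mean 0 and
#' sample SD 1 (denominator `n - 1`). Edges with zero variance are set to
#' all-zero and flagged.
#'
#' @param matrices List of `connectivity_matrix` objects, one per subject.
#'
#' @return An `edge_stack`: list with `z` (subjects x edges matrix),
#'   `edges` (tibble of `i`, `j` index pairs), `flagged` (logical vector of
#'   zero-variance edges), `subject_ids`, `band`, `n_regions`.
#' @export
zscore_edges <- function(matrices) {
  stopifnot(length(matrices) >= 3L)
  stopifnot(all(vapply(matrices, inherits, TRUE, "connectivity_matrix")))
  dims <- vapply(matrices, function(m) nrow(m$values), 1L)
  bands <- vapply(matrices, function(m) m$band$name, "")
  if (length(unique(dims)) != 1L) {
    stop("matrices differ in shape: ", paste(unique(dims), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(bands)) != 1L) {
    stop("matrices differ in band: ", paste(unique(bands), collapse = ", "),
         call. = FALSE)
  }
  n_regions <- dims[1]
  ut <- upper.tri(matrix(0, n_regions, n_regions))
  raw <- do.call(rbind, lapply(matrices, function(m) m$values[ut]))
  mu <- colMeans(raw)
  sdv <- apply(raw, 2, stats::sd)
  flagged <- sdv == 0
  z <- sweep(raw, 2, mu)
  z[, !flagged] <- sweep(z[, !flagged, drop = FALSE], 2, sdv[!flagged], `/`)
  z[, flagged] <- 0
  structure(
    list(z = z, edges = edge_index(n_regions), flagged = flagged,
         subject_ids = vapply(matrices, function(m) m$subject_id, ""),
         band = matrices[[1]]$band, n_regions = n_regions),
    class = "edge_stack"
  )
}

# Build the full-model design matrix and bookkeeping for an NBS GLM.
# Returns X (n x p), the predictor column index, residual df, and the rows
# kept after listwise deletion.
build_design <- function(cohort, design) {
  cols <- c(design$predictor, design$covariates)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(cohort[, cols, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " subject(s) dropped by listwise deletion for '",
            design$predictor, "'")
  }
  dat <- cohort[keep, cols, drop = FALSE]
  pred <- dat[[design$predictor]]
  if (design$mode == "group_contrast") {
    f <- factor(pred)
    if (nlevels(f) != 2L) {
      stop("group_contrast predictor must have exactly 2 levels, got ",
           nlevels(f), call. = FALSE)
    }
    pred_num <- as.numeric(f) - 1  # second level coded 1
  } else {
    if (!is.numeric(pred)) {
      stop("association predictor must be numeric", call. = FALSE)
    }
    pred_num <- pred
  }
  X <- cbind(`(Intercept)` = 1, pred = pred_num)
  colnames(X)[2] <- design$predictor
  for (cv in design$covariates) {
    v <- dat[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) next
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop_idx <- qrx$pivot[(qrx$rank + 1L):ncol(X)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
  }
  list(X = X, pred_col = 2L, df = nrow(X) - ncol(X), keep = keep)
}

# Edge-wise OLS t statistics for the predictor term.
# X: n x p design, Y: n x E response matrix. Returns a length-E vector.
glm_t_edges <- function(X, Y, pred_col) {
  qrx <- qr(X)
  coef <- qr.coef(qrx, Y)                       # p x E
  fitted <- X %*% coef
  rss <- colSums((Y - fitted)^2)
  df <- nrow(X) - ncol(X)
  xtxinv_kk <- chol2inv(qr.R(qrx))[pred_col, pred_col]
  se <- sqrt(pmax(rss, 0) / df * xtxinv_kk)
  t <- coef[pred_col, ] / se
  t[!is.finite(t)] <- 0
  t
}

#' Edge-wise GLM over a z-scored edge stack
#'
#' Fits, at every unique edge, an ordinary-least-squares regression of the
#' z-scored wPLI on an intercept, the predictor of interest and the
#' nuisance covariates, and returns the t statistic of the predictor
#' coefficient. With a binary predictor and no covariates this is exactly
#' the classical pooled-variance two-sample t-test at each edge.
#'
#' @param stack An `edge_stack` from [zscore_edges()].
#' @param cohort Cohort tibble, rows aligned with `stack$subject_ids`.
#' @param design A [design_spec()].
#'
#' @return An `edge_stats`: list with `t_edges` (vector over unique edges),
#'   `t_matrix` (symmetric regions x regions), `df`, `edges`, `design`.
#' @export
edge_glm <- function(stack, cohort, design) {
  stopifnot(inherits(stack, "edge_stack"), inherits(design, "design_spec"))
  if (nrow(cohort) != nrow(stack$z)) {
    stop("cohort rows (", nrow(cohort), ") do not align with stack subjects (",
         nrow(stack$z), ")", call. = FALSE)
  }
  bd <- build_design(cohort, design)
  Y <- stack$z[bd$keep, , drop = FALSE]
  t_edges <- glm_t_edges(bd$X, Y, bd$pred_col)
  n_regions <- stack$n_regions
  tm <- matrix(0, n_regions, n_regions)
  tm[cbind(stack$edges$i, stack$edges$j)] <- t_edges
  tm[cbind(stack$edges$j, stack$edges$i)] <- t_edges
  structure(
    list(t_edges = t_edges, t_matrix = tm, df = bd$df, edges = stack$edges,
         design = design, n_regions = n_regions),
    class = "edge_stats"
  )
}

#' Data-driven primary component threshold
#'
#' Chooses the numeric t threshold as the value of the k-th largest
#' direction-signed edge statistic, with `k = round(target_edge_fraction *
#' n_unique_edges)`, so that approximately that fraction of unique edges is
#' supra-threshold (for a 90-region atlas and the default 1% this is 40 of
#' 4,005 edges). Tied statistics at the cut are all retained, so the
#' supra-threshold count can exceed the target; this is reported via the
#' `n_supra` attribute.
#'
#' @param edge_stats An `edge_stats` from [edge_glm()].
#' @param target_edge_fraction Fraction of edges to retain.
#' @param direction `"positive"` or `"negative"` (default taken from the
#'   design used to build `edge_stats`).
#'
#' @return The numeric threshold on the direction-signed t scale, with
#'   attributes `n_supra` (supra-threshold edge count) and `k` (target).
#' @export
select_threshold <- function(edge_stats,
                             target_edge_fraction = NULL,
                             direction = NULL) {
  stopifnot(inherits(edge_stats, "edge_stats"))
  if (is.null(target_edge_fraction)) {
    target_edge_fraction <- edge_stats$design$target_edge_fraction
  }
  if (is.null(direction)) direction <- edge_stats$design$direction
  signed <- if (direction == "negative") -edge_stats$t_edges
            else edge_stats$t_edges
  signed <- signed[is.finite(signed)]
  if (!length(signed)) stop("no finite edge statistics", call. = FALSE)
  n_edges <- length(signed)
  k <- round(target_edge_fraction * n_edges)
  if (k < 1) {
    warning("fewer unique edges (", n_edges, ") than 1/target_edge_fraction; ",
            "keeping 1 edge", call. = FALSE)
    k <- 1L
  }
  thr <- sort(signed, decreasing = TRUE)[k]
  n_supra <- sum(signed >= thr)
  if (n_supra > k) {
    message("ties at the threshold: ", n_supra, " edges retained (target ",
            k, ")")
  }
  structure(thr, n_supra = n_supra, k = k)
}

#' Connected components of a supra-threshold edge set
#'
#' Forms the undirected graph of supra-threshold edges and returns its
#' connected components, sorted by extent (edge count) descending. The
#' component extent is the NBS test statistic.
#'
#' @param supra_edges Tibble or data frame with columns `i`, `j` of region
#'   index pairs.
#' @param n_regions Total number of regions (for bookkeeping).
#'
#' @return List of components; each is a list with `edges` (tibble `i`,
#'   `j`), `nodes` (sorted integer vector) and `extent` (edge count).
#'   Empty input gives an empty list.
#' @export
extract_components <- function(supra_edges, n_regions = NULL) {
  supra_edges <- tibble::as_tibble(supra_edges)
  if (nrow(supra_edges) == 0L) return(list())
  supra_edges$i <- as.integer(supra_edges$i)
  supra_edges$j <- as.integer(supra_edges$j)
  g <- igraph::graph_from_edgelist(
    cbind(supra_edges$i, supra_edges$j), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[supra_edges$i]
  comps <- lapply(split(seq_len(nrow(supra_edges)), comp_of_edge), function(ix) {
    e <- supra_edges[ix, , drop = FALSE]
    list(edges = e, nodes = sort(unique(c(e$i, e$j))), extent = nrow(e))
  })
  comps <- comps[order(vapply(comps, function(cp) cp$extent, 1L),
                       decreasing = TRUE)]
  names(comps) <- NULL
  comps
}

# Maximum component extent of an edge set, via union-find. Used in the
# permutation inner loop where only the maximum matters.
max_component_extent <- function(ei, ej) {
  m <- length(ei)
  if (m == 0L) return(0L)
  nodes <- unique(c(ei, ej))
  id <- match(c(ei, ej), nodes)
  a <- id[seq_len(m)]
  b <- id[m + seq_len(m)]
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  count <- integer(length(nodes))
  for (e in seq_len(m)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra == rb) {
      count[ra] <- count[ra] + 1L
    } else {
      parent[rb] <- ra
      count[ra] <- count[ra] + count[rb] + 1L
      count[rb] <- 0L
    }
  }
  max(count)
}

# Distinct permutations helper: draw n_permutations row orderings.
draw_permutations <- function(n, n_permutations, seed) {
  with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(k) sample.int(n),
             integer(n)))
  })
}

#' Network-based statistic with permutation FWER control
#'
#' Runs the full NBS: edge-wise GLM with covariates, data-driven primary
#' threshold, connected-component extraction, and a permutation null of
#' maximum component extents from which each observed component receives a
#' family-wise-error-corrected p-value
#' `(1 + #\{null >= extent\}) / (1 + n_permutations)`.
#'
#' The numeric t threshold is fixed from the observed data and re-applied
#' unchanged inside every permutation. The permutation scheme follows the
#' design: with no covariates in group-contrast mode the group labels are
#' permuted directly; whenever covariates are present (or the predictor is
#' continuous) Freedman-Lane permutation is used — residuals of the
#' reduced (covariates-only) model are permuted and added back to the
#' reduced-model fit before the full model is re-estimated — because plain
#' label permutation is not exchangeable under nuisance covariates.
#'
#' @param stack An `edge_stack` from [zscore_edges()].
#' @param cohort Cohort tibble aligned with the stack.
#' @param design A [design_spec()].
#' @param permutations Optional integer matrix (`n_permutations` x n) of
#'   row orderings to use as the permutation set, e.g. an exhaustive
#'   enumeration for small samples; overrides the seeded random draw.
#'
#' @return An `nbs_result`: list with `design`, `edge_stats`, `threshold`,
#'   `components` (each with `p_corrected` and `significant`),
#'   `null_max_extents`, `n_supra`, `seed`.
#' @export
nbs_test <- function(stack, cohort, design, permutations = NULL) {
  stopifnot(inherits(stack, "edge_stack"), inherits(design, "design_spec"))
  if (nrow(cohort) != nrow(stack$z)) {
    stop("cohort rows do not align with stack subjects", call. = FALSE)
  }
  bd <- build_design(cohort, design)
  Y <- stack$z[bd$keep, , drop = FALSE]
  n <- nrow(Y)
  if (n < 6L) {
    stop("too few subjects (", n, ") for permutation inference", call. = FALSE)
  }
  X <- bd$X
  sgn <- if (design$direction == "negative") -1 else 1

  t_obs <- glm_t_edges(X, Y, bd$pred_col)
  es <- structure(
    list(t_edges = t_obs,
         t_matrix = NULL, df = bd$df, edges = stack$edges, design = design,
         n_regions = stack$n_regions),
    class = "edge_stats"
  )
  tm <- matrix(0, stack$n_regions, stack$n_regions)
  tm[cbind(stack$edges$i, stack$edges$j)] <- t_obs
  tm[cbind(stack$edges$j, stack$edges$i)] <- t_obs
  es$t_matrix <- tm

  thr <- select_threshold(es)
  supra <- sgn * t_obs >= as.numeric(thr)
  comps <- extract_components(stack$edges[supra, , drop = FALSE],
                              stack$n_regions)

  if (is.null(permutations)) {
    permutations <- draw_permutations(n, design$n_permutations, design$seed)
  } else {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != n) {
      stop("permutation matrix must have one column per retained subject",
           call. = FALSE)
    }
  }
  n_perm <- nrow(permutations)

  use_fl <- length(design$covariates) > 0 || design$mode == "association"
  ei <- stack$edges$i
  ej <- stack$edges$j
  null_max <- integer(n_perm)

  if (use_fl) {
    X0 <- X[, -bd$pred_col, drop = FALSE]
    qr0 <- qr(X0)
    fitted0 <- X0 %*% qr.coef(qr0, Y)
    resid0 <- Y - fitted0
    for (p in seq_len(n_perm)) {
      Yp <- fitted0 + resid0[permutations[p, ], , drop = FALSE]
      tp <- sgn * glm_t_edges(X, Yp, bd$pred_col)
      sel <- tp >= as.numeric(thr)
      null_max[p] <- max_component_extent(ei[sel], ej[sel])
    }
  } else {
    for (p in seq_len(n_perm)) {
      Xp <- X
      Xp[, bd$pred_col] <- X[permutations[p, ], bd$pred_col]
      tp <- sgn * glm_t_edges(Xp, Y, bd$pred_col)
      sel <- tp >= as.numeric(thr)
      null_max[p] <- max_component_extent(ei[sel], ej[sel])
    }
  }

  comps <- lapply(comps, function(cp) {
    cp$p_corrected <- (1 + sum(null_max >= cp$extent)) / (1 + n_perm)
    cp$significant <- cp$p_corrected <= design$alpha
    cp
  })

  structure(
    list(design = design, edge_stats = es, threshold = as.numeric(thr),
         n_supra = attr(thr, "n_supra"), components = comps,
         null_max_extents = null_max, seed = design$seed),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> ", x$design$mode, " on '", x$design$predictor,
      "' (", x$design$direction, "), band-level NBS\n", sep = "")
  cat("  threshold t = ", signif(x$threshold, 4), " (", x$n_supra,
      " supra-threshold edges), ", length(x$null_max_extents),
      " permutations\n", sep = "")
  if (!length(x$components)) {
    cat("  no supra-threshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cp <- x$components[[k]]
      cat(sprintf("  component %d: %d edges, %d nodes, p_corr = %.4g%s\n",
                  k, cp$extent, length(cp$nodes), cp$p_corrected,
                  if (cp$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Tidy an NBS result into a component table
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `extent`,
#'   `n_nodes`, `p_corrected`, `significant`.
#' @export
tidy.nbs_result <- function(x, ...) {
  if (!length(x$components)) {
    return(tibble::tibble(component = integer(), extent = integer(),
                          n_nodes = integer(), p_corrected = numeric(),
                          significant = logical()))
  }
  tibble::tibble(
    component = seq_along(x$components),
    extent = vapply(x$components, function(cp) cp$extent, 1L),
    n_nodes = vapply(x$components, function(cp) length(cp$nodes), 1L),
    p_corrected = vapply(x$components, function(cp) cp$p_corrected, 1),
    significant = vapply(x$components, function(cp) cp$significant, TRUE)
  )
}

#' One-row summary of an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A one-row tibble: predictor, mode, direction, threshold,
#'   supra-threshold edge count, permutations, number of components,
#'   number significant, smallest corrected p.
#' @export
glance.nbs_result <- function(x, ...) {
  td <- tidy.nbs_result(x)
  tibble::tibble(
    predictor = x$design$predictor,
    mode = x$design$mode,
    direction = x$design$direction,
    threshold = x$threshold,
    n_supra_edges = x$n_supra,
    n_permutations = length(x$null_max_extents),
    n_components = nrow(td),
    n_significant = sum(td$significant),
    min_p_corrected = if (nrow(td)) min(td$p_corrected) else NA_real_
  )
}
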