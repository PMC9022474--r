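# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk.

# A complex tone epoch: analytic signal of cos(2*pi*f*t + phase).
tone_analytic <- function(freq, rate, n, phase = 0) {
  t <- (seq_len(n) - 1) / rate
  exp(1i * (2 * pi * freq * t + phase))
}

# Connectivity matrix with arbitrary (valid) wPLI values.
fake_connectivity <- function(subject_id, n_regions = 8,
                              band = canonical_bands()[2, ], seed = NULL,
                              values = NULL) {
  if (is.null(values)) {
    if (!is.null(seed)) set.seed(seed)
    v <- matrix(0, n_regions, n_regions)
    ut <- upper.tri(v)
    v[ut] <- stats::runif(sum(ut))
    values <- v + t(v)
  }
  structure(
    list(subject_id = subject_id, band = band, values = values,
         n_epochs_used = 5L),
    class = "connectivity_matrix"
  )
}

# Stack of fake connectivity matrices + aligned cohort table.
fake_stack_cohort <- function(n_a = 5, n_b = 5, n_regions = 8, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  ids <- sprintf("S%03d", seq_len(n))
  mats <- lapply(ids, function(id) fake_connectivity(id, n_regions))
  cohort <- tibble::tibble(
    subject_id = ids,
    group = rep(c("A", "B"), c(n_a, n_b)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_at_scan = round(stats::rnorm(n, 5.8, 0.3), 2),
    iq = stats::rnorm(n, 100, 15)
  )
  list(stack = zscore_edges(mats), cohort = cohort, matrices = mats)
}

# Brute-force connected components by breadth-first search; the oracle the
# igraph-backed extractor is checked against.
bfs_components <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  nodes <- sort(unique(c(edges$i, edges$j)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$j[edges$i == v], edges$i[edges$j == v])
  })
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[as.character(v)]) next
    queue <- v
    member <- integer()
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[as.character(u)]) next
      seen[as.character(u)] <- TRUE
      member <- c(member, u)
      queue <- c(queue, adj[[as.character(u)]])
    }
    member <- sort(member)
    in_comp <- edges$i %in% member & edges$j %in% member
    comps[[length(comps) + 1L]] <- list(
      nodes = member,
      edges = edges[in_comp, , drop = FALSE],
      extent = sum(in_comp)
    )
  }
  comps[order(vapply(comps, function(cp) cp$extent, 1L), decreasing = TRUE)]
}

# Small cohort spec used across synthetic-data tests: single alpha band,
# desk-scale sizes.
small_spec <- function(..., seed = 11) {
  args <- list(
    n_group_a = 2, n_group_b = 2, n_regions = 6, sampling_rate = 100,
    epoch_length = 2, n_epochs = 3,
    bands = canonical_bands()[2, , drop = FALSE],
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# Mean planted-edge wPLI over a freshly generated cohort.
planted_edge_wpli <- function(spec, band = "alpha") {
  gc_out <- generate_cohort(spec)
  vals <- vapply(gc_out$series, function(es) {
    cm <- subject_connectivity(band_analytic(es, band))
    mean(cm$values[cbind(spec$planted_edges$i, spec$planted_edges$j)])
  }, 1)
  mean(vals)
}
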