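test_that("edge z-scoring standardises each edge across participants", {
  v1 <- matrix(0, 3, 3); v1[1, 2] <- v1[2, 1] <- 0.1
  v2 <- matrix(0, 3, 3); v2[1, 2] <- v2[2, 1] <- 0.2
  v3 <- matrix(0, 3, 3); v3[1, 2] <- v3[2, 1] <- 0.3
  v1[1, 3] <- v1[3, 1] <- v2[1, 3] <- v2[3, 1] <- v3[1, 3] <- v3[3, 1] <- 0.5
  mats <- list(fake_connectivity("a", values = v1),
               fake_connectivity("b", values = v2),
               fake_connectivity("c", values = v3))
  st <- zscore_edges(mats)
  # edge (1,2) held values {.1,.2,.3} -> z-scores {-1, 0, 1} with sd n-1
  e12 <- which(st$edges$i == 1 & st$edges$j == 2)
  expect_equal(st$z[, e12], c(-1, 0, 1))
  # constant edge -> all zero and flagged
  e13 <- which(st$edges$i == 1 & st$edges$j == 3)
  expect_identical(st$z[, e13], c(0, 0, 0))
  expect_true(st$flagged[e13])
  expect_false(st$flagged[e12])
})

test_that("every unflagged edge has mean 0 and SD 1 after z-scoring", {
  fx <- fake_stack_cohort(6, 6, n_regions = 10, seed = 2)
  z <- fx$stack$z
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, stats::sd) - 1)), 1e-12)
})

test_that("z-scoring rejects mismatched stacks", {
  m1 <- fake_connectivity("a", n_regions = 5, seed = 1)
  m2 <- fake_connectivity("b", n_regions = 6, seed = 2)
  m3 <- fake_connectivity("c", n_regions = 5, seed = 3)
  expect_error(zscore_edges(list(m1, m2, m3)), "shape")
  m4 <- fake_connectivity("d", n_regions = 5, seed = 4,
                          band = canonical_bands()[1, ])
  expect_error(zscore_edges(list(m1, m3, m4)), "band")
})

test_that("edge GLM with binary predictor reproduces the classical two-sample t", {
  fx <- fake_stack_cohort(7, 6, n_regions = 9, seed = 3)
  des <- design_spec("group_contrast", "group", covariates = character(0),
                     n_permutations = 100, seed = 1)
  es <- edge_glm(fx$stack, fx$cohort, des)
  ga <- fx$cohort$group == "A"
  for (e in sample(ncol(fx$stack$z), 8)) {
    y <- fx$stack$z[, e]
    # predictor codes level B as 1, so t is for B minus A
    tt <- stats::t.test(y[!ga], y[ga], var.equal = TRUE)$statistic
    expect_equal(es$t_edges[e], unname(tt), tolerance = 1e-10)
  }
  expect_identical(es$df, 11L)
  expect_true(isSymmetric(es$t_matrix))
})

test_that("edge GLM adjusts for covariates like lm does", {
  fx <- fake_stack_cohort(6, 6, n_regions = 6, seed = 4)
  des <- design_spec("association", "iq", covariates = c("age_at_scan", "sex"),
                     n_permutations = 100, seed = 1)
  es <- edge_glm(fx$stack, fx$cohort, des)
  for (e in c(1, 5, 10)) {
    fit <- stats::lm(fx$stack$z[, e] ~ iq + age_at_scan + sex,
                     data = fx$cohort)
    expect_equal(es$t_edges[e],
                 unname(summary(fit)$coefficients["iq", "t value"]),
                 tolerance = 1e-10)
  }
})

test_that("edge GLM rejects rank-deficient designs naming the column", {
  fx <- fake_stack_cohort(5, 5, n_regions = 6, seed = 5)
  fx$cohort$age_copy <- fx$cohort$age_at_scan
  des <- design_spec("group_contrast", "group",
                     covariates = c("age_at_scan", "age_copy"),
                     n_permutations = 100, seed = 1)
  expect_error(edge_glm(fx$stack, fx$cohort, des),
               "rank deficient.*age_copy")
})

test_that("t statistics are calibrated under a permuted predictor", {
  set.seed(6)
  n <- 60
  z <- matrix(rnorm(n * 500), n)   # 500 independent null edges
  st <- structure(list(z = z, edges = edge_index(50)[1:500, ],
                       flagged = rep(FALSE, 500),
                       subject_ids = sprintf("S%03d", 1:n),
                       band = canonical_bands()[2, ], n_regions = 50),
                  class = c("edge_stack"))
  cohort <- tibble::tibble(subject_id = st$subject_ids,
                           pred = rnorm(n))
  des <- design_spec("association", "pred", covariates = character(0),
                     n_permutations = 100, seed = 1)
  es <- edge_glm(st, cohort, des)
  crit <- stats::qt(0.975, df = es$df)
  frac <- mean(abs(es$t_edges) > crit)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("threshold selection hits the target edge count", {
  # 90 regions at the 1% default: 40 of 4005 edges supra-threshold
  set.seed(7)
  idx <- edge_index(90)
  t_edges <- rnorm(nrow(idx))
  es <- structure(list(t_edges = t_edges, df = 60L, edges = idx,
                       design = design_spec("group_contrast", "group",
                                            seed = 1),
                       n_regions = 90),
                  class = "edge_stats")
  expect_identical(nrow(idx), 4005L)
  thr <- select_threshold(es, 0.01, direction = "positive")
  expect_identical(attr(thr, "n_supra"), 40L)
  expect_identical(sum(t_edges >= as.numeric(thr)), 40L)

  # 6 regions (15 edges) at fraction 0.2 -> 3 edges
  idx6 <- edge_index(6)
  es6 <- structure(list(t_edges = rnorm(15), df = 10L, edges = idx6,
                        design = es$design, n_regions = 6),
                   class = "edge_stats")
  thr6 <- select_threshold(es6, 0.2, direction = "positive")
  expect_identical(attr(thr6, "n_supra"), 3L)

  # all-tied statistics: every tied edge at the cut is kept
  es_tie <- es6
  es_tie$t_edges <- rep(1.5, 15)
  expect_message(thr_tie <- select_threshold(es_tie, 0.2,
                                             direction = "positive"),
                 "ties")
  expect_identical(attr(thr_tie, "n_supra"), 15L)

  # negative direction flips the sign convention
  thr_neg <- select_threshold(es6, 0.2, direction = "negative")
  expect_identical(sum(-es6$t_edges >= as.numeric(thr_neg)), 3L)
})

test_that("component extraction matches the listed examples", {
  comps <- extract_components(tibble::tibble(i = c(1, 2, 4),
                                             j = c(2, 3, 5)))
  expect_length(comps, 2)
  expect_identical(comps[[1]]$extent, 2L)
  expect_identical(comps[[1]]$nodes, c(1L, 2L, 3L))
  expect_identical(comps[[2]]$extent, 1L)
  expect_identical(comps[[2]]$nodes, c(4L, 5L))

  expect_identical(extract_components(tibble::tibble(i = integer(),
                                                     j = integer())),
                   list())

  # a 40-edge path is one component with 41 nodes
  path <- tibble::tibble(i = 1:40, j = 2:41)
  comps <- extract_components(path)
  expect_length(comps, 1)
  expect_identical(comps[[1]]$extent, 40L)
  expect_length(comps[[1]]$nodes, 41)
})

test_that("component extraction agrees with a breadth-first-search oracle", {
  set.seed(8)
  for (rep in 1:300) {
    n_nodes <- sample(3:20, 1)
    n_edges <- sample(1:min(25, n_nodes * (n_nodes - 1) / 2), 1)
    all_pairs <- edge_index(n_nodes)
    edges <- all_pairs[sample(nrow(all_pairs), n_edges), ]
    got <- extract_components(edges)
    want <- bfs_components(edges)
    expect_identical(length(got), length(want))
    expect_identical(lapply(got, function(cp) cp$extent),
                     lapply(want, function(cp) cp$extent))
    # identical node partitions (order by extent can tie; compare as sets)
    got_nodes <- sort(vapply(got, function(cp) paste(cp$nodes, collapse = ","),
                             ""))
    want_nodes <- sort(vapply(want, function(cp) paste(cp$nodes,
                                                       collapse = ","), ""))
    expect_identical(got_nodes, want_nodes)
  }
})

test_that("max-extent helper agrees with full extraction", {
  set.seed(9)
  for (rep in 1:100) {
    n_nodes <- sample(3:15, 1)
    all_pairs <- edge_index(n_nodes)
    n_edges <- sample(0:nrow(all_pairs), 1)
    edges <- all_pairs[sample(nrow(all_pairs), n_edges), ]
    comps <- extract_components(edges)
    want <- if (length(comps)) comps[[1]]$extent else 0L
    expect_identical(phasenet:::max_component_extent(edges$i, edges$j), want)
  }
})

test_that("NBS p-values respect their conventions and determinism", {
  fx <- fake_stack_cohort(6, 6, n_regions = 8, seed = 10)
  des <- design_spec("group_contrast", "group", target_edge_fraction = 0.1,
                     n_permutations = 200, seed = 99)
  res1 <- nbs_test(fx$stack, fx$cohort, des)
  res2 <- nbs_test(fx$stack, fx$cohort, des)
  expect_identical(res1$null_max_extents, res2$null_max_extents)
  expect_identical(tidy(res1), tidy(res2))
  for (cp in res1$components) {
    expect_identical(cp$p_corrected,
                     (1 + sum(res1$null_max_extents >= cp$extent)) / 201)
    expect_gte(cp$p_corrected, 1 / 201)
    expect_lte(cp$p_corrected, 1)
  }
  expect_length(res1$null_max_extents, 200L)
})

test_that("NBS refuses tiny samples", {
  fx <- fake_stack_cohort(3, 2, n_regions = 6, seed = 11)
  des <- design_spec("group_contrast", "group", n_permutations = 100,
                     seed = 1)
  expect_error(nbs_test(fx$stack, fx$cohort, des), "too few subjects")
})

test_that("listwise deletion drops incomplete subjects with a message", {
  fx <- fake_stack_cohort(6, 6, n_regions = 6, seed = 12)
  fx$cohort$iq[c(2, 9)] <- NA
  des <- design_spec("association", "iq", covariates = "age_at_scan",
                     target_edge_fraction = 0.1, n_permutations = 100,
                     seed = 5)
  expect_message(res <- nbs_test(fx$stack, fx$cohort, des),
                 "2 subject\\(s\\) dropped")
  expect_identical(res$edge_stats$df, 7L)  # n=10, p=3 -> df 7
})

test_that("direction reversal preserves the null law on symmetric data", {
  fx <- fake_stack_cohort(8, 8, n_regions = 8, seed = 13)
  des_pos <- design_spec("group_contrast", "group",
                         covariates = character(0),
                         target_edge_fraction = 0.05,
                         n_permutations = 300, seed = 7,
                         direction = "positive")
  des_neg <- design_spec("group_contrast", "group",
                         covariates = character(0),
                         target_edge_fraction = 0.05,
                         n_permutations = 300, seed = 7,
                         direction = "negative")
  res_pos <- nbs_test(fx$stack, fx$cohort, des_pos)
  res_neg <- nbs_test(fx$stack, fx$cohort, des_neg)
  # same null machinery both ways: compare distributions loosely
  expect_lt(abs(mean(res_pos$null_max_extents) -
                  mean(res_neg$null_max_extents)),
            2 * stats::sd(res_pos$null_max_extents))
})
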