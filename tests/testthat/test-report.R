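test_that("node degree follows the handshake lemma on canonical graphs", {
  star <- list(edges = tibble::tibble(i = rep(1L, 5), j = 2:6))
  deg <- node_degree(star)
  expect_identical(deg$degree[deg$region == 1], 5L)
  expect_true(all(deg$degree[deg$region != 1] == 1L))

  path <- list(edges = tibble::tibble(i = c(1L, 2L), j = c(2L, 3L)))
  expect_identical(node_degree(path)$degree, c(1L, 2L, 1L))

  set.seed(1)
  for (rep in 1:20) {
    all_pairs <- edge_index(10)
    edges <- all_pairs[sample(45, sample(1:20, 1)), ]
    cp <- list(edges = edges)
    expect_identical(sum(node_degree(cp)$degree), 2L * nrow(edges))
  }
})

test_that("hub ranking sorts by degree with lexicographic tie-break", {
  deg <- tibble::tibble(region = 1:3, degree = c(3L, 1L, 3L))
  atlas <- tibble::tibble(region = 1:3, label = c("A", "B", "C"),
                          x = 0, y = 0, z = 0)
  hubs <- identify_hubs(deg, top_k = 2, atlas = atlas)
  expect_identical(hubs$label, c("A", "C"))

  # single node, and top_k beyond the map size
  one <- identify_hubs(tibble::tibble(region = 5L, degree = 2L), top_k = 3)
  expect_identical(nrow(one), 1L)
  full <- identify_hubs(deg, top_k = 99, atlas = atlas)
  expect_identical(nrow(full), 3L)
  expect_error(identify_hubs(deg, top_k = 0), "at least 1")
})

test_that("the packaged atlas has 90 unique labelled regions", {
  atlas <- load_atlas()
  expect_identical(nrow(atlas), 90L)
  expect_identical(anyDuplicated(atlas$label), 0L)
  expect_true(all(is.finite(atlas$x + atlas$y + atlas$z)))
})

test_that("BrainNet export writes degrees as node sizes and round-trips", {
  atlas <- load_atlas()
  comp <- list(edges = tibble::tibble(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)),
               nodes = 1:3, extent = 3L)
  node_path <- withr::local_tempfile(fileext = ".node")
  edge_path <- withr::local_tempfile(fileext = ".edge")
  out <- export_brainnet(comp, atlas, node_path, edge_path)

  back <- read_brainnet(node_path, edge_path)
  expect_identical(dim(back$edge), c(90L, 90L))
  expect_identical(back$edge, out$edge)
  expect_equal(back$node$size, out$node$size)
  expect_identical(back$node$label, atlas$label)

  deg <- node_degree(comp)
  expect_equal(back$node$size[deg$region], as.numeric(deg$degree))
  # non-member regions have size 0
  expect_true(all(back$node$size[-(1:3)] == 0))

  # a 2-node single-edge component gives exactly two symmetric cells
  comp2 <- list(edges = tibble::tibble(i = 7L, j = 9L), nodes = c(7L, 9L),
                extent = 1L)
  out2 <- export_brainnet(comp2, atlas, node_path, edge_path)
  expect_identical(sum(out2$edge != 0), 2L)
  expect_identical(out2$edge[7, 9], 1)
  expect_identical(out2$edge[9, 7], 1)

  # unknown region is refused
  comp_bad <- list(edges = tibble::tibble(i = 1L, j = 91L),
                   nodes = c(1L, 91L), extent = 1L)
  expect_error(export_brainnet(comp_bad, atlas, node_path, edge_path),
               "does not cover")
})

test_that("demographic dispatch reproduces the sex chi-square of 0.95", {
  # 16 M : 21 F in one group against 15 M : 12 F in the other
  cohort <- tibble::tibble(
    group = rep(c("A", "B"), c(37, 27)),
    sex = c(rep("M", 16), rep("F", 21), rep("M", 15), rep("F", 12))
  )
  rep_out <- compare_demographics(
    cohort, tibble::tibble(variable = "sex", type = "categorical"))
  expect_identical(rep_out$test, "chi-square")
  expect_identical(rep_out$df, 1)
  expect_equal(round(rep_out$statistic, 2), 0.95)
  expect_equal(rep_out$p_value, 0.33, tolerance = 0.01)
})

test_that("a 2x3 contingency table gets the standard chi-square with 2 df", {
  counts <- matrix(c(10, 23, 4, 0, 15, 12), nrow = 2, byrow = TRUE)
  cohort <- tibble::tibble(
    group = rep(rep(c("A", "B"), c(37, 27))),
    edu = c(rep(c("high_school", "university", "postgrad"), counts[1, ]),
            rep(c("high_school", "university", "postgrad"), counts[2, ]))
  )
  rep_out <- compare_demographics(
    cohort, tibble::tibble(variable = "edu", type = "categorical"))
  # oracle: direct sum((O-E)^2/E) over the table
  tab <- table(cohort$group, cohort$edu)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  expect_identical(rep_out$df, 2)
  expect_equal(rep_out$statistic, chi2, tolerance = 1e-12)
})

test_that("continuous dispatch follows Shapiro-Wilk and formats accordingly", {
  set.seed(14)
  cohort <- tibble::tibble(
    group = rep(c("A", "B"), each = 25),
    normal_var = rnorm(50, 10, 2),
    skewed_var = exp(rnorm(50, 0, 1.2))
  )
  rep_out <- compare_demographics(
    cohort,
    tibble::tibble(variable = c("normal_var", "skewed_var"),
                   type = "continuous"))
  expect_identical(rep_out$test[1], "t-test")
  expect_match(rep_out$summary_a[1], "±")
  expect_identical(rep_out$test[2], "mann-whitney")
  expect_match(rep_out$summary_a[2], "\\{")

  # the dispatch is a pure function of the Shapiro outcomes: re-running
  # gives the same choices
  rep2 <- compare_demographics(
    cohort,
    tibble::tibble(variable = c("normal_var", "skewed_var"),
                   type = "continuous"))
  expect_identical(rep_out$test, rep2$test)

  # identical groups: t branch returns p = 1
  cohort$same <- rep(rnorm(25, 10, 1), 2)
  rep3 <- compare_demographics(
    cohort, tibble::tibble(variable = "same", type = "continuous"))
  if (rep3$test == "t-test") expect_equal(rep3$p_value, 1)

  # groups that are too small are skipped with a warning
  cohort_small <- tibble::tibble(group = c("A", "A", "B", "B", "B"),
                                 v = c(1, 2, 3, 4, 5))
  expect_warning(
    out <- compare_demographics(
      cohort_small, tibble::tibble(variable = "v", type = "continuous")),
    "fewer than 3")
  expect_identical(nrow(out), 0L)
})

test_that("intake summaries average days 9-29 and flag achievement", {
  # constant 3.6 g/kg/day protein: mean 3.6, achieved against 3.5
  intakes <- tidyr::expand_grid(subject_id = "S001", postnatal_day = 1:29,
                                nutrient = "protein")
  intakes$value <- 3.6
  out <- summarize_intake(intakes)
  expect_equal(out$subjects$mean_intake, 3.6)
  expect_true(out$subjects$achieved)
  expect_identical(out$subjects$n_days, 21L)

  # values outside the window never change the mean
  intakes2 <- intakes
  intakes2$value[intakes2$postnatal_day <= 8] <- 0
  out2 <- summarize_intake(intakes2)
  expect_identical(out2$subjects$mean_intake, out$subjects$mean_intake)
  intakes3 <- intakes[intakes$postnatal_day >= 9, ]
  out3 <- summarize_intake(intakes3)
  expect_identical(out3$subjects$mean_intake, out$subjects$mean_intake)

  # missing days inside the window are excluded and counted
  intakes4 <- intakes[!(intakes$postnatal_day %in% c(10, 11)), ]
  out4 <- summarize_intake(intakes4)
  expect_identical(out4$subjects$n_missing_days, 2L)

  expect_error(summarize_intake(dplyr::mutate(intakes, value = -1)),
               "negative")
})

test_that("achievement percentages round half away from zero: 24 of 37 is 65%", {
  intakes <- tidyr::expand_grid(subject_id = sprintf("S%03d", 1:37),
                                postnatal_day = 9:29, nutrient = "protein")
  # 24 achievers at 3.6, 13 below at 3.0
  intakes$value <- ifelse(intakes$subject_id %in% sprintf("S%03d", 1:24),
                          3.6, 3.0)
  out <- summarize_intake(intakes)
  expect_identical(out$summary$n_achieved, 24L)
  expect_identical(out$summary$n_subjects, 37L)
  expect_identical(out$summary$pct_achieved, 65)
})
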