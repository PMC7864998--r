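test_that("group assembly pools inter-grader and grader-model distances", {
  # 3 graders x 200 scans -> 600 distances in each group
  scans <- sprintf("s%03d", 1:200)
  big <- make_table(do.call(rbind, lapply(scans, function(s)
    data.frame(scan_id = s,
               grading_a = c("g1", "g1", "g2", "g1", "g2", "g3"),
               grading_b = c("g2", "g3", "g3", "cnn", "cnn", "cnn"),
               scope = "all", distance = 0.01, stringsAsFactors = FALSE))))
  g <- assemble_groups(big, c("g1", "g2", "g3"), "cnn")
  expect_length(g$group_a, 600L)
  expect_length(g$group_b, 600L)

  # 2 graders, 10 scans -> |A| = 10, |B| = 20
  small <- make_table(do.call(rbind, lapply(1:10, function(i)
    data.frame(scan_id = paste0("s", i),
               grading_a = c("g1", "g1", "g2"),
               grading_b = c("g2", "cnn", "cnn"),
               scope = "all", distance = c(0.5, 0.1, 0.2),
               stringsAsFactors = FALSE))))
  g2 <- assemble_groups(small, c("g1", "g2"), "cnn")
  expect_length(g2$group_a, 10L)
  expect_length(g2$group_b, 20L)
  expect_equal(sort(unique(g2$group_a)), 0.5)
  expect_equal(sort(unique(g2$group_b)), c(0.1, 0.2))

  # exact multiset for a 2-scan toy table
  toy <- make_table(data.frame(
    scan_id = rep(c("a", "b"), each = 3),
    grading_a = rep(c("g1", "g1", "g2"), 2),
    grading_b = rep(c("g2", "cnn", "cnn"), 2),
    scope = "all", distance = c(1, 2, 3, 4, 5, 6) / 10,
    stringsAsFactors = FALSE))
  gt <- assemble_groups(toy, c("g1", "g2"), "cnn")
  expect_equal(sort(gt$group_a), c(0.1, 0.4))
  expect_equal(sort(gt$group_b), c(0.2, 0.3, 0.5, 0.6))

  expect_error(assemble_groups(toy, c("g1", "g3"), "cnn"), "no all-scope")
})

test_that("exhaustive enumeration yields exact p-values", {
  # {0} vs {1}: both splits tie or exceed -> two-sided p = 1
  r <- exhaustive_permutation_test(list(group_a = 0, group_b = 1))
  expect_equal(r$n_resamples, 2L)
  expect_equal(r$p_two_sided, 1.0)

  # {1,2,3} vs {4,5,6}: observed -3 is the unique minimum of 20 splits
  r2 <- exhaustive_permutation_test(list(group_a = 1:3, group_b = 4:6))
  expect_equal(r2$n_resamples, 20L)
  expect_equal(r2$p_lower, 1 / 20)
  expect_equal(r2$p_two_sided, 2 / 20)

  r3 <- exhaustive_permutation_test(list(group_a = c(1, 2), group_b = c(1, 2)))
  expect_equal(r3$p_two_sided, 1.0)

  expect_error(exhaustive_permutation_test(
    list(group_a = 1:30, group_b = 1:30)), "enumeration bound")
})

test_that("Monte-Carlo p-values agree with the exhaustive oracle", {
  g <- list(group_a = c(1, 2, 3), group_b = c(4, 5, 6))
  exact <- exhaustive_permutation_test(g)
  B <- 20000L
  mc <- mc_permutation_test(g, n_resamples = B, seed = 42)
  se <- sqrt(exact$p_lower * (1 - exact$p_lower) / B)
  expect_lt(abs(mc$p_lower - exact$p_lower), 3 * se + 2 / B)

  # a non-degenerate overlapping configuration
  g2 <- list(group_a = c(0.1, 0.5, 0.4, 0.9), group_b = c(0.3, 0.2, 0.8))
  exact2 <- exhaustive_permutation_test(g2)
  mc2 <- mc_permutation_test(g2, n_resamples = B, seed = 7)
  for (side in c("p_lower", "p_upper")) {
    se2 <- sqrt(exact2[[side]] * (1 - exact2[[side]]) / B)
    expect_lt(abs(mc2[[side]] - exact2[[side]]), 3 * se2 + 2 / B)
  }
})

test_that("degenerate equal groups give the capped p of 1 and determinism holds", {
  g <- list(group_a = rep(0.02, 5), group_b = rep(0.02, 7))
  r <- mc_permutation_test(g, n_resamples = 999, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_two_sided, 1.0)

  g2 <- list(group_a = c(0.1, 0.3, 0.2), group_b = c(0.25, 0.15))
  r1 <- mc_permutation_test(g2, n_resamples = 2999, seed = 11)
  r2 <- mc_permutation_test(g2, n_resamples = 2999, seed = 11)
  expect_identical(r1$p_two_sided, r2$p_two_sided)
  expect_error(mc_permutation_test(list(group_a = numeric(), group_b = 1)),
               "non-empty")
})

test_that("p floor is 2/(B+1) and the 99% CI contains the p-value", {
  # widely separated groups: zero exceedances in the smaller tail
  a <- trex:::local_seed(1, rnorm(60, 100, 1))
  b <- trex:::local_seed(2, rnorm(60, 0, 1))
  r <- mc_permutation_test(list(group_a = a, group_b = b),
                           n_resamples = 999, seed = 5)
  expect_equal(r$p_two_sided, 2 / 1000)
  expect_equal(r$exceed_count, 0L)
  expect_equal(r$ci99[1], 0)
  expect_gte(r$p_two_sided, r$ci99[1])
  # CI convention covers the attainable floor
  expect_lte(r$p_two_sided, r$ci99[2] + 2 / 1000)

  g2 <- list(group_a = c(0.1, 0.5, 0.4, 0.9), group_b = c(0.3, 0.2, 0.8))
  r2 <- mc_permutation_test(g2, n_resamples = 999, seed = 3)
  expect_gte(r2$p_two_sided, r2$ci99[1])
  expect_lte(r2$p_two_sided, r2$ci99[2])
})

test_that("type-I error under exchangeable groups is calibrated at 5%", {
  n_sim <- 2000L
  B <- 199L
  rejections <- trex:::local_seed(2024, {
    sum(vapply(seq_len(n_sim), function(i) {
      pool <- rnorm(16)
      g <- list(group_a = pool[1:8], group_b = pool[9:16])
      mc_permutation_test(g, n_resamples = B,
                          seed = sample.int(2^30, 1))$p_two_sided <= 0.05
    }, logical(1)))
  })
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rejections / n_sim - 0.05), 3 * se)
})

test_that("boxplot summaries follow the strict IQR whisker rule", {
  s <- boxplot_summary(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  expect_length(s$outliers, 0L)

  s2 <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(s2$upper_whisker, 4)
  expect_equal(s2$outliers, 100)

  s3 <- boxplot_summary(rep(7, 4))
  expect_equal(unlist(s3[c("q1", "median", "q3", "mean",
                           "lower_whisker", "upper_whisker")]),
               rep(7, 6), ignore_attr = TRUE)
  expect_length(s3$outliers, 0L)

  expect_error(boxplot_summary(numeric()), "non-empty")
})

test_that("permutation results serialize to JSON with all fields", {
  r <- mc_permutation_test(list(group_a = c(1, 2, 3), group_b = c(2, 3, 4),
                                scope = "all"),
                           n_resamples = 499, seed = 9)
  path <- tempfile(fileext = ".json")
  permutation_result_json(r, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$scope, "all")
  expect_equal(j$n_resamples, 499L)
  expect_equal(j$p_two_sided, r$p_two_sided)
  expect_length(j$ci99, 2L)
  expect_equal(j$seed, 9L)
})
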