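# Densitometry normalizations and group statistics. The t and F routes are
# cross-checked against R's stats implementations as independent oracles.

test_that("ratios, fold changes and compartment percentages", {
  expect_equal(normalized_ratio(2.0, 1.0), 2.0)
  expect_equal(normalized_ratio(3, 2), 1.5)
  expect_equal(normalized_ratio(5, 5), 1.0)
  expect_error(normalized_ratio(1, 0), "positive")
  expect_error(normalized_ratio(-1, 2), "positive")

  v <- c(1, 1, 2, 2); g <- c("wt", "wt", "ko", "ko")
  expect_equal(fold_change(v, g, "wt"), c(1, 1, 2, 2))
  expect_equal(fold_change(rep(3, 4), g, "ko"), rep(1, 4))
  expect_error(fold_change(v, g, "absent"), "absent")

  expect_equal(compartment_percentages(c(2, 1, 1)), c(50, 25, 25))
  expect_equal(compartment_percentages(7), 100)
  set.seed(1)
  r <- compartment_percentages(runif(6) + 0.01)
  expect_equal(sum(r), 100, tolerance = 1e-9)
  expect_error(compartment_percentages(c(0, 0)), "zero")
})

test_that("unpaired t-test matches stats::t.test in both variants", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  ours <- unpaired_t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$statistic, -1.095445, tolerance = 1e-6)

  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = 2)
    ow <- unpaired_t_test(x, y, var_equal = FALSE)
    rw <- t.test(x, y)
    expect_equal(ow$statistic, unname(rw$statistic), tolerance = 1e-12)
    expect_equal(ow$df, unname(rw$parameter), tolerance = 1e-9)
    expect_equal(ow$p, rw$p.value, tolerance = 1e-12)
  }
})

test_that("t-test conventions: identical samples, shifts, errors", {
  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_message(zv <- unpaired_t_test(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(c(zv$statistic, zv$p), c(0, 1))
  expect_error(unpaired_t_test(c(2, 2), c(3, 3)), "zero variance")

  a <- c(1.2, 3.4, 2.2, 4.8); b <- c(2.5, 3.1, 4.4, 1.1)
  base <- unpaired_t_test(a, b)
  shifted <- unpaired_t_test(a + 100, b + 100)
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-9)
  expect_equal(shifted$p, base$p, tolerance = 1e-9)
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA matches anova(lm) and Sidak behaves", {
  set.seed(11)
  v <- rnorm(24); g <- rep(c("a", "b", "c"), each = 8)
  ours <- one_way_anova_sidak(v, g)
  ref <- anova(lm(v ~ g))
  expect_equal(ours$anova$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(ours$anova$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(c(ours$anova$df1, ours$anova$df2), c(2, 21))

  # equal group means, nonzero variance: F = 0, p = 1
  flat <- one_way_anova_sidak(rep(c(1, 3), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(flat$anova$F, 0)
  expect_equal(flat$anova$p, 1)

  # Sidak identity at m = 1 and monotonicity in m
  one <- one_way_anova_sidak(v, g, comparisons = list(c("a", "b")))
  expect_equal(one$comparisons$p_adj, one$comparisons$p)
  all3 <- one_way_anova_sidak(v, g)
  ab <- all3$comparisons[all3$comparisons$comparison == "a vs b", ]
  expect_gte(ab$p_adj, ab$p)
  expect_gte(ab$p_adj, one$comparisons$p_adj)

  bon <- one_way_anova_sidak(v, g, adjust = "bonferroni")
  expect_equal(bon$comparisons$p_adj, pmin(1, 3 * bon$comparisons$p))

  expect_error(one_way_anova_sidak(v, rep("a", 24)), "2 groups")
  expect_error(one_way_anova_sidak(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
  expect_error(one_way_anova_sidak(v, g, comparisons = list(c("a", "zz"))),
               "bad comparison")
})

test_that("pairwise Sidak p-values derive from the pooled within-group t", {
  set.seed(12)
  v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  res <- one_way_anova_sidak(v, g, comparisons = list(c("a", "c")))
  # oracle: recompute from first principles
  ms_within <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / 15
  tstat <- (mean(v[g == "a"]) - mean(v[g == "c"])) /
    sqrt(ms_within * (1 / 6 + 1 / 6))
  expect_equal(res$comparisons$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$comparisons$p, 2 * pt(-abs(tstat), 15), tolerance = 1e-12)
})

test_that("band analysis wires ratios, folds and tests together", {
  tab <- generate_band_table(c(wt = 1, ko = 1.8), n_lanes = 5,
                             noise_sd = 0.08, seed = 3)
  res <- analyze_bands(tab, control = "wt", test = "t")
  expect_identical(nrow(res$stats), 1L)
  expect_match(res$stats$comparison, "wt vs ko")
  wt_mean <- mean(res$per_lane$fold_change[res$per_lane$group == "wt"])
  expect_equal(wt_mean, 1, tolerance = 1e-12)

  res2 <- analyze_bands(tab, control = "wt", test = "anova")
  expect_true(is.list(res2$stats))
  expect_identical(nrow(res2$stats$comparisons), 1L)

  tab$marker2 <- tab$marker * 2
  r3 <- analyze_bands(tab, control = "wt", mode = "marker_ratio")
  expect_equal(unique(round(r3$per_lane$ratio, 12)), 2)
})
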