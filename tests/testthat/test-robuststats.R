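test_that("BFB matches Eq.-style closed form and its printed pairs", {
  expect_equal(as.numeric(bfb(exp(-1))), 1, tolerance = 1e-12)
  # printed pairs, truncation-tolerant at two decimals
  pairs <- cbind(p = c(0.005, 0.001, 0.003, 0.006, 0.17),
                 printed = c(13.88, 53.25, 21.11, 11.98, 1.22))
  for (i in seq_len(nrow(pairs))) {
    expect_lt(abs(trunc(as.numeric(bfb(pairs[i, 1])) * 100) / 100 -
                    pairs[i, 2]), 0.01 + 1e-9)
  }
  expect_identical(attr(bfb(0.5), "direction"), "favors H_0")
  expect_identical(attr(bfb(0.01), "direction"), "favors H_a")
  expect_error(bfb(0), "strictly")
  expect_error(bfb(1), "strictly")
})

test_that("BFB is strictly decreasing and continuous on (0, 1/e)", {
  grid <- seq(1e-6, exp(-1) - 1e-6, length.out = 500)
  vals <- as.numeric(bfb(grid))
  expect_true(all(diff(vals) < 0))
  expect_true(all(is.finite(vals)))
  expect_identical(significance_label(c(0.004, 0.02, 0.2)),
                   c("significant", "suggestive", "not significant"))
})

test_that("biweight midvariance matches direct evaluation and is consistent", {
  # independent hand evaluation of the formula for {-1, 0, 1}:
  # M = 0, MAD = 1, u = x/9, all |u| < 1
  x <- c(-1, 0, 1)
  u <- x / 9
  oracle <- 3 * sum(x^2 * (1 - u^2)^4) / sum((1 - u^2) * (1 - 5 * u^2))^2
  expect_equal(biweight_midvariance(x), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.7012, tolerance = 1e-4)

  expect_warning(v0 <- biweight_midvariance(rep(3, 10)), "MAD")
  expect_equal(v0, 0)

  set.seed(1)
  g <- rnorm(1e5)
  expect_lt(abs(biweight_midvariance(g) - 1), 0.05)
  expect_error(biweight_midvariance(1), "n >= 2")
})

test_that("normality gate routes Gaussian and exponential samples", {
  param <- vapply(1:20, function(s) {
    set.seed(s)
    normality_gate(rnorm(200))$parametric
  }, logical(1))
  expect_gte(mean(param), 0.8)

  robust <- vapply(1:20, function(s) {
    set.seed(s)
    !normality_gate(rexp(200))$parametric
  }, logical(1))
  expect_equal(mean(robust), 1)

  expect_error(normality_gate(rep(1, 20)), "degenerate")
  expect_error(normality_gate(rnorm(2)), "3 <= n")
})

test_that("group difference test gates correctly and matches oracles", {
  set.seed(2)
  x <- rnorm(60)
  same <- group_difference_test(c(x, x), rep(c("a", "b"), each = 60))
  expect_equal(same$statistic, 0, tolerance = 1e-10)
  expect_gt(same$p, 0.95)

  # normal branch reduces to classic ANOVA
  set.seed(3)
  vals <- c(rnorm(50), rnorm(50, mean = 3))
  grp <- rep(c("a", "b"), each = 50)
  r <- group_difference_test(vals, grp)
  expect_identical(r$statistic_name, "F")
  a <- anova(lm(vals ~ factor(grp)))
  expect_equal(r$p, a$`Pr(>F)`[1], tolerance = 1e-10)
  expect_lt(r$p, 0.005)

  # non-normal branch: Kruskal-Wallis against brute-force rank evaluation
  set.seed(4)
  ev <- c(rexp(40), rexp(40) + 1, rexp(40))
  eg <- rep(c("a", "b", "c"), each = 40)
  rk <- group_difference_test(ev, eg)
  expect_identical(rk$statistic_name, "chi-squared")
  rr <- rank(ev)
  n <- length(ev)
  h_brute <- 12 / (n * (n + 1)) *
    sum(tapply(rr, eg, function(z) length(z) * mean(z)^2)) - 3 * (n + 1)
  expect_equal(unname(rk$statistic), h_brute, tolerance = 1e-10)

  expect_error(group_difference_test(1:5, c("a", "a", "a", "a", "b")),
               "n >= 2")
})

test_that("multivariate test matches the manova oracle and handles gates", {
  set.seed(5)
  Y <- matrix(rnorm(240), 80, 3)
  g <- rep(c("a", "b"), each = 40)
  Y[g == "b", ] <- Y[g == "b", ] + 1.2

  for (stat in c("Wilks", "Hotelling-Lawley")) {
    r <- multivariate_test(Y, g, statistic = stat)
    o <- summary(manova(Y ~ g), test = stat)$stats
    expect_equal(unname(r$statistic), o[1, 2], tolerance = 1e-10)
    expect_equal(r$p, o[1, 6], tolerance = 1e-10)
  }

  # identical groups: Lambda = 1, p ~ 1
  set.seed(6)
  Z <- matrix(rnorm(120), 40, 3)
  dup <- rbind(Z, Z)
  rid <- multivariate_test(dup, rep(c("a", "b"), each = 40),
                           statistic = "Wilks")
  expect_equal(unname(rid$statistic), 1, tolerance = 1e-10)
  expect_gt(rid$p, 0.99)

  # strong separation in 5 dims is decisive
  set.seed(7)
  Y5 <- rbind(matrix(rnorm(80 * 5), 80, 5),
              sweep(matrix(rnorm(80 * 5), 80, 5), 2, rep(4 / sqrt(5), 5),
                    `+`))
  r5 <- multivariate_test(Y5, rep(c("a", "b"), each = 80))
  expect_lte(r5$p, 0.001)

  expect_error(multivariate_test(matrix(rnorm(18), 6, 3),
                                 rep(c("a", "b"), each = 3)), "n > number")
})

test_that("pairwise multivariate comparisons cover all pairs", {
  set.seed(8)
  Y <- matrix(rnorm(360), 120, 3)
  g <- rep(c("a", "b", "c"), each = 40)
  tab <- pairwise_multivariate_test(Y, g, statistic = "Wilks")
  expect_equal(nrow(tab), 3)
  tab_bh <- pairwise_multivariate_test(Y, g, statistic = "Wilks",
                                       adjust = "BH")
  expect_true(all(tab_bh$p_adjusted >= tab_bh$p))
})

test_that("robust equivalence behaves across regimes", {
  set.seed(9)
  a <- rnorm(2000)
  same <- robust_equivalence(a, a, margin = 0.2)
  expect_equal(same$d_abs, 0)
  expect_lt(same$p, 1e-6)

  # same distribution at n = 2000 (the TOST margin is ~5 standard errors;
  # at n = 500 the margin is < 2.6 se and equivalence is undecidable)
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    robust_equivalence(rnorm(2000), rnorm(2000), margin = 0.2)$p <= 0.005
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # a 1-sd shift is never declared equivalent at margin 0.2
  miss <- vapply(1:10, function(s) {
    set.seed(s)
    robust_equivalence(rnorm(300), rnorm(300, 1), margin = 0.2)$p > 0.005
  }, logical(1))
  expect_equal(mean(miss), 1)

  expect_error(robust_equivalence(rnorm(5), rnorm(50)), "n >= 10")
  expect_error(robust_equivalence(rnorm(50), rnorm(50), margin = 0),
               "margin")
})
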