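test_that("Shapiro-Wilk separates normal from exponential samples", {
  set.seed(1)
  expect_gt(shapiroWilk(stats::rnorm(500))$p, 0.01)
  expect_lt(shapiroWilk(stats::rexp(500))$p, 0.01)
  const <- shapiroWilk(rep(2, 10))
  expect_true(const$degenerate)
  expect_equal(const$p, 0)
  expect_error(shapiroWilk(c(1, 2)), "3 <= n")
})

test_that("signed-rank test handles degenerate and all-positive cases", {
  eq <- wilcoxonSignedRank(1:8, 1:8)
  expect_true(eq$degenerate)
  expect_equal(eq$p, 1)
  # n = 6, all differences positive: extreme rank sum, p = 2/2^6
  res <- wilcoxonSignedRank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p, 2 / 2^6)
  expect_identical(res$method, "exact")
})

test_that("exact signed-rank p matches exhaustive sign-flip enumeration", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    d <- round(stats::rnorm(n, sd = 3), 1)
    d[d == 0] <- 0.5
    # include ties in |d| regularly
    if (i %% 3 == 0 && n > 3) d[2] <- -d[1]
    got <- wilcoxonSignedRank(d, rep(0, n))
    expect_equal(got$p, enumSignedRankP(d), tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the base implementation when tie-free", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(c(8, 12, 20), 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    ours <- wilcoxonSignedRank(a, b)
    base <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, unname(base$p.value), tolerance = 1e-10)
    expect_equal(ours$statistic, unname(base$statistic))
  }
  # large-n path: normal approximation with continuity correction
  set.seed(56)
  a <- stats::rnorm(60); b <- stats::rnorm(60)
  ours <- wilcoxonSignedRank(a, b)
  base <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_identical(ours$method, "normal")
  expect_equal(ours$p, unname(base$p.value), tolerance = 1e-8)
})

test_that("spearman reproduces hand-computed and monotone cases", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  # x=(1,2,3,4), y=(1,3,2,4): d^2 = (0,1,1,0), rho = 1 - 6*2/(4*15)
  r <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_true(spearman(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman(1:2, 1:2), "at least 3")
  # p-value via the t approximation
  set.seed(8)
  x <- stats::rnorm(30); y <- x + stats::rnorm(30)
  got <- spearman(x, y)
  tt <- got$rho * sqrt(28 / (1 - got$rho^2))
  expect_equal(got$p, 2 * stats::pt(abs(tt), 28, lower.tail = FALSE))
})

test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(30)
  for (i in 1:50) {
    p <- stats::runif(sample(2:12, 1))
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # permutation invariance: adjusted values follow their p-values
    perm <- sample(seq_along(p))
    expect_equal(bhAdjust(p[perm]), adj[perm])
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("variant comparisons pair cases and share one BH family", {
  mk <- function(delta, n = 30) {
    base <- stats::runif(n, 0.3, 0.5)
    rbind(
      data.frame(case_id = sprintf("c%02d", 1:n), sequence = "T1w",
                 variant = "unprocessed", class_name = "tumor",
                 dsc = base, ref_volume_cm3 = 1, pred_volume_cm3 = 1),
      data.frame(case_id = sprintf("c%02d", 1:n), sequence = "T1w",
                 variant = "inverted_black", class_name = "tumor",
                 dsc = base + delta, ref_volume_cm3 = 1,
                 pred_volume_cm3 = 1))
  }
  set.seed(9)
  same <- mk(0)
  res <- compareVariants(same,
                         pairs = list(c("unprocessed", "inverted_black")),
                         level = "tumor")
  expect_true(res$degenerate)
  expect_equal(res$p_raw, 1)
  shifted <- mk(0.2)
  res2 <- compareVariants(shifted,
                          pairs = list(c("unprocessed", "inverted_black")),
                          level = "tumor")
  expect_lt(res2$p_raw, 0.001)
  expect_true(all(res2$p_adjusted >= res2$p_raw))
  # unmatched cases are an explicit error naming the cases
  broken <- shifted[-1, ]
  expect_error(compareVariants(
    broken, pairs = list(c("unprocessed", "inverted_black")),
    level = "tumor"), "c01")
})
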