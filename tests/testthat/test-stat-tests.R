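test_that("McNemar exact branch doubles the smaller binomial tail, capped at 1", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(10, 0)$p_value, 2 * 0.5^10)
  # spot-check against direct enumeration (full sweep lives in the
  # acceptance suite)
  for (bc in list(c(3, 7), c(0, 12), c(12, 13), c(1, 20))) {
    expect_equal(mcnemar_test(bc[1], bc[2])$p_value,
                 enumerate_mcnemar_p(bc[1], bc[2]))
  }
})

test_that("McNemar large-sample branch matches the corrected chi-square", {
  res <- mcnemar_test(40, 20)
  expect_equal(res$statistic, (abs(40 - 20) - 1)^2 / 60)
  expect_equal(res$p_value, pchisq((19)^2 / 60, 1, lower.tail = FALSE))
  ref <- stats::mcnemar.test(matrix(c(5, 20, 40, 5), 2, 2))
  expect_equal(res$p_value, ref$p.value)
})

test_that("McNemar with no discordant pairs is degenerate with p = 1", {
  res <- mcnemar_test(0, 0)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("chi-square equals the definitional sum and the reference implementation", {
  same <- matrix(c(10, 20, 10, 20), 2, 2)  # identical rows
  res <- chi2_rxc(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(6)
  for (i in 1:50) {
    m <- matrix(sample(1:30, 6, replace = TRUE), 2, 3)
    res <- chi2_rxc(m)
    # brute-force cell-by-cell
    stat <- 0
    for (r in 1:2) for (cc in 1:3) {
      e <- sum(m[r, ]) * sum(m[, cc]) / sum(m)
      stat <- stat + (m[r, cc] - e)^2 / e
    }
    expect_equal(res$statistic, stat)
    expect_identical(res$df, 2L)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
  expect_error(chi2_rxc(matrix(c(0, 0, 3, 4), 2, 2)), "zero marginal")
  expect_error(chi2_rxc(matrix(1:3, 1)), "at least 2x2")
})

test_that("Yates-corrected 2x2 chi-square matches the reference", {
  m <- matrix(c(12, 5, 7, 15), 2, 2)
  expect_equal(chi2_rxc(m, yates = TRUE)$statistic,
               unname(stats::chisq.test(m, correct = TRUE)$statistic))
  expect_error(chi2_rxc(matrix(1:6, 2, 3), yates = TRUE), "2x2")
})

test_that("rank-sum statistic matches exhaustive enumeration and ref p-values", {
  # complete separation of {1,2,3} vs {4,5,6}: U of x is the enumeration
  # minimum, 0
  res <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  dist <- enumerate_u_distribution(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, min(dist))
  expect_identical(length(dist), 20L)

  set.seed(7)
  for (i in 1:10) {
    x <- sample(1:6, 4, replace = TRUE)  # ties across and within groups
    y <- sample(2:8, 4, replace = TRUE)
    res <- wilcoxon_ranksum(x, y)
    r <- rank(c(x, y))
    expect_equal(res$statistic, sum(r[1:4]) - 4 * 5 / 2)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic))
    if (!res$degenerate) expect_equal(res$p_value, ref$p.value)
  }
})

test_that("rank-sum degenerate and identical-sample cases", {
  expect_equal(wilcoxon_ranksum(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_true(wilcoxon_ranksum(c(2, 2, 2), c(2, 2))$degenerate)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(wilcoxon_ranksum(x, x)$p_value, 1)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "nonempty")
})

test_that("severely affected endovascular-like NIHSS values separate from the rest", {
  # generated severity scores with medians 18 vs 5, at cohort-like sizes
  set.seed(8)
  endo <- pmin(42, round(rlnorm(31, log(18), 0.4)))
  rest <- pmin(42, round(rlnorm(618, log(5), 0.8)))
  expect_lt(wilcoxon_ranksum(endo, rest)$p_value, 0.001)
})

test_that("Welch t: reference agreement, pooled-t limit, degenerate input", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  res <- welch_t(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p_value, ref$p.value)

  expect_equal(welch_t(x, x)$statistic, 0)
  expect_equal(welch_t(x, x)$p_value, 1)

  # equal n, equal sample variance: Welch collapses to the pooled t exactly
  y2 <- x + 1
  res2 <- welch_t(x, y2)
  pooled <- stats::t.test(x, y2, var.equal = TRUE)
  expect_equal(res2$statistic, unname(pooled$statistic))
  expect_equal(res2$df, unname(pooled$parameter))

  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Welch t from published age summaries gives p near 0.11", {
  res <- welch_t_summary(65.9, 18.3, 121, 68.8, 14.7, 528)
  expect_lt(abs(res$p_value - 0.11), 0.01)
})
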