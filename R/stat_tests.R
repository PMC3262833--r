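# Hypothesis tests used in the cohort evaluation: McNemar's paired test,
# Pearson r x c chi-square, Wilcoxon rank-sum with tie-corrected normal
# approximation, and the Welch t test (raw-data and summary-statistic forms).

test_result <- function(statistic, df, p_value, method, degenerate = FALSE) {
  structure(
    list(statistic = statistic, df = df,
         p_value = min(max(p_value, 0), 1),
         method = method, degenerate = degenerate),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g%s, p = %.4g%s\n", x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(" (df %.3g)", x$df) else "",
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' McNemar's test for paired binary classifications
#'
#' Operates on the two discordant counts of a paired 2x2 table. When
#' b + c <= `exact_max` the exact two-sided binomial p-value is used
#' (double the smaller tail of Binomial(b + c, 1/2), capped at 1);
#' otherwise the continuity-corrected chi-square statistic
#' (|b - c| - 1)^2 / (b + c) on 1 df. When b + c = 0 the test is degenerate
#' and p = 1.
#'
#' @param b,c the two discordant counts.
#' @param exact_max largest b + c for which the exact branch is used
#'   (default 25).
#' @return a `test_result`.
#' @export
mcnemar_test <- function(b, c, exact_max = 25) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  n <- b + c
  if (n == 0)
    return(test_result(NA_real_, NA_integer_, 1, "McNemar (degenerate)",
                       degenerate = TRUE))
  if (n <= exact_max) {
    k <- min(b, c)
    p <- 2 * stats::pbinom(k, n, 0.5)
    return(test_result(as.numeric(k), NA_integer_, p, "McNemar exact binomial"))
  }
  stat <- (abs(b - c) - 1)^2 / n
  test_result(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
              "McNemar chi-square (continuity corrected)")
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction for general r x c tables; for 2x2 tables the
#' Yates correction can be requested.
#'
#' @param table numeric matrix of counts, at least 2x2.
#' @param yates apply the Yates continuity correction (2x2 only).
#' @return a `test_result` with df = (r-1)(c-1).
#' @export
chi2_rxc <- function(table, yates = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("table must be at least 2x2")
  if (any(m < 0)) stop("negative counts")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal row or column")
  expected <- outer(rs, cs) / n
  if (yates) {
    if (!all(dim(m) == c(2, 2))) stop("Yates correction applies to 2x2 tables only")
    stat <- sum((abs(m - expected) - 0.5)^2 / expected)
  } else {
    stat <- sum((m - expected)^2 / expected)
  }
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              sprintf("Pearson chi-square%s", if (yates) " (Yates)" else ""))
}

#' Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Midranks are assigned to ties; the reported statistic is the
#' Mann--Whitney U of `x` (rank sum of `x` minus n1(n1+1)/2). The two-sided
#' p-value uses the normal approximation with tie-corrected variance
#' n1 n2 / 12 * (N + 1 - sum(t^3 - t) / (N (N - 1))), without continuity
#' correction. If every value across both groups is identical the test is
#' degenerate with p = 1.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return a `test_result`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0)
    return(test_result(u, NA_integer_, 1, "Wilcoxon rank-sum (degenerate)",
                       degenerate = TRUE))
  z <- (u - n1 * n2 / 2) / sqrt(v)
  test_result(u, NA_integer_, 2 * stats::pnorm(-abs(z)),
              "Wilcoxon rank-sum (normal approximation)")
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return a `test_result`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  welch_t_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y))
}

#' Welch t test from summary statistics
#'
#' Same test as [welch_t()] but computed from group means, standard
#' deviations and sizes, as needed when only published summaries are
#' available.
#'
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y group summaries.
#' @return a `test_result`.
#' @export
welch_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y) {
  stopifnot(n_x >= 2, n_y >= 2)
  vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
  if (vx + vy == 0) stop("zero variance in both groups")
  stat <- (mean_x - mean_y) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  test_result(stat, df, 2 * stats::pt(-abs(stat), df), "Welch two-sample t")
}
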