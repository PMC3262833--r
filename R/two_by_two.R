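# 2x2 classification-vs-outcome tables, diagnostic metrics, odds ratios.
#
# Row convention: rows are predicted MAJOR / NONMAJOR, columns are poor /
# good outcome, so tp = MAJOR & poor, fp = MAJOR & good, fn = NONMAJOR &
# poor, tn = NONMAJOR & good.

#' Construct a 2x2 classification-vs-outcome table
#'
#' @param tp,fp,fn,tn non-negative integer counts (predicted-major & poor,
#'   predicted-major & good, predicted-nonmajor & poor, predicted-nonmajor &
#'   good).
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- stats::setNames(as.integer(counts), c("tp", "fp", "fn", "tn"))
  structure(as.list(counts), n = sum(counts), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("MAJOR", "NONMAJOR"), c("poor", "good")))
  print(m)
  invisible(x)
}

#' Cross-tabulate predictions against outcomes
#'
#' @param predicted_major logical vector (instrument says MAJOR).
#' @param poor_outcome logical vector (6-month mRS > 2).
#' @return a [two_by_two()].
#' @export
confusion <- function(predicted_major, poor_outcome) {
  if (length(predicted_major) != length(poor_outcome))
    stop("length mismatch between predictions and outcomes")
  if (length(predicted_major) == 0) stop("empty input")
  if (any(is.na(predicted_major)) || any(is.na(poor_outcome)))
    stop("missing values in predictions or outcomes")
  two_by_two(
    tp = sum(predicted_major & poor_outcome),
    fp = sum(predicted_major & !poor_outcome),
    fn = sum(!predicted_major & poor_outcome),
    tn = sum(!predicted_major & !poor_outcome)
  )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return c(lower, upper); `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Diagnostic metrics of a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
#' NPV tn/(tn+fn), accuracy (tp+tn)/n, each with a two-sided Wilson score
#' confidence interval. A metric whose denominator is zero is flagged
#' undefined (`defined = FALSE`) rather than raising an error. On counts the
#' identity accuracy = prevalence * sensitivity + (1 - prevalence) *
#' specificity holds exactly.
#'
#' @param t a [two_by_two()].
#' @param conf confidence level for the Wilson intervals.
#' @return data.frame with columns metric, numerator, denominator, estimate,
#'   lower, upper, defined.
#' @export
diagnostic_metrics <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  num <- c(sensitivity = t$tp, specificity = t$tn, ppv = t$tp,
           npv = t$tn, accuracy = t$tp + t$tn)
  den <- c(sensitivity = t$tp + t$fn, specificity = t$tn + t$fp,
           ppv = t$tp + t$fp, npv = t$tn + t$fn, accuracy = attr(t, "n"))
  est <- ifelse(den > 0, num / den, NA_real_)
  ci <- t(mapply(wilson_ci, num, den, MoreArgs = list(conf = conf)))
  data.frame(
    metric = names(num),
    numerator = as.integer(num),
    denominator = as.integer(den),
    estimate = as.numeric(est),
    lower = as.numeric(ci[, 1]),
    upper = as.numeric(ci[, 2]),
    defined = den > 0,
    row.names = NULL
  )
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' OR = (tp * tn) / (fp * fn); the 95% interval is exp(log OR +/- z * se)
#' with se = sqrt(1/tp + 1/fp + 1/fn + 1/tn) and z = 1.96 at the default
#' level. If any cell is zero, 0.5 is added to all four cells
#' (Haldane--Anscombe) and the result is flagged `corrected`.
#'
#' @param t a [two_by_two()].
#' @param conf confidence level.
#' @return object of class `or_result`: list(estimate, ci_low, ci_high,
#'   log_se, corrected).
#' @export
odds_ratio <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$tp, t$fp, t$fn, t$tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  log_se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(
    list(estimate = or,
         ci_low = exp(log(or) - z * log_se),
         ci_high = exp(log(or) + z * log_se),
         log_se = log_se,
         corrected = corrected),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f to %.2f)%s\n", x$estimate, x$ci_low,
              x$ci_high, if (x$corrected) " [0.5 cell correction]" else ""))
  invisible(x)
}
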