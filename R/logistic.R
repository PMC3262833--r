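# Maximum-likelihood logistic regression via iteratively reweighted least
# squares, a likelihood-ratio test, and stepwise (forward/backward) variable
# selection -- the machinery behind the forced-entry and stepwise
# multivariate outcome models.

# log(1 + exp(eta)) without overflow
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

logistic_loglik <- function(eta, y) sum(y * eta - log1pexp(eta))

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood fit of P(y = 1) = logit^-1(b0 + X b). Convergence is
#' declared when the log-likelihood changes by less than `tol` (default
#' 1e-8) between iterations, up to `max_iter` iterations. Complete
#' separation (coefficients diverging past `beta_max` on the linear scale)
#' and exact collinearity of the design are reported as errors.
#'
#' @param x numeric matrix or data.frame of predictors (no intercept column;
#'   one is added). Column names label the coefficients.
#' @param y logical or 0/1 outcome vector.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum IRLS iterations.
#' @param beta_max divergence threshold for separation detection.
#' @return object of class `logistic_fit`: coefficients, standard errors,
#'   per-predictor odds ratios (exp of each coefficient), log-likelihood,
#'   convergence flag, iterations used, gradient norm at the optimum, n.
#' @export
logistic_fit <- function(x, y, tol = 1e-8, max_iter = 100, beta_max = 15) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be logical or 0/1")
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)")
  if (length(unique(y)) < 2) stop("constant outcome")
  X <- cbind(`(Intercept)` = 1, x)
  if (qr(X)$rank < ncol(X)) stop("collinear predictors (design not full rank)")

  beta <- rep(0, ncol(X))
  ll <- logistic_loglik(drop(X %*% beta), y)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    beta_new <- drop(solve(XtWX, crossprod(X, w * z)))
    if (any(!is.finite(beta_new)) || max(abs(beta_new)) > beta_max)
      stop("complete separation detected (diverging coefficients)")
    ll_new <- logistic_loglik(drop(X %*% beta_new), y)
    beta <- beta_new
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  info <- crossprod(X, X * w)
  se <- sqrt(diag(solve(info)))
  grad <- drop(crossprod(X, y - mu))

  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)),
         odds_ratios = stats::setNames(exp(beta), colnames(X)),
         loglik = ll,
         converged = converged,
         iterations = iter,
         gradient_norm = sqrt(sum(grad^2)),
         n = length(y)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.3f, %d IRLS iteration(s)%s)\n",
              x$n, x$loglik, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  print(data.frame(coef = x$coefficients, se = x$se, OR = x$odds_ratios))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param fit_full,fit_reduced `logistic_fit` objects on the same data, the
#'   reduced model nested in the full one.
#' @param df degrees of freedom of the comparison (default: difference in
#'   number of coefficients).
#' @return a `test_result`.
#' @export
lr_test <- function(fit_full, fit_reduced, df = NULL) {
  stopifnot(inherits(fit_full, "logistic_fit"), inherits(fit_reduced, "logistic_fit"),
            fit_full$n == fit_reduced$n)
  if (is.null(df))
    df <- length(fit_full$coefficients) - length(fit_reduced$coefficients)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              "likelihood-ratio test")
}

#' Stepwise logistic regression by likelihood-ratio tests
#'
#' Alternating forward selection (best candidate enters if its LR p-value is
#' below `p_enter`) and backward elimination (worst included predictor is
#' removed if its LR p-value exceeds `p_remove`), iterated to a fixpoint.
#' Every add/drop is recorded with its p-value in the selection trace.
#'
#' @param candidates numeric matrix or data.frame of candidate predictors
#'   with column names.
#' @param y logical or 0/1 outcome.
#' @param p_enter p-to-enter threshold (default 0.05).
#' @param p_remove p-to-remove threshold (default 0.10).
#' @param max_steps safety cap on the number of add/drop steps.
#' @param ... passed to [logistic_fit()].
#' @return list with `fit` (the final `logistic_fit`; intercept-only when
#'   nothing enters), `selected` (character vector of retained predictors)
#'   and `trace` (data.frame: step, action, variable, p_value).
#' @export
stepwise_logistic <- function(candidates, y, p_enter = 0.05, p_remove = 0.10,
                              max_steps = 50, ...) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates))) stop("candidates must have column names")
  vars <- colnames(candidates)
  fit_on <- function(sel) {
    if (length(sel) == 0) {
      # intercept-only: closed form, logit of the outcome mean
      p <- mean(y)
      eta <- rep(stats::qlogis(p), length(y))
      structure(list(coefficients = c(`(Intercept)` = stats::qlogis(p)),
                     se = c(`(Intercept)` = 1 / sqrt(length(y) * p * (1 - p))),
                     odds_ratios = c(`(Intercept)` = p / (1 - p)),
                     loglik = logistic_loglik(eta, as.numeric(y)),
                     converged = TRUE, iterations = 0L,
                     gradient_norm = 0, n = length(y)),
                class = "logistic_fit")
    } else {
      logistic_fit(candidates[, sel, drop = FALSE], y, ...)
    }
  }

  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), p_value = numeric(0))
  current <- fit_on(selected)
  step <- 0
  repeat {
    changed <- FALSE
    # forward
    pool <- setdiff(vars, selected)
    if (length(pool) > 0) {
      ps <- vapply(pool, function(v) {
        lr_test(fit_on(c(selected, v)), current)$p_value
      }, numeric(1))
      if (min(ps) < p_enter) {
        v <- pool[which.min(ps)]
        selected <- c(selected, v)
        current <- fit_on(selected)
        step <- step + 1
        trace <- rbind(trace, data.frame(step = step, action = "add",
                                         variable = v, p_value = min(ps)))
        changed <- TRUE
      }
    }
    # backward
    if (length(selected) > 0) {
      ps <- vapply(selected, function(v) {
        lr_test(current, fit_on(setdiff(selected, v)))$p_value
      }, numeric(1))
      if (max(ps) > p_remove) {
        v <- selected[which.max(ps)]
        selected <- setdiff(selected, v)
        current <- fit_on(selected)
        step <- step + 1
        trace <- rbind(trace, data.frame(step = step, action = "drop",
                                         variable = v, p_value = max(ps)))
        changed <- TRUE
      }
    }
    if (!changed || step >= max_steps) break
  }
  list(fit = current, selected = selected, trace = trace)
}
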