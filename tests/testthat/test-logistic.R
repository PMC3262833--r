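test_that("single binary predictor: slope equals the log sample odds ratio", {
  set.seed(10)
  x <- rbinom(300, 1, 0.4)
  y <- rbinom(300, 1, plogis(-0.5 + 1.2 * x))
  fit <- logistic_fit(matrix(x, dimnames = list(NULL, "x")), y)
  tab <- table(x, y)
  sample_or <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(unname(fit$coefficients["x"]), log(sample_or), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-4)
})

test_that("intercept-only model recovers the logit of the outcome mean", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- logistic_fit(matrix(numeric(0), nrow = 100, ncol = 0), y)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.3), tolerance = 1e-8)
})

test_that("IRLS matches the reference fitter on coefficients, SEs and loglik", {
  set.seed(11)
  d <- data.frame(a = rnorm(400), b = rbinom(400, 1, 0.5), c = runif(400))
  y <- rbinom(400, 1, plogis(-1 + 0.8 * d$a - 0.5 * d$b))
  fit <- logistic_fit(d, y)
  ref <- stats::glm(y ~ a + b + c, data = d, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$odds_ratios), unname(exp(coef(ref))), tolerance = 1e-6)
})

test_that("degenerate designs raise explicit errors", {
  set.seed(12)
  x <- rnorm(50)
  expect_error(logistic_fit(cbind(x = x), rep(1, 50)), "constant outcome")
  expect_error(logistic_fit(cbind(x = x, x2 = 2 * x), rbinom(50, 1, 0.5)),
               "collinear")
  y_sep <- as.numeric(x > 0)
  expect_error(logistic_fit(cbind(x = x), y_sep), "separation")
})

test_that("synthetic-cohort fit recovers the generating coefficients", {
  params <- default_params(n = 5000, seed = 13)
  cl <- classify_cohort(generate_cohort(params))
  X <- cbind(nihss_major = as.numeric(cl$nihss_class == "MAJOR"),
             basis_major = as.numeric(cl$basis_class == "MAJOR"),
             age_centered = cl$age - params$age_mean)
  fit <- logistic_fit(X, cl$poor_outcome)
  truth <- c(params$outcome$intercept, params$outcome$beta_nihss_major,
             params$outcome$beta_basis_major, params$outcome$beta_age)
  expect_true(all(abs(fit$coefficients - truth) <= 3 * fit$se))
})

test_that("stepwise keeps a strong predictor, drops pure noise, records a trace", {
  set.seed(14)
  n <- 2000
  cand <- cbind(strong = rbinom(n, 1, 0.5), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * cand[, "strong"]))
  sw <- stepwise_logistic(cand, y)
  expect_identical(sw$selected, "strong")
  expect_identical(sw$trace$action[1], "add")
  expect_identical(sw$trace$variable[1], "strong")
  expect_lt(sw$trace$p_value[1], 0.05)
})

test_that("stepwise returns the intercept-only model when nothing enters", {
  set.seed(15)
  cand <- cbind(junk1 = rnorm(100), junk2 = rnorm(100))
  y <- rbinom(100, 1, 0.5)
  sw <- stepwise_logistic(cand, y)
  expect_identical(sw$selected, character(0))
  expect_identical(names(sw$fit$coefficients), "(Intercept)")
  expect_equal(unname(sw$fit$coefficients[1]), qlogis(mean(y)))
})

test_that("likelihood-ratio test is chi-square on the deviance difference", {
  set.seed(16)
  d <- data.frame(a = rnorm(200), b = rnorm(200))
  y <- rbinom(200, 1, plogis(0.7 * d$a))
  full <- logistic_fit(d, y)
  red <- logistic_fit(d[, "a", drop = FALSE], y)
  res <- lr_test(full, red)
  ref_full <- stats::glm(y ~ a + b, data = d, family = binomial())
  ref_red <- stats::glm(y ~ a, data = d, family = binomial())
  ref <- stats::anova(ref_red, ref_full, test = "LRT")
  expect_equal(res$statistic, ref$Deviance[2], tolerance = 1e-6)
  expect_equal(res$p_value, ref$`Pr(>Chi)`[2], tolerance = 1e-6)
})
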