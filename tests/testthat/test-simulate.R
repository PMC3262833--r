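test_that("default parameters validate and carry the analytic calibration", {
  p <- default_params()
  expect_true(validate_params(p))
  expect_identical(p$n, 649L)

  # expected BASIS-major fraction, computed analytically from the params
  exp_basis <- p$p_occlusion + (1 - p$p_occlusion) *
    (1 - (1 - p$p_aspects_major_nonoccluded) *
       (1 - p$p_bilateral_pons) * (1 - p$p_bilateral_thalamus))
  expect_lt(abs(exp_basis - 249 / 649), 0.02)

  # expected poor-outcome fraction from the stratum mixture the outcome
  # coefficients were solved against
  p10_minor <- 1 - pnorm(log(10.5 / p$nihss_median_minor) / p$nihss_sigma_minor)
  p10_major <- 1 - pnorm(log(10.5 / p$nihss_median_major) / p$nihss_sigma_major)
  pB <- p$targets[["basis_major_rate"]]
  w <- c(cm = pB * p10_major, cn = (1 - pB) * (1 - p10_minor),
         d1 = (1 - pB) * p10_minor, d2 = pB * (1 - p10_major))
  f <- function(x) integrate(function(z)
    plogis(x + p$outcome$beta_age * p$age_sd * z) * dnorm(z), -8, 8)$value
  oc <- p$outcome
  exp_poor <- w[["cm"]] * f(oc$intercept + oc$beta_nihss_major + oc$beta_basis_major) +
    w[["cn"]] * f(oc$intercept) +
    w[["d1"]] * f(oc$intercept + oc$beta_nihss_major) +
    w[["d2"]] * f(oc$intercept + oc$beta_basis_major)
  expect_lt(abs(exp_poor - 253 / 649), 0.02)
})

test_that("invalid parameters are rejected", {
  p <- default_params()
  p$p_occlusion <- 1.2
  expect_error(validate_params(p), "probability")
  p <- default_params()
  p$site_weights <- c(DISTAL_ICA = 0.5, MCA_M1 = 0.2, MCA_M2 = 0.2, BASILAR = 0.2)
  expect_error(validate_params(p), "sum to 1")
  p <- default_params()
  p$n <- -1L
  expect_error(generate_cohort(p))
})

test_that("generation is deterministic under a seed and varies across seeds", {
  p <- default_params(n = 200, seed = 17)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(default_params(n = 200, seed = 18))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  # the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_cohort(default_params(n = 20, seed = 1)))
  expect_identical(runif(1), before)
})

test_that("n = 0 yields an empty cohort", {
  co <- generate_cohort(default_params(n = 0))
  expect_identical(nrow(co), 0L)
  expect_s3_class(co, "cohort_table")
})

test_that("generated records always satisfy the record invariants", {
  for (seed in c(21, 22, 23)) {
    co <- generate_cohort(default_params(n = 400, seed = seed))
    # re-validation in strict mode must not drop anything
    revalidated <- cohort_table(as.data.frame(co), strict = TRUE)
    expect_identical(nrow(revalidated), 400L)
    expect_true(all(co$nihss_admission >= 0 & co$nihss_admission <= 42))
    expect_true(all(co$mrs_6mo %in% 0:6))
    expect_true(all(co$age > 0))
    expect_false(any(duplicated(co$patient_id)))
  }
})

test_that("calibration report covers every target and handles tiny cohorts", {
  p <- default_params(n = 10, seed = 24)
  rep <- calibration_report(generate_cohort(p), p)
  expect_setequal(
    setdiff(rep$target, "nihss_major_and_occlusion_rate"),
    names(p$targets))
  expect_true(all(is.finite(rep$tolerance[!is.na(rep$within)]) |
                    rep$n[!is.na(rep$within)] == 0))
  # the published-count conflict row is informational only
  expect_true(is.na(rep$within[rep$target == "nihss_major_and_occlusion_rate"]))
})

test_that("a deliberately broken occlusion rate is flagged out of tolerance", {
  p <- default_params(n = 2000, seed = 25)
  p$p_occlusion <- 0
  rep <- calibration_report(generate_cohort(p), p)
  expect_false(rep$within[rep$target == "basis_major_rate"])
  expect_false(rep$within[rep$target == "occlusion_rate"])
})
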