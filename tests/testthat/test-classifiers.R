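test_that("ASPECTS score deducts one point per distinct hypodense region", {
  expect_identical(aspects_score(fnd()), 10L)
  expect_identical(aspects_score(fnd(regions = c("I", "M1c", "M2c"))), 7L)
  expect_identical(aspects_score(fnd(regions = ASPECTS_REGIONS)), 0L)
  # posterior flags and occlusions are ignored by ASPECTS
  expect_identical(aspects_score(fnd(sites = "BASILAR", pons = TRUE, thal = TRUE)), 10L)
})

test_that("ASPECTS dichotomy cuts at score <= 7", {
  expect_identical(classify_aspects(fnd(regions = c("I", "M1c", "M2c"))), "MAJOR")
  expect_identical(classify_aspects(fnd(regions = c("I", "M1c"))), "NONMAJOR")
  expect_identical(classify_aspects(fnd()), "NONMAJOR")
})

test_that("BASIS is major on qualifying occlusion, parenchymal or posterior criteria", {
  expect_identical(classify_basis(fnd(sites = "MCA_M1")), "MAJOR")
  expect_identical(classify_basis(fnd(sites = "MCA_M2")), "MAJOR")
  expect_identical(classify_basis(fnd(sites = "DISTAL_ICA")), "MAJOR")
  expect_identical(classify_basis(fnd(sites = "BASILAR")), "MAJOR")
  expect_identical(classify_basis(fnd(sites = "OTHER")), "NONMAJOR")
  expect_identical(classify_basis(fnd(regions = c("C", "L", "IC"))), "MAJOR")
  expect_identical(classify_basis(fnd(pons = TRUE)), "MAJOR")
  expect_identical(classify_basis(fnd(thal = TRUE)), "MAJOR")
  expect_identical(classify_basis(fnd()), "NONMAJOR")
})

test_that("NIHSS dichotomy is strictly greater than 10", {
  expect_identical(classify_nihss(10L), "NONMAJOR")
  expect_identical(classify_nihss(11L), "MAJOR")
  expect_identical(classify_nihss(0L), "NONMAJOR")
  expect_identical(classify_nihss(c(5L, 42L)), c("NONMAJOR", "MAJOR"))
  expect_error(classify_nihss(43L), "range")
  expect_error(classify_nihss(-1L), "range")
  expect_error(classify_nihss(NA_integer_), "missing")
})

test_that("combined classes map concordance and discordance correctly", {
  expect_identical(classify_combined("MAJOR", "MAJOR"), "CONCORDANT_MAJOR")
  expect_identical(classify_combined("NONMAJOR", "NONMAJOR"), "CONCORDANT_MINOR")
  expect_identical(classify_combined("MAJOR", "NONMAJOR"), "DISCORDANT")
  expect_identical(classify_combined("NONMAJOR", "MAJOR"), "DISCORDANT")
  expect_error(classify_combined("MAJOR", "maybe"))
})

test_that("classify_cohort appends consistent per-patient classes", {
  cl <- classify_cohort(make_small_cohort())
  expect_identical(cl$aspects_score, c(6L, 10L, 10L, 10L, 8L, 10L))
  expect_identical(cl$basis_class,
                   c("MAJOR", "NONMAJOR", "MAJOR", "NONMAJOR", "NONMAJOR", "NONMAJOR"))
  expect_identical(cl$poor_outcome, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))

  # empty cohort classifies to an empty result
  empty <- classify_cohort(generate_cohort(default_params(n = 0)))
  expect_identical(nrow(empty), 0L)

  # missing mRS is the caller's problem
  df <- make_small_cohort_df()
  df$mrs_6mo[1] <- NA_integer_
  expect_error(classify_cohort(cohort_table(df)), "exclude_unanalyzable")
})

test_that("cohort-level invariants: subset, partition, outcome dichotomy", {
  cl <- classify_cohort(generate_cohort(default_params(n = 500, seed = 9)))
  expect_lte(sum(cl$aspects_class == "MAJOR"), sum(cl$basis_class == "MAJOR"))
  expect_true(all(cl$aspects_class != "MAJOR" | cl$basis_class == "MAJOR"))
  expect_identical(sum(table(cl$combined_class)), 500L)
  expect_identical(cl$poor_outcome, cl$mrs_6mo > 2L)
  # vectorized cohort path agrees with the per-record classifiers
  for (i in sample.int(nrow(cl), 20)) {
    f <- fnd(sites = strsplit(cl$occlusion_sites[i], ";")[[1]],
             regions = strsplit(cl$anterior_hypodense_regions[i], ";")[[1]],
             pons = cl$bilateral_pons_hypodensity[i],
             thal = cl$bilateral_thalamus_hypodensity[i])
    expect_identical(cl$aspects_score[i], aspects_score(f))
    expect_identical(cl$basis_class[i], classify_basis(f))
    expect_identical(cl$aspects_class[i], classify_aspects(f))
  }
})

test_that("BASIS is monotone under added findings (spot check)", {
  set.seed(4)
  for (rep in 1:50) {
    regions <- sample(ASPECTS_REGIONS, sample(0:9, 1))
    sites <- sample(OCCLUSION_SITES, sample(0:2, 1))
    f <- fnd(sites = sites, regions = regions)
    if (classify_basis(f) == "MAJOR") {
      extra_r <- sample(setdiff(ASPECTS_REGIONS, regions), 1)
      expect_identical(classify_basis(fnd(sites, c(regions, extra_r))), "MAJOR")
      expect_identical(classify_basis(fnd(union(sites, "MCA_M1"), regions)), "MAJOR")
    }
  }
})
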