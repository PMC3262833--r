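# Shared fixtures built in code.

# A small handcrafted cohort covering the main record shapes: occlusions,
# parenchymal-only findings, posterior flags, a pure-minor stroke, a death.
make_small_cohort_df <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3", "A4", "A5", "A6"),
    age = c(70.5, 55, 81.2, 64, 77, 49.9),
    sex = c("male", "female", "female", "male", "male", "female"),
    nihss_admission = c(18L, 4L, 22L, 2L, 9L, 0L),
    diabetes = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    cad = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    atrial_fibrillation = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    smoking = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    hyperlipidemia = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    hypertension = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    iv_tpa = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    ia_therapy = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    occlusion_sites = c("MCA_M1", "", "BASILAR;OTHER", "OTHER", "", ""),
    anterior_hypodense_regions = c("I;M1c;M2c;M3c", "", "", "", "C;L", ""),
    bilateral_pons_hypodensity = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    bilateral_thalamus_hypodensity = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    mrs_6mo = c(5L, 1L, 6L, 0L, 3L, 2L),
    stringsAsFactors = FALSE
  )
}

make_small_cohort <- function() {
  cohort_table(make_small_cohort_df(), provenance = "handcrafted test cohort")
}

# cohort columns without provenance/bookkeeping attributes, for equality
cohort_fields <- function(co) {
  df <- as.data.frame(co)
  attr(df, "provenance") <- NULL
  attr(df, "dropped") <- NULL
  df
}

# findings shortcut
fnd <- function(sites = character(0), regions = character(0),
                pons = FALSE, thal = FALSE) {
  imaging_findings(occlusion_sites = sites,
                   anterior_hypodense_regions = regions,
                   bilateral_pons_hypodensity = pons,
                   bilateral_thalamus_hypodensity = thal)
}

# random 2x2 with strictly positive cells
random_positive_table <- function(max_cell = 50) {
  two_by_two(sample.int(max_cell, 1), sample.int(max_cell, 1),
             sample.int(max_cell, 1), sample.int(max_cell, 1))
}

# exact two-sided McNemar p by direct binomial enumeration with choose()
enumerate_mcnemar_p <- function(b, c) {
  n <- b + c
  k <- min(b, c)
  tail <- sum(choose(n, 0:k)) * 0.5^n
  min(1, 2 * tail)
}

# exhaustive-permutation null distribution of the Mann-Whitney U of group 1
enumerate_u_distribution <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  idx <- utils::combn(length(r), n1)
  apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
}
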