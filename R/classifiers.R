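# Severity classification instruments: ASPECTS, BASIS, dichotomized NIHSS,
# and the combined NIHSS/BASIS scheme.
#
# Each instrument dichotomizes a stroke as MAJOR vs NONMAJOR:
#   * ASPECTS: early ischemic change in >= 3 of the 10 anterior regions,
#     i.e. ASPECTS score <= 7.
#   * BASIS: qualifying arterial occlusion on CTA (distal ICA, M1/M2, basilar)
#     OR the anterior parenchymal criterion (ASPECTS <= 7) OR, for the
#     posterior circulation, bilateral pons or bilateral thalamus hypodensity.
#   * NIHSS: admission score strictly greater than 10.

MAJOR <- "MAJOR"
NONMAJOR <- "NONMAJOR"
COMBINED_LEVELS <- c("CONCORDANT_MAJOR", "DISCORDANT", "CONCORDANT_MINOR")

as_class <- function(major) ifelse(major, MAJOR, NONMAJOR)

#' ASPECTS score from coded imaging findings
#'
#' Ten minus the number of distinct hypodense anterior (ASPECTS) regions.
#' Posterior-circulation flags and occlusion sites are ignored; a pure
#' posterior stroke with no anterior involvement scores 10.
#'
#' @param findings an [imaging_findings()] object.
#' @return integer score in 0..10.
#' @export
aspects_score <- function(findings) {
  stopifnot(inherits(findings, "imaging_findings"))
  10L - length(unique(findings$anterior_hypodense_regions))
}

#' Classify a stroke by ASPECTS
#'
#' MAJOR iff the ASPECTS score is 7 or less (hypodensity in 3 or more
#' regions).
#'
#' @inheritParams aspects_score
#' @return `"MAJOR"` or `"NONMAJOR"`.
#' @export
classify_aspects <- function(findings) {
  as_class(aspects_score(findings) <= 7L)
}

#' Classify a stroke by BASIS
#'
#' MAJOR iff a qualifying arterial occlusion is present (distal ICA, MCA M1
#' or M2, basilar), or the anterior parenchymal criterion holds (ASPECTS
#' score <= 7), or a posterior parenchymal criterion holds (bilateral pons
#' or bilateral thalamus hypodensity). `OTHER` occlusions never qualify.
#'
#' @inheritParams aspects_score
#' @return `"MAJOR"` or `"NONMAJOR"`.
#' @export
classify_basis <- function(findings) {
  stopifnot(inherits(findings, "imaging_findings"))
  major <- length(intersect(findings$occlusion_sites, QUALIFYING_SITES)) > 0 ||
    aspects_score(findings) <= 7L ||
    findings$bilateral_pons_hypodensity ||
    findings$bilateral_thalamus_hypodensity
  as_class(major)
}

#' Classify a stroke by dichotomized NIHSS
#'
#' MAJOR iff the admission NIHSS is strictly greater than 10.
#'
#' @param nihss_admission integer score(s) in 0..42 (vectorized).
#' @return `"MAJOR"`/`"NONMAJOR"`, same length as the input.
#' @export
classify_nihss <- function(nihss_admission) {
  if (any(is.na(nihss_admission)))
    stop("missing NIHSS score; run exclude_unanalyzable first")
  if (any(nihss_admission < 0 | nihss_admission > 42))
    stop("NIHSS score out of range 0..42")
  as_class(nihss_admission > 10)
}

#' Combine the NIHSS and BASIS classes
#'
#' Both MAJOR -> `CONCORDANT_MAJOR`; both NONMAJOR -> `CONCORDANT_MINOR`;
#' mixed -> `DISCORDANT`. Vectorized.
#'
#' @param nihss_class,basis_class `"MAJOR"`/`"NONMAJOR"` vectors.
#' @return combined class vector with levels
#'   `CONCORDANT_MAJOR`, `DISCORDANT`, `CONCORDANT_MINOR`.
#' @export
classify_combined <- function(nihss_class, basis_class) {
  stopifnot(length(nihss_class) == length(basis_class),
            all(nihss_class %in% c(MAJOR, NONMAJOR)),
            all(basis_class %in% c(MAJOR, NONMAJOR)))
  ifelse(nihss_class == MAJOR & basis_class == MAJOR, "CONCORDANT_MAJOR",
         ifelse(nihss_class == NONMAJOR & basis_class == NONMAJOR,
                "CONCORDANT_MINOR", "DISCORDANT"))
}

#' Apply all four instruments to a cohort
#'
#' Appends per-patient columns `aspects_score`, `aspects_class`,
#' `basis_class`, `nihss_class`, `combined_class`, and the outcome dichotomy
#' `poor_outcome` (6-month mRS > 2; death, mRS 6, counts as poor). All
#' records must have a present mRS and NIHSS (run [exclude_unanalyzable()]
#' first).
#'
#' @param cohort a [cohort_table()].
#' @return a `classified_cohort` data.frame: the cohort plus class columns.
#' @export
classify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (any(is.na(cohort$mrs_6mo)))
    stop("missing mRS in cohort; run exclude_unanalyzable first")
  out <- as.data.frame(cohort)

  n_regions <- vapply(out$anterior_hypodense_regions,
                      function(cell) length(unique(parse_tokens(cell))),
                      integer(1), USE.NAMES = FALSE)
  has_occl <- vapply(out$occlusion_sites, function(cell)
    length(intersect(parse_tokens(cell), QUALIFYING_SITES)) > 0,
    logical(1), USE.NAMES = FALSE)

  out$aspects_score <- 10L - n_regions
  out$aspects_class <- as_class(out$aspects_score <= 7L)
  out$basis_class <- as_class(has_occl | out$aspects_score <= 7L |
                                out$bilateral_pons_hypodensity |
                                out$bilateral_thalamus_hypodensity)
  out$nihss_class <- classify_nihss(out$nihss_admission)
  out$combined_class <- classify_combined(out$nihss_class, out$basis_class)
  out$poor_outcome <- out$mrs_6mo > 2L

  structure(out,
            provenance = attr(cohort, "provenance"),
            class = c("classified_cohort", "data.frame"))
}

#' Class counts of a classified cohort
#'
#' @param classified a [classify_cohort()] result.
#' @return named list of count tables per instrument.
#' @export
class_counts <- function(classified) {
  stopifnot(inherits(classified, "classified_cohort"))
  list(
    n = nrow(classified),
    aspects = table(factor(classified$aspects_class, c(MAJOR, NONMAJOR))),
    basis = table(factor(classified$basis_class, c(MAJOR, NONMAJOR))),
    nihss = table(factor(classified$nihss_class, c(MAJOR, NONMAJOR))),
    combined = table(factor(classified$combined_class, COMBINED_LEVELS)),
    poor_outcome = sum(classified$poor_outcome)
  )
}
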