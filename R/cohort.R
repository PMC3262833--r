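# Cohort domain model: patient records, imaging findings, delimited-text I/O.

#' The ten ASPECTS regions of the anterior circulation
#'
#' Caudate (C), lentiform nucleus (L), internal capsule (IC), insula (I),
#' and six MCA cortical territories (M1c--M6c; the "c" suffix distinguishes
#' cortical regions from the M1/M2 arterial segments).
#' @export
ASPECTS_REGIONS <- c("C", "L", "IC", "I", "M1c", "M2c", "M3c", "M4c", "M5c", "M6c")

#' Arterial occlusion sites that qualify a stroke as BASIS-major
#'
#' Distal (intracranial) internal carotid artery, proximal middle cerebral
#' artery (M1 or M2 segment), or basilar artery. `OTHER` covers any coded
#' occlusion outside this set (ACA, PCA, distal MCA branches, extracranial
#' disease); it never satisfies the arterial criterion.
#' @export
QUALIFYING_SITES <- c("DISTAL_ICA", "MCA_M1", "MCA_M2", "BASILAR")

#' @rdname QUALIFYING_SITES
#' @export
OCCLUSION_SITES <- c(QUALIFYING_SITES, "OTHER")

# Canonical column order of the cohort CSV dialect.
COHORT_COLUMNS <- c(
  "patient_id", "age", "sex", "nihss_admission",
  "diabetes", "cad", "atrial_fibrillation", "smoking", "hyperlipidemia",
  "hypertension", "iv_tpa", "ia_therapy",
  "occlusion_sites", "anterior_hypodense_regions",
  "bilateral_pons_hypodensity", "bilateral_thalamus_hypodensity",
  "mrs_6mo"
)

LOGICAL_COLUMNS <- c(
  "diabetes", "cad", "atrial_fibrillation", "smoking", "hyperlipidemia",
  "hypertension", "iv_tpa", "ia_therapy",
  "bilateral_pons_hypodensity", "bilateral_thalamus_hypodensity"
)

# ";"-separated token cells <-> character vectors
parse_tokens <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character(0))
  strsplit(cell, ";", fixed = TRUE)[[1]]
}

join_tokens <- function(tokens) paste(tokens, collapse = ";")

#' Coded imaging findings for one patient
#'
#' @param occlusion_sites character vector of CTA occlusion sites, drawn from
#'   [OCCLUSION_SITES].
#' @param anterior_hypodense_regions character vector of hypodense ASPECTS
#'   regions (subset of [ASPECTS_REGIONS], no duplicates).
#' @param bilateral_pons_hypodensity,bilateral_thalamus_hypodensity logical
#'   flags for the posterior-circulation parenchymal criteria.
#' @return an object of class `imaging_findings`.
#' @export
imaging_findings <- function(occlusion_sites = character(0),
                             anterior_hypodense_regions = character(0),
                             bilateral_pons_hypodensity = FALSE,
                             bilateral_thalamus_hypodensity = FALSE) {
  bad_site <- setdiff(occlusion_sites, OCCLUSION_SITES)
  if (length(bad_site) > 0)
    stop("unknown occlusion site(s): ", paste(bad_site, collapse = ", "))
  bad_reg <- setdiff(anterior_hypodense_regions, ASPECTS_REGIONS)
  if (length(bad_reg) > 0)
    stop("unknown ASPECTS region(s): ", paste(bad_reg, collapse = ", "))
  if (anyDuplicated(anterior_hypodense_regions))
    stop("duplicate ASPECTS regions")
  stopifnot(is.logical(bilateral_pons_hypodensity), length(bilateral_pons_hypodensity) == 1,
            is.logical(bilateral_thalamus_hypodensity), length(bilateral_thalamus_hypodensity) == 1)
  structure(
    list(
      occlusion_sites = occlusion_sites,
      anterior_hypodense_regions = anterior_hypodense_regions,
      bilateral_pons_hypodensity = bilateral_pons_hypodensity,
      bilateral_thalamus_hypodensity = bilateral_thalamus_hypodensity
    ),
    class = "imaging_findings"
  )
}

# Validate one-row-per-patient data; returns a character vector of reasons
# (zero-length = valid) for each row.
row_problems <- function(df) {
  n <- nrow(df)
  reason <- character(n)
  flag <- function(bad, why) reason[bad & !nzchar(reason)] <<- why

  flag(is.na(df$patient_id) | !nzchar(df$patient_id) | grepl("[,;]", df$patient_id),
       "bad_patient_id")
  flag(duplicated(df$patient_id), "duplicate_patient_id")
  flag(is.na(df$age) | df$age <= 0, "bad_age")
  flag(!(df$sex %in% c("male", "female")), "bad_sex")
  # NIHSS may be missing at enrollment (handled by exclude_unanalyzable),
  # but a present score must be in 0..42.
  flag(!is.na(df$nihss_admission) & (df$nihss_admission < 0 | df$nihss_admission > 42),
       "bad_nihss")
  flag(!is.na(df$mrs_6mo) & (df$mrs_6mo < 0 | df$mrs_6mo > 6), "bad_mrs")
  for (col in LOGICAL_COLUMNS) flag(is.na(df[[col]]), paste0("bad_", col))

  site_ok <- vapply(df$occlusion_sites, function(cell)
    all(parse_tokens(cell) %in% OCCLUSION_SITES), logical(1), USE.NAMES = FALSE)
  flag(!site_ok, "bad_occlusion_sites")
  reg_ok <- vapply(df$anterior_hypodense_regions, function(cell) {
    toks <- parse_tokens(cell)
    all(toks %in% ASPECTS_REGIONS) && !anyDuplicated(toks)
  }, logical(1), USE.NAMES = FALSE)
  flag(!reg_ok, "bad_anterior_hypodense_regions")
  reason
}

#' Construct a validated cohort table
#'
#' A cohort table is a `data.frame` with one row per patient and the fixed
#' column set of the cohort CSV dialect, plus a provenance attribute.
#'
#' @param df data.frame with the cohort columns.
#' @param provenance character note on where the rows came from (file path or
#'   generator seed).
#' @param strict if `TRUE`, any invalid row aborts; if `FALSE`, invalid rows
#'   are dropped and counted by reason in `attr(, "dropped")`.
#' @return a `cohort_table` (also a `data.frame`).
#' @export
cohort_table <- function(df, provenance = "in-memory", strict = TRUE) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, COHORT_COLUMNS, drop = FALSE]

  df$patient_id <- as.character(df$patient_id)
  df$age <- as.numeric(df$age)
  df$sex <- as.character(df$sex)
  df$nihss_admission <- as.integer(df$nihss_admission)
  df$mrs_6mo <- as.integer(df$mrs_6mo)
  for (col in LOGICAL_COLUMNS) df[[col]] <- as.logical(df[[col]])
  df$occlusion_sites <- as.character(df$occlusion_sites)
  df$anterior_hypodense_regions <- as.character(df$anterior_hypodense_regions)
  df$occlusion_sites[is.na(df$occlusion_sites)] <- ""
  df$anterior_hypodense_regions[is.na(df$anterior_hypodense_regions)] <- ""

  reason <- row_problems(df)
  bad <- nzchar(reason)
  dropped <- integer(0)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("invalid record(s): %s",
                   paste(sprintf("row %d (%s)", which(bad), reason[bad]),
                         collapse = "; ")))
    }
    dropped <- table(reason[bad])
    dropped <- stats::setNames(as.integer(dropped), names(dropped))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df,
            provenance = provenance,
            dropped = dropped,
            class = c("cohort_table", "data.frame"))
}

empty_cohort_df <- function() {
  df <- data.frame(
    patient_id = character(0), age = numeric(0), sex = character(0),
    nihss_admission = integer(0), stringsAsFactors = FALSE
  )
  for (col in LOGICAL_COLUMNS) df[[col]] <- logical(0)
  df$occlusion_sites <- character(0)
  df$anterior_hypodense_regions <- character(0)
  df$mrs_6mo <- integer(0)
  df[, COHORT_COLUMNS]
}

#' Read a cohort from delimited text
#'
#' Dialect: comma-separated, UTF-8, header row naming every column;
#' list-valued cells (occlusion sites, hypodense regions) use ";" as inner
#' separator; missing values (the 6-month mRS) are empty cells; logicals are
#' written `TRUE`/`FALSE`.
#'
#' @param source path or connection to a CSV in the cohort dialect.
#' @param strict if `TRUE` (default) any invariant violation aborts; if
#'   `FALSE` offending rows are dropped and counted in `attr(, "dropped")`.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(source, strict = TRUE) {
  df <- utils::read.csv(source, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    return(cohort_table(empty_cohort_df(),
                        provenance = paste0("read: ", paste(source, collapse = ""))))
  }

  conv_int <- function(x) suppressWarnings(as.integer(ifelse(nzchar(x), x, NA)))
  conv_num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  conv_lgl <- function(x) ifelse(x == "TRUE", TRUE, ifelse(x == "FALSE", FALSE, NA))

  out <- df
  out$age <- conv_num(df$age)
  out$nihss_admission <- conv_int(df$nihss_admission)
  out$mrs_6mo <- conv_int(df$mrs_6mo)
  for (col in LOGICAL_COLUMNS) out[[col]] <- conv_lgl(df[[col]])

  prov <- if (is.character(source)) paste0("read: ", source) else "read: connection"
  ct <- cohort_table(out, provenance = prov, strict = strict)
  nd <- sum(attr(ct, "dropped"))
  if (nd > 0)
    attr(ct, "provenance") <- sprintf("%s (%d row(s) dropped)", prov, nd)
  ct
}

#' Write a cohort in the same dialect `read_cohort` accepts
#'
#' `read_cohort(write_cohort(x))` is the identity field-for-field; missing
#' mRS is an empty cell, never the string "NA".
#'
#' @param cohort a [cohort_table()].
#' @param sink path or connection to write to.
#' @return `invisible(sink)`.
#' @export
write_cohort <- function(cohort, sink) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  out$age <- vapply(out$age, function(a) as.character(a), character(1))
  for (col in LOGICAL_COLUMNS) out[[col]] <- ifelse(out[[col]], "TRUE", "FALSE")
  out$mrs_6mo <- ifelse(is.na(out$mrs_6mo), "", as.character(out$mrs_6mo))
  utils::write.table(out, sink, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(sink)
}

#' Drop records that cannot be analyzed
#'
#' Removes records with a missing 6-month mRS or a missing admission NIHSS
#' (records missing both are counted under missing mRS, the first exclusion
#' applied). Idempotent.
#'
#' @param cohort a [cohort_table()].
#' @return list with elements `cohort` (the analyzable subset) and
#'   `exclusions` (named counts: `missing_mrs`, `missing_nihss`).
#' @export
exclude_unanalyzable <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  miss_mrs <- is.na(cohort$mrs_6mo)
  miss_nihss <- !miss_mrs & is.na(cohort$nihss_admission)
  keep <- !(miss_mrs | miss_nihss)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- if (any(!keep)) {
    sprintf("%s; %d excluded (no mRS %d, no NIHSS %d)",
            attr(cohort, "provenance"),
            sum(!keep), sum(miss_mrs), sum(miss_nihss))
  } else {
    attr(cohort, "provenance")
  }
  attr(out, "dropped") <- attr(cohort, "dropped")
  class(out) <- c("cohort_table", "data.frame")
  list(cohort = out,
       exclusions = c(missing_mrs = sum(miss_mrs), missing_nihss = sum(miss_nihss)))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patient(s) [%s]\n", nrow(x), attr(x, "provenance")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
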