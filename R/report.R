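# End-to-end analysis: classify -> evaluate -> report.

#' Run the full severity-classification analysis on a cohort
#'
#' Orchestrates the pipeline on an analyzable cohort: per-instrument class
#' counts; the diagnostic-performance block (sensitivity, specificity, PPV,
#' NPV, accuracy with Wilson intervals) for NIHSS>10, BASIS and ASPECTS;
#' the combined-instrument block (3x2 outcome table, per-stratum outcome
#' percentages, chi-square across strata, odds ratios of the
#' concordant-major stratum versus the other strata); treatment subgroup
#' blocks (IV tPA, endovascular, including the NIHSS rank-sum comparison of
#' endovascular patients against the rest); and forced-entry plus stepwise
#' logistic models of poor outcome on the NIHSS class, BASIS class, ASPECTS
#' class and age. Deterministic given the cohort; percentages use half-up
#' one-decimal rounding at render time only.
#'
#' @param cohort a nonempty [cohort_table()] that passes
#'   [exclude_unanalyzable()] (no missing mRS or NIHSS).
#' @param include_stepwise run the stepwise selection as well as the
#'   forced-entry fit (default `TRUE`).
#' @return a nested list of class `analysis_report`, JSON-serializable via
#'   [report_to_json()].
#' @export
run_full_analysis <- function(cohort, include_stepwise = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort) == 0) stop("empty cohort: nothing to analyze")
  if (any(is.na(cohort$mrs_6mo)) || any(is.na(cohort$nihss_admission)))
    stop("cohort has missing mRS or NIHSS; run exclude_unanalyzable first")

  cl <- with_stage("classify", classify_cohort(cohort))
  counts <- class_counts(cl)

  metrics <- with_stage("metrics", {
    lapply(list(nihss = cl$nihss_class, basis = cl$basis_class,
                aspects = cl$aspects_class), function(cls) {
      m <- diagnostic_metrics(confusion(cls == "MAJOR", cl$poor_outcome))
      m$estimate_pct <- as_pct(m$estimate)
      m
    })
  })

  combined <- with_stage("combined", {
    tab <- t(vapply(COMBINED_LEVELS, function(lev) {
      idx <- cl$combined_class == lev
      c(poor = sum(cl$poor_outcome & idx), good = sum(!cl$poor_outcome & idx))
    }, c(poor = 0, good = 0)))
    strata <- data.frame(
      stratum = rownames(tab), n = as.integer(rowSums(tab)),
      poor = as.integer(tab[, "poor"]),
      poor_pct = as_pct(ifelse(rowSums(tab) > 0, tab[, "poor"] / rowSums(tab), NA)),
      row.names = NULL
    )
    or_vs <- function(other) {
      odds_ratio(two_by_two(tab["CONCORDANT_MAJOR", "poor"],
                            tab["CONCORDANT_MAJOR", "good"],
                            tab[other, "poor"], tab[other, "good"]))
    }
    list(
      table = data.frame(stratum = rownames(tab),
                         poor = as.integer(tab[, "poor"]),
                         good = as.integer(tab[, "good"]), row.names = NULL),
      strata = strata,
      chi2_p = if (all(rowSums(tab) > 0)) chi2_rxc(tab)$p_value else NA_real_,
      or_concordant_major_vs_minor =
        unclass(or_vs("CONCORDANT_MINOR"))[c("estimate", "ci_low", "ci_high")],
      or_concordant_major_vs_discordant =
        unclass(or_vs("DISCORDANT"))[c("estimate", "ci_low", "ci_high")],
      concordance_pct = as_pct(mean(cl$combined_class != "DISCORDANT"))
    )
  })

  subgroups <- with_stage("subgroups", {
    sub_block <- function(idx) {
      list(n = sum(idx), poor = sum(cl$poor_outcome & idx),
           poor_pct = as_pct(if (sum(idx) > 0) mean(cl$poor_outcome[idx]) else NA))
    }
    endo <- cl$ia_therapy
    nihss_cmp <- if (any(endo) && any(!endo))
      wilcoxon_ranksum(cl$nihss_admission[endo], cl$nihss_admission[!endo])$p_value
    else NA_real_
    list(
      iv_tpa = sub_block(cl$iv_tpa),
      no_iv_tpa = sub_block(!cl$iv_tpa),
      endovascular = c(sub_block(endo),
                       median_nihss = stats::median(cl$nihss_admission[endo]),
                       median_nihss_rest = stats::median(cl$nihss_admission[!endo]),
                       nihss_ranksum_p = nihss_cmp)
    )
  })

  design <- data.frame(
    nihss_major = as.numeric(cl$nihss_class == "MAJOR"),
    basis_major = as.numeric(cl$basis_class == "MAJOR"),
    aspects_major = as.numeric(cl$aspects_class == "MAJOR"),
    age = cl$age
  )
  logistic <- with_stage("logistic", {
    forced <- logistic_fit(design, cl$poor_outcome)
    out <- list(forced_entry = list(
      coefficients = as.list(forced$coefficients),
      se = as.list(forced$se),
      odds_ratios = as.list(forced$odds_ratios),
      loglik = forced$loglik, converged = forced$converged,
      iterations = forced$iterations
    ))
    if (include_stepwise) {
      sw <- stepwise_logistic(design, cl$poor_outcome)
      out$stepwise <- list(
        selected = sw$selected,
        coefficients = as.list(sw$fit$coefficients),
        odds_ratios = as.list(sw$fit$odds_ratios),
        trace = sw$trace
      )
    }
    out
  })

  structure(list(
    cohort_summary = list(
      n = nrow(cl),
      provenance = attr(cohort, "provenance"),
      poor_outcomes = counts$poor_outcome,
      poor_outcome_pct = as_pct(counts$poor_outcome / nrow(cl))
    ),
    class_counts = lapply(counts[c("aspects", "basis", "nihss", "combined")],
                          function(t) as.list(stats::setNames(as.integer(t), names(t)))),
    metrics = metrics,
    combined = combined,
    subgroups = subgroups,
    logistic = logistic,
    software = list(package = "strokeclass",
                    version = as.character(utils::packageVersion("strokeclass")))
  ), class = "analysis_report")
}

#' Serialize an analysis report to JSON
#'
#' @param report an [run_full_analysis()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
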