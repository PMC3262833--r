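#!/usr/bin/env Rscript
# Stage 3: full statistical evaluation of the classified cohort --
# diagnostic metrics per instrument, combined-instrument strata with odds
# ratios, treatment subgroups, and the forced-entry + stepwise logistic
# outcome models -- written as one structured JSON report.

suppressPackageStartupMessages(library(strokeclass))

cohort <- read_cohort("results/synthetic_cohort.csv")
report <- run_full_analysis(exclude_unanalyzable(cohort)$cohort)
report_to_json(report, "results/analysis_report.json")

message(sprintf("n = %d, poor outcome %.1f%%",
                report$cohort_summary$n, report$cohort_summary$poor_outcome_pct))
for (inst in names(report$metrics)) {
  m <- report$metrics[[inst]]
  message(sprintf("%-8s sens %.1f  spec %.1f  ppv %.1f  npv %.1f  acc %.1f",
                  inst, m$estimate_pct[1], m$estimate_pct[2], m$estimate_pct[3],
                  m$estimate_pct[4], m$estimate_pct[5]))
}
or <- report$combined$or_concordant_major_vs_minor
message(sprintf("concordant-major vs concordant-minor OR %.1f (%.1f to %.1f), concordance %.1f%%",
                or$estimate, or$ci_low, or$ci_high, report$combined$concordance_pct))
message("stepwise retained: ",
        paste(report$logistic$stepwise$selected, collapse = ", "))
message("wrote results/analysis_report.json")
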