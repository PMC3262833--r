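#!/usr/bin/env Rscript
# Stage 2: apply the four severity instruments to the cohort from stage 1
# and write the classified table.

suppressPackageStartupMessages(library(strokeclass))

cohort <- read_cohort("results/synthetic_cohort.csv")
analyzable <- exclude_unanalyzable(cohort)
message(sprintf("cohort: %d records, %d excluded (missing mRS %d, missing NIHSS %d)",
                nrow(cohort), sum(analyzable$exclusions),
                analyzable$exclusions[["missing_mrs"]],
                analyzable$exclusions[["missing_nihss"]]))

cl <- classify_cohort(analyzable$cohort)
write.csv(as.data.frame(cl), "results/classified_cohort.csv", row.names = FALSE)

counts <- class_counts(cl)
message(sprintf("ASPECTS major: %d  BASIS major: %d  NIHSS>10: %d  poor outcomes: %d",
                counts$aspects[["MAJOR"]], counts$basis[["MAJOR"]],
                counts$nihss[["MAJOR"]], counts$poor_outcome))
message("combined classes: ",
        paste(sprintf("%s %d", names(counts$combined), counts$combined), collapse = ", "))
message("wrote results/classified_cohort.csv")
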