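#!/usr/bin/env Rscript
# Batch quality control: validate every analytical batch against the four
# acceptance conditions (blank without peaks; standard mix within 10% of
# expected; duplicate-injection top-100 deviation < 15%; pooled injection
# within 5% of the running pooled centroid), then apply the 80% feature
# presence filter. Also demonstrates that an injected fault is caught.
# Writes: results/qc_reports.json, results/cohort_filtered.csv.

suppressPackageStartupMessages(library(emlscreen))
dir.create("results", showWarnings = FALSE)

seed <- 2024L
cohort <- read_peak_table("results/cohort.csv")
batches <- generate_batches(cohort, batch_size = 25, seed = seed + 1L)

reports <- validate_batches(batches)
ok <- vapply(reports, `[[`, logical(1), "pass")
cat(sprintf("batches passing all four QC conditions: %d / %d\n",
            sum(ok), length(ok)))
write_qc_reports(reports, "results/qc_reports.json")

# a deliberately drifted standard mix is flagged on exactly that condition
bad <- corrupt_batch(batches[[2]], "standard_drift", magnitude = 0.20)
bad_report <- validate_batch(bad)
cat("corrupted batch (20% standard drift):\n")
print(bad_report)

filtered <- filter_features(cohort, presence_threshold = 0.80)
cat(sprintf("presence filter: %d features retained, %d removed\n",
            ncol(filtered$table$areas), length(filtered$removed)))
write_peak_table(filtered$table, "results/cohort_filtered.csv")
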