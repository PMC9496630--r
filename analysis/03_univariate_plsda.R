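#!/usr/bin/env Rscript
# Univariate and PLS-DA characterization of the cohort: volcano analysis
# (fold change > 2 or < 0.5 and p < 0.05 on IS-normalized areas) and PLS-DA
# diagnostics (latent-variable choice, VIP scores, R2/Q2, permutation test).
# Writes: results/volcano.csv, results/vip.csv, results/plsda.json.

suppressPackageStartupMessages(library(emlscreen))
dir.create("results", showWarnings = FALSE)

seed <- 2024L
cohort <- read_peak_table("results/cohort_filtered.csv")
norm <- normalize_to_is(cohort)

v <- volcano(norm)
write.csv(v, "results/volcano.csv", row.names = FALSE)
cat(sprintf("volcano: %d metabolites flagged (%d raised, %d lowered in EC)\n",
            sum(v$flagged), sum(v$flagged & v$direction == "up"),
            sum(v$flagged & v$direction == "down")))
print(v[v$flagged, c("feature", "fold_change", "p_value", "direction")],
      row.names = FALSE, digits = 3)

complete <- impute_missing(norm, "half_min")$table
pm <- log_and_autoscale(complete)
diag <- plsda_diagnostics(pm, max_lv = 3, folds = 7, n_perm = 2000,
                          seed = seed)
print(diag)

vt <- vip_table(diag, cutoff = 2.0)
write.csv(vt, "results/vip.csv", row.names = FALSE)
cat(sprintf("metabolites with VIP > 2.0: %d\n", nrow(vt)))
print(vt, row.names = FALSE, digits = 3)

jsonlite::write_json(
  list(ncomp = diag$ncomp, r2 = diag$r2, q2 = diag$q2,
       perm_p = diag$perm_p, n_perm = diag$n_perm,
       cv_accuracy = diag$cv_accuracy),
  "results/plsda.json", auto_unbox = TRUE, digits = NA)
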