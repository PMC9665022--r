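#!/usr/bin/env Rscript
# Stage 4: the two-stage stability screen.
#
# Stage 1 keeps features with excellent ICC (>= 0.75) in at least 4 organs of
# the winning subset/mode table; stage 2 keeps those that additionally show
# segmentation-resegmentation concordance (CCC > 0.6) in at least 3 organs in
# at least 6 VM reconstructions. Writes the full audit trail under
# results/screening/.

library(pcctstab)

ft <- read_feature_table("results/features.csv")

report <- screen_features(ft, stability_criteria())
write_report(report, "results/screening")
print(report)

counts <- report$per_organ
cat("\nExcellent-or-good features per organ:\n")
print(counts)
cat(sprintf("\nMost stable organ: %s (%d features); least stable: %s (%d).\n",
            counts$organ[which.max(counts$n_stable)], max(counts$n_stable),
            counts$organ[which.min(counts$n_stable)], min(counts$n_stable)))
cat("Full audit trail in results/screening/ (CSV tables + summary.md)\n")
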