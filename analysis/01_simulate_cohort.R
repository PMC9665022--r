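#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic PCCT cohort.
#
# Ten patients, each with frozen block anatomy (six tissue classes carrying a
# patient-specific texture field and iodine uptake) rendered into 12
# reconstruction channels: VM 40-120 keV, polyenergetic T3D, VNC and the
# iodine map. Writes the reproducibility manifest and a compact per-channel
# intensity summary; the volumes themselves are regenerated on demand from the
# manifest seeds, so nothing bulky needs to be stored.

library(pcctstab)

dir.create("results", showWarnings = FALSE)
spec <- cohort_spec(master_seed = 20221115L)

manifest <- cohort_manifest(spec)
jsonlite::write_json(manifest, "results/cohort_manifest.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# per-channel mean/sd inside each tissue of patient 1, as a sanity table
st <- generate_patient_stack(spec, 1)
tis <- default_tissues()
rows <- list()
for (ch in channel_ids()) {
  img <- st$channels[[ch]]
  for (i in seq_len(nrow(tis))) {
    v <- img[st$material$label_map == i]
    rows[[length(rows) + 1L]] <- data.frame(
      channel = ch, tissue = tis$tissue[i],
      mean = mean(v), sd = sd(v)
    )
  }
}
summary_tab <- do.call(rbind, rows)
write.csv(summary_tab, "results/channel_tissue_summary.csv", row.names = FALSE)

liver40 <- subset(summary_tab, channel == "VM40" & tissue == "liver")$mean
liver120 <- subset(summary_tab, channel == "VM120" & tissue == "liver")$mean
cat(sprintf("Simulated %d patients x %d channels on a %s grid.\n",
            spec$n_patients, length(channel_ids()),
            paste(spec$shape, collapse = "x")))
cat(sprintf("Liver mean falls from %.0f HU at 40 keV to %.0f HU at 120 keV — the\n",
            liver40, liver120))
cat("iodine-driven energy dependence the stability analysis probes.\n")
cat("Wrote results/cohort_manifest.json and results/channel_tissue_summary.csv\n")
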