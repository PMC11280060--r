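#!/usr/bin/env Rscript
# Step 1 — define the study samples and show what the simulator produces.
#
# Four samples of the mefloquine/polacrilin system: the pure drug (MQ),
# the pure cation-exchange resin (R), the resinate complex (MQ-R), and a
# literal physical mixture (MQ+R). Each is a list of carbon sites with
# ground-truth chemical shifts and CP dynamics constants (TCH, T1rhoH);
# the complex differs from the mixture in the drug carbons' T1rhoH (and a
# handful of shift edits), which is exactly the contrast the downstream
# classifier exploits. Writes the ground-truth site tables and a
# demonstration spectrum; the spectral series themselves are cheap and are
# regenerated by the later steps.

suppressPackageStartupMessages(library(resinate))
dir.create("results", showWarnings = FALSE)

specs <- default_sample_specs()        # 2% multiplicative noise

site_table <- do.call(rbind, lapply(names(specs), function(id) {
  s <- specs[[id]]$sites
  data.frame(sample = id, assignment = s$assignment,
             component = s$component,
             shifts_ppm = vapply(s$shifts, paste, "", collapse = ";"),
             S0 = s$S0, TCH_us = s$TCH, T1rhoH_ms = s$T1rhoH,
             linewidth_hz = s$linewidth)
}))
write.csv(site_table, "results/sample_sites.csv", row.names = FALSE)
cat(sprintf("wrote %d ground-truth sites for %d samples\n",
            nrow(site_table), length(specs)))

# one demonstration spectrum of the complex near its C2 curve maximum
ser <- generate_vct_series(specs[["MQ-R"]], contact_times = c(2000, 5000),
                           seed = 20240702)
dir.create("scratch", showWarnings = FALSE)
write_spectrum(ser$spectra[[2]], "scratch/MQ-R_tc5000us.csv")
pk <- pick_peaks(ser$spectra[[2]], min_prominence = 0.05,
                 min_separation = 1.0)
cat(sprintf("demo MQ-R spectrum at tc = 5000 us: %d peaks picked; ", nrow(pk)))
cat(sprintf("%d in the C11 region (65.5-71.5 ppm) — the split C-OH signal\n",
            sum(pk$center > 65.5 & pk$center < 71.5)))
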