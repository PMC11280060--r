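#!/usr/bin/env Rscript
# Step 2 — fit the CP dynamics model per carbon for every sample.
#
# For each sample a variable-contact-time series (24 log-spaced contact
# times, 20-50,000 us, 2% multiplicative noise) is generated and each
# peak's integrated intensity curve is fit with
# S(tc) = S0 (1 - exp(-tc/TCH)) exp(-tc/T1rhoH). Peaks buried under the
# other component in the physical mixture are flagged and reported n.d.,
# mirroring how overlapping signals restrict the measurable set in
# practice. Writes one relaxation table per sample (the shape of a
# per-carbon relaxation report).

suppressPackageStartupMessages(library(resinate))
dir.create("results", showWarnings = FALSE)

specs <- default_sample_specs()
seed0 <- 20240702
mixture_overlaps <- c("C12", "C14", "C15", "C16", "C17",
                      "CH/CH2 ~57", "CH/CH2 ~47", "C6 (CH3)")

for (id in names(specs)) {
  ov <- if (id == "MQ+R") mixture_overlaps else character(0)
  tab <- spec_peak_table(specs[[id]], overlap_assignments = ov,
                         overlap_group = "overlap")
  ser <- generate_vct_series(specs[[id]], seed = seed0 + match(id, names(specs)))
  fits <- fit_sample_table(ser, tab)
  out <- sprintf("results/relaxation_%s.csv", gsub("[+]", "plus", id))
  write.csv(fits, out, row.names = FALSE)
  ok <- fits$status == "ok"
  cat(sprintf("%-5s %2d peaks, %2d fit ok | median TCH %5.0f us | median T1rhoH %6.1f ms\n",
              id, nrow(fits), sum(ok),
              median(fits$TCH_us[ok]), median(fits$T1rhoH_ms[ok])))
}

cat("\ncurve maxima from the ground-truth constants:\n")
cat(sprintf("  MQ C2 (TCH 2420 us, T1rhoH 140 ms): t* = %.0f us\n",
            cp_tmax(2420, 140)))
cat(sprintf("  resin CO2-K+ (TCH 1930 us, T1rhoH 9.7 ms): t* = %.0f us\n",
            cp_tmax(1930, 9.7)))
cat("the drug's buildup peaks an order of magnitude later than the resin's —\n")
cat("the mobility contrast the relaxation comparison rests on\n")
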