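# resinate

Solid-state NMR relaxometry and electronic-tongue analytics for
drug–ion-exchange-resin complexes.

Taste-masking a bitter drug by binding it to a cation-exchange resin only
works if the product is a true molecular-scale complex, not a blend of two
powders. `resinate` is for formulation scientists and solid-state NMR
spectroscopists who need to make that call quantitatively. It implements,
over plain-text spectra and tables:

* **Cross-polarization dynamics.** Per-carbon variable-contact-time
  (VCT) curves are fit with the classical CPMAS model

  S(t_c) = S₀ (1 − e^(−t_c/T_CH)) e^(−t_c/T₁ρᴴ)

  by Levenberg–Marquardt least squares with analytic Jacobian, giving
  T_CH (µs) and T₁ρᴴ (ms) with standard errors, plus the closed-form
  curve maximum t\* = T_CH ln(1 + T₁ρᴴ/T_CH).
* **Mixing-state inference.** Chemical-shift changes (Δδ, deshielded /
  shielded / split) and a proton spin-diffusion criterion: in an intimate
  complex, fast ¹H spin diffusion drags the drug carbons' T₁ρᴴ down to
  resin-like values; in a physical mixture each component keeps its own.
  `classify_mixing()` turns that into a
  complex / physical_mixture / indeterminate verdict with explicit
  evidence.
* **Electronic-tongue analytics.** Impedance-magnitude feature
  extraction, 2-D projection (Fastmap-initialized force scheme, or
  classical MDS), silhouette scoring, hierarchical clustering with
  class-centroid Euclidean distances, and single-exponential
  drug-release fitting with t95 = τ ln 20.
* **Synthetic data.** Seeded generators for VCT spectral series (per-carbon
  ground truth for the drug MQ, resin R, complex MQ–R, and physical
  mixture MQ+R), three-class six-unit sensor-array sets, and dissolution
  traces — the study conditions the tests and acceptance checks run on.

## Worked example

```r
library(resinate)

specs <- default_sample_specs()                       # ground-truth samples
ser   <- generate_vct_series(specs[["MQ-R"]], seed = 1)  # 24 contact times
fits  <- fit_sample_table(ser, spec_peak_table(specs[["MQ-R"]]))
head(fits[, c("assignment","delta_ppm","TCH_us","T1rhoH_ms","T1rhoH_se","status")])
#>    assignment delta_ppm TCH_us T1rhoH_ms T1rhoH_se status
#> 1 C1 (CO2-K+)       187   1189      8.93    0.0267     ok
#> 2          C4       152    713     55.95    0.2776     ok
#> 3          C2       148   1156     22.93    0.0651     ok
#> 4          C2       147   1210     23.60    0.0672     ok
#> 5         C8a       144   2384     44.91    0.2653     ok
#> 6         C8a       144   2516     38.49    0.1357     ok

pure_mq <- fit_sample_table(generate_vct_series(specs[["MQ"]], seed = 2),
                            spec_peak_table(specs[["MQ"]]))
pure_r  <- fit_sample_table(generate_vct_series(specs[["R"]], seed = 3),
                            spec_peak_table(specs[["R"]]))
classify_mixing(fits, pure_mq, pure_r)
#> <mixing_report> verdict: complex
#>   median T1rhoH (ms): drug-in-sample 23.8 | pure drug 121 | resin-in-sample 10 | pure resin 9.6
#>   fold reduction 5.06, drug/resin ratio 2.38
```

The drug carbons' median T₁ρᴴ has collapsed five-fold from the pure drug
and sits within a factor 2.4 of the resin carbons in the same sample —
one relaxation domain, hence a complex. Rerun with `specs[["MQ+R"]]` (the
literal union of drug and resin sites) and the verdict flips to
`physical_mixture`: two domains, each keeping its pure-component value.

The taste-masking read-out:

```r
tongue <- project_2d(feature_matrix(generate_etongue_set(seed = 7)), seed = 7)
tongue
#> <projection_result force_scheme> 9 samples, stress 0.0236, silhouette 0.910
#>          MQ   MQ-R      R
#> MQ    0.000 16.604 37.443
#> MQ-R 16.604  0.000 26.590
#> R    37.443 26.590  0.000
```

Three clean clusters (silhouette 0.91), with the complex between drug and
resin but nearer the drug — the signature of a real but partial taste
mask.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing small tables to
`results/` (run them in order from the repository root):

1. `01_simulate.R` — ground-truth site tables for the four samples and a
   demonstration spectrum (the split C11 signal of the complex).
2. `02_fit_cpdyn.R` — per-carbon relaxation tables for every sample, with
   overlap-flagged peaks reported n.d.
3. `03_mixing.R` — Δδ/splitting tables and the mixing verdicts for the
   complex and the physical mixture.
4. `04_etongue.R` — sensor-array projection, silhouette, cluster
   distances, and the release-kinetics fit.

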