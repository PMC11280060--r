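test_that("shift changes reproduce the reported per-carbon deltas", {
  tabs <- default_shift_tables()
  ds <- delta_shifts(tabs$MQ_solid, tabs[["MQ-R"]])

  c4 <- ds[ds$assignment == "C4", ]
  expect_equal(c4$delta_shift[c4$delta_ref == 148.5], 6.5)
  expect_equal(c4$classification[c4$delta_ref == 148.5], "deshielded")

  c7 <- ds[ds$assignment == "C7", ]
  expect_equal(c7$delta_shift, -2.1)
  expect_equal(c7$classification, "shielded")

  c11 <- ds[ds$assignment == "C11", ]
  expect_true(all(c11$classification == "split"))

  c14 <- ds[ds$assignment == "C14", ]
  expect_true(all(c14$classification == "overlap"))

  # identical tables: all zero, all unchanged
  same <- delta_shifts(tabs$MQ_solid, tabs$MQ_solid)
  expect_true(all(same$delta_shift == 0))
  expect_true(all(same$classification == "unchanged"))
})

test_that("solution-reference mode uses the DMSO shifts as baseline", {
  tabs <- default_shift_tables()
  ds <- delta_shifts(tabs$MQ_dmso, tabs[["MQ-R"]])
  # the packing effect vanishes: C7 slightly shielded vs solution too
  c7 <- ds[ds$assignment == "C7", ]
  expect_equal(c7$delta_shift, 128.0 - 130.39, tolerance = 1e-9)
  expect_equal(c7$classification, "shielded")
})

test_that("delta shifts are antisymmetric under swapping the tables", {
  tabs <- default_shift_tables()
  # restrict to assignments with equal multiplicity so pairing is 1-1
  a <- tabs$MQ_solid
  counts_a <- table(a$assignment)
  b <- tabs[["MQ-R"]]
  b <- b[is.na(b$overlap_group), ]
  counts_b <- table(b$assignment)
  shared <- intersect(names(counts_a), names(counts_b))
  shared <- shared[counts_a[shared] == counts_b[shared]]
  a <- a[a$assignment %in% shared, ]
  b <- b[b$assignment %in% shared, ]

  fwd <- delta_shifts(a, b)
  rev <- delta_shifts(b, a)
  key <- function(d) d[order(d$assignment, d$delta_ref + d$delta_complex), ]
  fwd <- key(fwd); rev <- key(rev)
  expect_equal(fwd$delta_shift, -rev$delta_shift)
  swap <- c(deshielded = "shielded", shielded = "deshielded",
            unchanged = "unchanged")
  expect_equal(unname(swap[fwd$classification]), rev$classification)
})

test_that("splitting multiplicity counts match the reported unfolding", {
  tabs <- default_shift_tables()
  sp <- detect_splitting(tabs$MQ_solid, tabs[["MQ-R"]])
  expect_equal(sp[sp$assignment == "C11", ]$multiplicity_ref, 1)
  expect_equal(sp[sp$assignment == "C11", ]$multiplicity_complex, 3)
  expect_equal(sp[sp$assignment == "C4", ]$multiplicity_ref, 2)
  expect_equal(sp[sp$assignment == "C4", ]$multiplicity_complex, 2)
  same <- detect_splitting(tabs$MQ_solid, tabs$MQ_solid)
  expect_equal(same$multiplicity_ref, same$multiplicity_complex)
})

test_that("the reported relaxation values classify as a complex", {
  tv <- table_t1rho()
  rep <- classify_mixing(tv$mqr_drug, tv$mq, tv$r,
                         sample_resin_fits = tv$mqr_resin)
  expect_equal(rep$verdict, "complex")
  expect_true(rep$evidence$drug_T1rho_reduced)
  expect_true(rep$evidence$drug_resin_converged)
})

test_that("unchanged component relaxation classifies as a physical mixture", {
  tv <- table_t1rho()
  # a literal mixture: drug keeps 100-200 ms, resin keeps 9-12 ms
  rep <- classify_mixing(tv$mq, tv$mq, tv$r, sample_resin_fits = tv$r)
  expect_equal(rep$verdict, "physical_mixture")
})

test_that("fewer than two usable drug fits is indeterminate", {
  tv <- table_t1rho()
  rep <- classify_mixing(c(C2 = 22.2), tv$mq, tv$r,
                         sample_resin_fits = tv$mqr_resin)
  expect_equal(rep$verdict, "indeterminate")
  expect_false(rep$evidence$enough_drug_fits)
})

test_that("the verdict is monotone: lowering drug T1rhoH never un-complexes", {
  tv <- table_t1rho()
  base <- classify_mixing(tv$mqr_drug, tv$mq, tv$r,
                          sample_resin_fits = tv$mqr_resin)
  expect_equal(base$verdict, "complex")
  for (f in c(0.8, 0.5, 0.2, 0.05)) {
    rep <- classify_mixing(tv$mqr_drug * f, tv$mq, tv$r,
                           sample_resin_fits = tv$mqr_resin)
    expect_equal(rep$verdict, "complex")
  }
})

test_that("the verdict ignores fit order and uniform amplitude scaling", {
  specs <- default_sample_specs()
  sp <- specs[["MQ-R"]]; sp$noise_mult <- 0
  ser <- generate_vct_series(sp, default_contact_times(16), seed = 1)
  tab <- spec_peak_table(sp)
  ft <- fit_sample_table(ser, tab)
  tv <- table_t1rho()
  v1 <- classify_mixing(ft, tv$mq, tv$r)$verdict
  v2 <- classify_mixing(ft[rev(seq_len(nrow(ft))), ], tv$mq, tv$r)$verdict
  expect_equal(v1, v2)
  expect_equal(v1, "complex")

  sp2 <- sp
  sp2$sites$S0 <- sp2$sites$S0 * 12
  ser2 <- generate_vct_series(sp2, default_contact_times(16), seed = 1)
  v3 <- classify_mixing(fit_sample_table(ser2, tab), tv$mq, tv$r)$verdict
  expect_equal(v3, v1)
})

test_that("synthetic complex and physical mixture round-trip to their verdicts across seeds", {
  specs <- default_sample_specs()       # 2% multiplicative noise
  tcs <- default_contact_times(20)
  tv <- table_t1rho()
  for (seed in 1:3) {
    cpx <- fit_sample_table(
      generate_vct_series(specs[["MQ-R"]], tcs, seed = seed),
      spec_peak_table(specs[["MQ-R"]]))
    expect_equal(classify_mixing(cpx, tv$mq, tv$r)$verdict, "complex")

    mix <- fit_sample_table(
      generate_vct_series(specs[["MQ+R"]], tcs, seed = seed + 100),
      spec_peak_table(specs[["MQ+R"]],
                      overlap_assignments = mixture_overlaps(),
                      overlap_group = "overlap"))
    expect_equal(classify_mixing(mix, tv$mq, tv$r)$verdict,
                 "physical_mixture")
  }
})

test_that("drug loading efficiency is the bound mass fraction in percent", {
  expect_equal(drug_loading_efficiency(100, 0), 100)
  expect_equal(drug_loading_efficiency(100, 50), 50)
  expect_equal(drug_loading_efficiency(100, 0.36), 99.64)
  expect_error(drug_loading_efficiency(100, 101), "mass_unbound")
  expect_error(drug_loading_efficiency(0, 0), "mass_total")
})
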