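test_that("csv spectra round-trip, re-sort, and report parse errors by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_id: demo", "# spin_rate: 9800",
               "180,0.1", "170,0.9", "160,0.2"), path)
  sp <- load_spectrum(path, "csv")
  expect_s3_class(sp, "nmr_spectrum")
  expect_equal(sp$ppm, c(180, 170, 160))
  expect_equal(sp$intensity, c(0.1, 0.9, 0.2))
  expect_equal(sp$meta$sample_id, "demo")
  expect_equal(sp$meta$spin_rate, 9800)

  # ascending rows give the identical spectrum
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("160,0.2", "170,0.9", "180,0.1"), path2)
  sp2 <- load_spectrum(path2, "csv")
  expect_equal(sp2$ppm, sp$ppm)
  expect_equal(sp2$intensity, sp$intensity)

  # full write/read round trip preserves data
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path3)
  sp3 <- load_spectrum(path3, "csv")
  expect_equal(sp3$ppm, sp$ppm)
  expect_equal(sp3$intensity, sp$intensity, tolerance = 1e-9)

  # text in the intensity column names the offending line
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("180,0.1", "170,oops", "160,0.2"), path4)
  expect_error(load_spectrum(path4, "csv"), "line 2")

  path5 <- withr::local_tempfile(fileext = ".csv")
  writeLines("180,0.1", path5)
  expect_error(load_spectrum(path5, "csv"), "fewer than 2")
})

test_that("single-block JCAMP XYDATA is read with X/Y factors", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=synthetic",
               "##JCAMP-DX=4.24",
               "##XUNITS=PPM", "##YUNITS=ARBITRARY",
               "##FIRSTX=200", "##LASTX=0", "##NPOINTS=5",
               "##XFACTOR=1", "##YFACTOR=0.5",
               "##XYDATA=(X++(Y..Y))",
               "200 0 2 8 2",
               "0 0",
               "##END="), path)
  sp <- load_spectrum(path, "jcamp")
  expect_length(sp, 5)
  expect_equal(sp$ppm, c(200, 150, 100, 50, 0))
  expect_equal(sp$intensity, c(0, 1, 4, 1, 0))  # YFACTOR applied
})

test_that("referencing is an exact translation against the glycine carbonyl", {
  sp <- lorentzian_spectrum(c(175.0, 100.0), c(1, 1), 0.6)
  ref <- reference_shift(sp, observed_ref = 175.0)
  expect_equal(ref$meta$reference_offset, 1.03)
  # the observed line now sits at 176.03
  expect_equal(ref$ppm[which.max(ref$intensity)],
               sp$ppm[which.max(sp$intensity)] + 1.03)
  # identity when already on reference
  same <- reference_shift(sp, observed_ref = 176.03)
  expect_equal(same$ppm, sp$ppm)
  # pairwise differences preserved to machine precision
  expect_equal(diff(ref$ppm), diff(sp$ppm), tolerance = 1e-14)
  expect_error(reference_shift(sp, observed_ref = 250), "outside")
})

test_that("pick_peaks finds isolated lines, merges close ones, tolerates flat input", {
  sp1 <- lorentzian_spectrum(114.4, 1, 0.6)
  pk1 <- pick_peaks(sp1)
  expect_equal(nrow(pk1), 1)
  step <- abs(diff(sp1$ppm[1:2]))
  expect_lt(abs(pk1$center - 114.4), step)

  # the unfolded triplet: three lines 60 Hz wide at 100.61 MHz
  sp3 <- lorentzian_spectrum(c(70.2, 68.6, 66.9), c(1, 1, 1), 60 / 100.61)
  pk3 <- pick_peaks(sp3, min_separation = 0.5)
  expect_equal(nrow(pk3), 3)
  expect_equal(sort(pk3$center), c(66.9, 68.6, 70.2), tolerance = 0.06)

  # two lines closer than min_separation collapse to the taller
  sp2 <- lorentzian_spectrum(c(100.0, 100.3), c(2, 1), 0.2)
  pk2 <- pick_peaks(sp2, min_separation = 0.8)
  expect_equal(nrow(pk2), 1)
  expect_lt(abs(pk2$center - 100.0), step)

  flat <- nmr_spectrum(seq(200, 0, length.out = 1024), rep(1, 1024))
  expect_equal(nrow(pick_peaks(flat)), 0)
})

test_that("integration matches the closed-form Lorentzian area and is linear", {
  # unit-area line, window wide enough that truncation loss < 2%
  sp <- lorentzian_spectrum(100, 1, 0.5, lo = 50, hi = 150, n = 8192)
  pk <- list(window_lo = 75, window_hi = 125)
  area <- integrate_peak(sp, pk, "area")
  # closed form: fraction of a Lorentzian within +/- w is (2/pi) atan(2w/fwhm)
  expect_equal(area, (2 / pi) * atan(2 * 25 / 0.5), tolerance = 0.005)
  expect_lt(abs(area - 1), 0.02)

  zero <- nmr_spectrum(seq(150, 50, length.out = 512), rep(0, 512))
  expect_equal(integrate_peak(zero, pk, "area"), 0)

  doubled <- sp; doubled$intensity <- 2 * doubled$intensity
  expect_equal(integrate_peak(doubled, pk, "area"), 2 * area)
  expect_equal(integrate_peak(doubled, pk, "height"),
               2 * integrate_peak(sp, pk, "height"))
  expect_error(integrate_peak(sp, list(window_lo = 300, window_hi = 310)),
               "outside")
})

test_that("area is additive over disjoint windows", {
  sp <- lorentzian_spectrum(c(80, 120), c(1, 2), 0.5, lo = 50, hi = 150,
                            n = 8192)
  whole <- integrate_peak(sp, list(window_lo = 60, window_hi = 140), "area")
  left <- integrate_peak(sp, list(window_lo = 60, window_hi = 100), "area")
  right <- integrate_peak(sp, list(window_lo = 100, window_hi = 140), "area")
  # up to one axis-step trapezoid straddling the shared endpoint
  expect_equal(left + right, whole, tolerance = 1e-4)
})

test_that("sideband flagging uses the spin-rate spacing, spares the parent, is idempotent", {
  spacing <- 9800 / 100.61                    # 97.406 ppm
  expect_equal(spacing, 97.4058, tolerance = 1e-4)
  tab <- peak_table(c("", ""), c(148.5, 148.5 - spacing),
                    c(148, 50.5), c(149, 51.7))
  tab$height <- c(10, 1)
  out <- flag_sidebands(tab, spin_rate = 9800, larmor = 100.61,
                        max_order = 1)
  expect_false(out$is_sideband[1])            # parent untouched
  expect_true(out$is_sideband[2])
  expect_equal(out$sideband_order[2], -1L)
  expect_identical(flag_sidebands(out, 9800, 100.61, max_order = 1), out)

  # spacing so large that all candidates fall off-axis: no flags
  none <- flag_sidebands(tab, spin_rate = 1e6, larmor = 100.61,
                         max_order = 1)
  expect_false(any(none$is_sideband))
})

test_that("peak table invariants are enforced", {
  expect_error(peak_table("a", 10, 11, 12), "within its window")
  expect_error(peak_table("a", 10, 11, 9), "lo < hi")
  expect_error(peak_table(c("a", "b"), c(10, 10.5), c(9, 10), c(11, 11.5)),
               "disjoint")
  # overlap-flagged windows may overlap
  tab <- peak_table(c("a", "b"), c(10, 10.5), c(9, 10), c(11, 11.5),
                    overlap_group = c(NA, "overlap"))
  expect_equal(nrow(tab), 2)
})

test_that("assignments join by nearest center within the gate", {
  picked <- peak_table(c("", ""), c(145.25, 60.0), c(144, 59), c(146, 61))
  ref <- peak_table(c("C2", "C12"), c(145.2, 59.5), c(144, 59), c(146, 60.5))
  out <- assign_peaks(picked, ref, gate = 0.5)
  expect_equal(out$assignment, c("C2", "C12"))
  far <- assign_peaks(picked, ref, gate = 0.01)
  expect_equal(far$assignment, c("", ""))
})
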