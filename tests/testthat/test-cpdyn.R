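test_that("the CP buildup/decay model evaluates to its closed form", {
  # independent arithmetic: (1 - e^-1) * e^-0.01
  expect_equal(cp_signal(1000, S0 = 1, TCH = 1000, T1rhoH = 100),
               (1 - exp(-1)) * exp(-0.01), tolerance = 1e-12)
  expect_equal(cp_signal(1000, 1, 1000, 100), 0.6258309, tolerance = 1e-6)
  expect_equal(cp_signal(0, 5, 1000, 100), 0)
  tc <- c(0, 50, 500, 5000, 50000)
  expect_equal(cp_signal(tc, 2, 1000, 100), 2 * cp_signal(tc, 1, 1000, 100))
  expect_error(cp_signal(10, 1, -5, 100), "positive")
})

test_that("the curve maximum sits at TCH * log(1 + T1rhoH/TCH)", {
  expect_equal(cp_tmax(1000, 1), 1000 * log(2))    # equal time constants
  expect_equal(cp_tmax(2420, 140), 9861.531, tolerance = 1e-6)
  expect_equal(cp_tmax(1930, 9.7), 3466.411, tolerance = 1e-6)
  expect_error(cp_tmax(0, 1), "positive")
})

test_that("the model has a single interior maximum at the closed-form point", {
  set.seed(11)
  for (i in 1:100) {
    TCH <- exp(stats::runif(1, log(50), log(8000)))
    T1 <- exp(stats::runif(1, log(2), log(300)))
    tstar <- cp_tmax(TCH, T1)
    eps <- tstar * 1e-4
    s <- cp_signal(c(tstar - eps, tstar, tstar + eps), 1, TCH, T1)
    expect_gt(s[2], s[1]); expect_gt(s[2], s[3])
    # increasing before, decreasing after, over a broad grid
    grid <- exp(seq(log(tstar / 50), log(tstar * 50), length.out = 60))
    v <- cp_signal(grid, 1, TCH, T1)
    d <- diff(v); before <- grid[-1] < tstar; after <- grid[-60] > tstar
    expect_true(all(d[before] > 0))
    expect_true(all(d[after] < 0))
  }
})

test_that("curve extraction reproduces the model and honours overlap flags", {
  tcs <- default_contact_times(12)
  spec <- sample_spec("one", carbon_site("C2", 145.2, 100, 2420, 140))
  ser <- generate_vct_series(spec, tcs, seed = 1)
  pk <- peak_table("C2", 145.2, 142, 148)
  cv <- extract_vct_curve(ser, pk)
  # areas are proportional to the model (fixed truncation fraction)
  model <- cp_signal(tcs, 100, 2420, 140)
  expect_equal(cv$intensities / cv$intensities[8], model / model[8],
               tolerance = 1e-8)

  pk_ov <- peak_table("C14", 145.2, 142, 148, overlap_group = "overlap/R")
  cv_ov <- extract_vct_curve(ser, pk_ov)
  expect_true(cv_ov$contaminated)
  expect_equal(fit_cp_dynamics(cv_ov)$status, "n.d.")
  expect_equal(fit_cp_dynamics(cv_ov, force = TRUE)$status, "ok")

  pk_out <- peak_table("x", 500, 499, 501)
  expect_error(extract_vct_curve(ser, pk_out), "outside")
})

test_that("noiseless curves are recovered to high relative accuracy", {
  tcs <- default_contact_times(24)
  for (p in list(c(100, 2420, 140), c(100, 68.1, 14.8), c(7, 1930, 9.7))) {
    cv <- vct_curve(tcs, cp_signal(tcs, p[1], p[2], p[3]))
    f <- fit_cp_dynamics(cv)
    expect_equal(f$status, "ok")
    expect_equal(f$S0, p[1], tolerance = 1e-4)
    expect_equal(f$TCH, p[2], tolerance = 1e-4)
    expect_equal(f$T1rhoH, p[3], tolerance = 1e-4)
  }
})

test_that("short or degenerate curves report n.d.", {
  tcs <- c(100, 500, 1000, 5000)
  cv <- vct_curve(tcs, cp_signal(tcs, 100, 1000, 50))
  expect_equal(fit_cp_dynamics(cv)$status, "n.d.")
  cv0 <- vct_curve(default_contact_times(8), rep(0, 8))
  expect_equal(fit_cp_dynamics(cv0)$status, "n.d.")
})

test_that("the fit is scale-equivariant in the intensities", {
  cv <- simulate_vct_curve(100, 2420, 140, noise_mult = 0.02, seed = 5)
  f1 <- fit_cp_dynamics(cv)
  cv$intensities <- cv$intensities * 37
  f2 <- fit_cp_dynamics(cv)
  expect_equal(f2$S0 / f1$S0, 37, tolerance = 1e-8)
  expect_equal(f2$TCH, f1$TCH, tolerance = 1e-8)
  expect_equal(f2$T1rhoH, f1$T1rhoH, tolerance = 1e-8)
})

test_that("a 200x200 grid search never beats the optimizer and brackets it on noiseless data", {
  tcs <- default_contact_times(24)
  sse <- function(p, y) sum((y - cp_signal(tcs, p$S0, p$TCH, p$T1rhoH))^2)

  # noiseless: the optimum must fall within one grid cell of the argmin
  y0 <- cp_signal(tcs, 100, 2420, 140)
  g0 <- grid_search_cp(tcs, y0)
  f0 <- fit_cp_dynamics(vct_curve(tcs, y0))
  expect_lte(sse(f0, y0), g0$sse + 1e-12)
  expect_lte(abs(log(f0$TCH) - log(g0$TCH)), g0$log_step_tch)
  # the SSE valley runs diagonally in (TCH, T1rhoH): the discrete argmin
  # can trade one axis against the other by up to a neighbouring cell
  expect_lte(abs(log(f0$T1rhoH) - log(g0$T1rhoH)), 2 * g0$log_step_t1)

  # noisy curves: the converged SSE is never above the grid minimum
  for (s in c(2, 9)) {
    cv <- simulate_vct_curve(100, 690, 25, noise_mult = 0.02, seed = s)
    g <- grid_search_cp(cv$contact_times, cv$intensities)
    f <- fit_cp_dynamics(cv)
    expect_lte(sse(f, cv$intensities), g$sse * (1 + 1e-10))
  }
})

test_that("parameter recovery over the reported ranges is nearly unbiased with calibrated intervals", {
  set.seed(2024)
  n_sim <- 200
  tcs <- default_contact_times(24)
  bias <- numeric(n_sim); covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    TCH <- exp(stats::runif(1, log(67.8), log(6380)))
    T1 <- exp(stats::runif(1, log(8.9), log(212)))
    y <- cp_signal(tcs, 100, TCH, T1) * (1 + stats::rnorm(24, 0, 0.02))
    f <- fit_cp_dynamics(vct_curve(tcs, y))
    bias[i] <- f$T1rhoH / T1 - 1
    covered[i] <- abs(f$T1rhoH - T1) <= f$T1rhoH_se
  }
  expect_lt(stats::median(abs(bias)), 0.03)
  expect_gte(mean(covered), 0.55)
  expect_lte(mean(covered), 0.80)
})

test_that("poorly separated timescales inflate the reported uncertainty", {
  tcs <- default_contact_times(24)
  rel_se <- function(T1, TCH) {
    v <- sapply(1:5, function(s) {
      f <- fit_cp_dynamics(simulate_vct_curve(100, TCH, T1,
                                              noise_mult = 0.02, seed = s))
      f$T1rhoH_se / f$T1rhoH
    })
    mean(v)
  }
  # timescale ratio 1 vs 12.5 at the same TCH and noise level: the
  # overlapping rise and fall correlate the parameters and widen se
  expect_gt(rel_se(2, 2000), 1.5 * rel_se(25, 2000))
})

test_that("table-level fitting mirrors the per-peak statuses", {
  specs <- default_sample_specs()
  sp <- specs[["MQ-R"]]; sp$noise_mult <- 0
  ser <- generate_vct_series(sp, default_contact_times(16), seed = 1)
  tab <- spec_peak_table(sp)
  # add an overlap-flagged row the way the aliphatic drug carbons appear
  ov <- peak_table("C14", 47.0, 45.5, 48.5, overlap_group = "overlap/R")
  ov$component <- "drug"
  tab2 <- rbind(tab, ov)
  class(tab2) <- class(tab)
  ft <- fit_sample_table(ser, tab2)
  expect_equal(nrow(ft), nrow(tab2))
  expect_equal(ft$status[nrow(ft)], "n.d.")
  expect_true(all(ft$status[ft$assignment == "C2"] == "ok"))
  expect_error(fit_sample_table(ser, tab[0, ]), "non-empty")
})
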