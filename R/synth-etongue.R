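# Synthetic impedimetric electronic-tongue data. Each class (solution) is
# described, per sensing unit, by a four-parameter log-logistic magnitude
# curve in log-frequency:
#
#   log10 |Z|(f) = log10(Z_high) + (log10(Z_low) - log10(Z_high)) /
#                  (1 + (f / f0)^slope)
#
# which is smooth and strictly decreasing from the low-frequency plateau
# Z_low to the high-frequency plateau Z_high. Replicates jitter the curve
# multiplicatively with a fixed coefficient of variation.

#' Per-class impedance curve parameters
#'
#' @param class_label class name (e.g. `"MQ"`).
#' @param z_low low-frequency plateau per sensing unit (Ohm, > 0).
#' @param z_high high-frequency plateau per sensing unit (Ohm, > 0,
#'   < `z_low`).
#' @param f0 transition frequency per unit (Hz, within 1–1e6).
#' @param slope log-logistic slope per unit (> 0).
#' @param replicate_cv replicate coefficient of variation (fraction >= 0).
#' @return an object of class `impedance_class_params`.
#' @export
impedance_class_params <- function(class_label, z_low, z_high, f0, slope,
                                   replicate_cv = 0.03) {
  n <- length(z_low)
  stopifnot(length(z_high) == n, length(f0) == n, length(slope) == n,
            all(z_low > 0), all(z_high > 0), all(z_high < z_low),
            all(f0 >= 1), all(f0 <= 1e6), all(slope > 0),
            replicate_cv >= 0)
  structure(list(class_label = class_label,
                 units = data.frame(unit = seq_len(n), z_low = z_low,
                                    z_high = z_high, f0 = f0, slope = slope),
                 replicate_cv = replicate_cv),
            class = "impedance_class_params")
}

#' Default three-class sensor-array parameterization
#'
#' Three solutions — pure drug (`MQ`), pure resin (`R`) and the resinate
#' complex (`MQ-R`) — over six sensing units. The classes sit on a line in
#' parameter space at positions 0 (MQ), 0.35 (MQ-R) and 1 (R), so the
#' complex lies between drug and resin and nearer the drug: mean-curve
#' distances obey d(MQ, MQ-R) < d(MQ-R, R) < d(MQ, R), the geometry a
#' partially taste-masked complex produces on such an array.
#'
#' @param n_units number of sensing units.
#' @param replicate_cv replicate coefficient of variation.
#' @return named list of [impedance_class_params()] for MQ, MQ-R, R.
#' @export
default_etongue_params <- function(n_units = 6, replicate_cv = 0.03) {
  u <- seq_len(n_units)
  make <- function(label, p) {
    impedance_class_params(
      label,
      z_low = 10^(6.2 - 0.9 * p + 0.08 * u),
      z_high = 10^(2.5 - 0.4 * p + 0.05 * u),
      f0 = 10^(3.0 + 0.8 * p + 0.15 * (u - mean(u))),
      slope = 0.9 + 0.1 * p + 0.03 * u,
      replicate_cv = replicate_cv)
  }
  list("MQ" = make("MQ", 0), "MQ-R" = make("MQ-R", 0.35), "R" = make("R", 1))
}

log_logistic_z <- function(f, z_low, z_high, f0, slope) {
  lhi <- log10(z_high); llo <- log10(z_low)
  10^(lhi + (llo - lhi) / (1 + (f / f0)^slope))
}

#' Generate a labelled synthetic electronic-tongue data set
#'
#' Log-spaced frequencies over 1–1e6 Hz; per class and sensing unit a
#' smooth monotone-decreasing magnitude curve, replicated with
#' multiplicative jitter of the class's `replicate_cv`.
#'
#' @param params list of [impedance_class_params()] (>= 2 classes).
#' @param n_freq number of frequencies (>= 10).
#' @param n_replicates replicates per class (>= 2).
#' @param seed integer RNG seed.
#' @param f_range frequency bounds (Hz), default `c(1, 1e6)`.
#' @return an object of class `impedance_set`: a long data frame with
#'   columns `frequency_hz`, `magnitude_ohm`, `class`, `unit`, `replicate`.
#' @export
generate_etongue_set <- function(params = default_etongue_params(),
                                 n_freq = 50, n_replicates = 3, seed = 1,
                                 f_range = c(1, 1e6)) {
  stopifnot(n_freq >= 10, n_replicates >= 2, length(params) >= 2)
  if (length(f_range) != 2 || f_range[1] <= 0 || f_range[2] <= f_range[1]) {
    stop("invalid frequency bounds", call. = FALSE)
  }
  freqs <- 10^seq(log10(f_range[1]), log10(f_range[2]), length.out = n_freq)
  set.seed(as.integer(seed))
  rows <- list()
  for (cp in params) {
    stopifnot(inherits(cp, "impedance_class_params"))
    for (rep_i in seq_len(n_replicates)) {
      for (ui in seq_len(nrow(cp$units))) {
        p <- cp$units[ui, ]
        z <- log_logistic_z(freqs, p$z_low, p$z_high, p$f0, p$slope)
        if (cp$replicate_cv > 0) {
          z <- z * (1 + stats::rnorm(length(z), 0, cp$replicate_cv))
        }
        z <- pmax(z, .Machine$double.eps)  # |Z| stays positive
        rows[[length(rows) + 1]] <- data.frame(
          frequency_hz = freqs, magnitude_ohm = z,
          class = cp$class_label, unit = p$unit, replicate = rep_i,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("impedance_set", "data.frame")
  attr(out, "frequencies") <- freqs
  out
}

#' Generate a synthetic dissolution (drug-release) trace
#'
#' The sample trace relaxes exponentially from `Z_start` to `Z_end` with
#' time constant `tau`; the paired blank trace stays at `Z_start`. Both
#' carry multiplicative noise of coefficient of variation `noise_cv`.
#'
#' @param tau release time constant (s, > 0).
#' @param Z_start,Z_end initial and asymptotic impedance magnitudes (Ohm).
#' @param duration total time (s); a warning is raised below `3 * tau`.
#' @param dt sampling interval (s, > 0).
#' @param noise_cv multiplicative noise sd (fraction).
#' @param seed integer RNG seed.
#' @return an object of class `dissolution_curve`: data frame with
#'   columns `time_s`, `z_sample_ohm`, `z_blank_ohm`.
#' @export
generate_dissolution <- function(tau = 68.1, Z_start = 753, Z_end = 827,
                                 duration = 300, dt = 1, noise_cv = 0.03,
                                 seed = 1) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (dt <= 0 || duration <= 0) {
    stop("dt and duration must be > 0", call. = FALSE)
  }
  if (duration < 3 * tau) {
    warning("duration below 3*tau: the plateau is poorly constrained")
  }
  t <- seq(0, duration, by = dt)
  set.seed(as.integer(seed))
  z <- Z_end + (Z_start - Z_end) * exp(-t / tau)
  z0 <- rep(Z_start, length(t))
  if (noise_cv > 0) {
    z <- z * (1 + stats::rnorm(length(t), 0, noise_cv))
    z0 <- z0 * (1 + stats::rnorm(length(t), 0, noise_cv))
  }
  out <- data.frame(time_s = t, z_sample_ohm = z, z_blank_ohm = z0)
  class(out) <- c("dissolution_curve", "data.frame")
  attr(out, "tau_true") <- tau
  out
}
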