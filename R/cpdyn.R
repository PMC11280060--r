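# Cross-polarization dynamics: the classical single-component CPMAS
# buildup/decay model
#
#   S(tc) = S0 * (1 - exp(-tc/TCH)) * exp(-tc/T1rhoH)
#
# with TCH the cross-polarization growth time constant (us) and T1rhoH the
# proton rotating-frame relaxation time (ms). All public interfaces take
# contact times and TCH in microseconds and T1rhoH in milliseconds — the
# units the two constants are conventionally reported in — and convert to
# a single microsecond time base internally.

US_PER_MS <- 1000

#' Cross-polarization signal at a given contact time
#'
#' @param tc contact time(s), microseconds, >= 0.
#' @param S0 equilibrium amplitude (arbitrary units).
#' @param TCH cross-polarization time constant, microseconds, > 0.
#' @param T1rhoH proton rotating-frame relaxation time, milliseconds, > 0.
#' @return signal value(s), same length as `tc`.
#' @examples
#' cp_signal(1000, S0 = 1, TCH = 1000, T1rhoH = 100) # (1 - e^-1) e^-0.01
#' @export
cp_signal <- function(tc, S0, TCH, T1rhoH) {
  if (any(TCH <= 0) || any(T1rhoH <= 0)) {
    stop("TCH and T1rhoH must be positive", call. = FALSE)
  }
  if (any(tc < 0)) stop("contact time must be >= 0", call. = FALSE)
  S0 * (1 - exp(-tc / TCH)) * exp(-tc / (T1rhoH * US_PER_MS))
}

#' Contact time of maximum signal
#'
#' The buildup/decay curve has a single interior maximum at
#' t* = TCH * log(1 + T1rhoH/TCH) (both constants on one time base); the
#' signal rises before t* and decays after it.
#'
#' @inheritParams cp_signal
#' @return t* in microseconds.
#' @examples
#' cp_tmax(TCH = 2420, T1rhoH = 140) # ~9861 us
#' @export
cp_tmax <- function(TCH, T1rhoH) {
  if (any(TCH <= 0) || any(T1rhoH <= 0)) {
    stop("TCH and T1rhoH must be positive", call. = FALSE)
  }
  TCH * log(1 + T1rhoH * US_PER_MS / TCH)
}

#' Construct a variable-contact-time intensity curve
#'
#' @param contact_times microseconds, strictly increasing.
#' @param intensities signal readouts, same length.
#' @param assignment carbon label.
#' @param center peak position (ppm).
#' @param readout_mode `"area"` or `"height"`.
#' @param contaminated logical: TRUE when the peak overlaps another
#'   component's signal and the curve should not be fitted as a single
#'   site.
#' @return an object of class `vct_curve`.
#' @export
vct_curve <- function(contact_times, intensities, assignment = "",
                      center = NA_real_, readout_mode = "area",
                      contaminated = FALSE) {
  stopifnot(length(contact_times) == length(intensities))
  if (any(diff(contact_times) <= 0)) {
    stop("contact times must be strictly increasing", call. = FALSE)
  }
  structure(list(contact_times = as.numeric(contact_times),
                 intensities = as.numeric(intensities),
                 assignment = assignment, center = center,
                 readout_mode = readout_mode,
                 contaminated = isTRUE(contaminated)),
            class = "vct_curve")
}

#' Extract a VCT curve for one peak from a spectral series
#'
#' Reads one intensity per contact time via [integrate_peak()]. Peaks
#' carrying an `overlap_group` are extracted but marked contaminated, so a
#' downstream fit reports n.d. unless forced.
#'
#' @param series a [spectrum_series].
#' @param peak one row of a [peak_table].
#' @param readout_mode `"area"` or `"height"`.
#' @return a [vct_curve].
#' @export
extract_vct_curve <- function(series, peak, readout_mode = c("area", "height")) {
  readout_mode <- match.arg(readout_mode)
  stopifnot(inherits(series, "spectrum_series"))
  vals <- vapply(series$spectra, integrate_peak, numeric(1),
                 peak = peak, mode = readout_mode)
  vct_curve(series$contact_times, vals,
            assignment = peak$assignment, center = peak$center,
            readout_mode = readout_mode,
            contaminated = !is.na(peak$overlap_group))
}

#' Fit the cross-polarization dynamics model to one curve
#'
#' Levenberg–Marquardt least squares with the analytic Jacobian of the
#' model, bounds TCH in \[1, 1e5\] us and T1rhoH in \[0.1, 1e4\] ms, and up
#' to three perturbed restarts on non-convergence. Standard errors come
#' from the asymptotic covariance at the optimum. Status is `"ok"` only
#' when the fit converged with finite covariance and a relative standard
#' error on T1rhoH below 100%; a T1rhoH at its upper bound yields
#' `"poor_fit"`; anything else (including curves with fewer than 5 points,
#' all-nonpositive intensities, or a contaminated flag) is `"n.d."`.
#'
#' @param curve a [vct_curve].
#' @param init `"auto"` or a named numeric vector `c(S0=, TCH=, T1rhoH=)`
#'   (TCH in us, T1rhoH in ms).
#' @param weighting `"uniform"` (default) or `"relative"` (residuals
#'   scaled by the model value).
#' @param force fit even when the curve is marked contaminated.
#' @return an object of class `cp_fit`: estimates, standard errors, 3x3
#'   covariance, r_squared, n_points, converged, status.
#' @export
fit_cp_dynamics <- function(curve, init = "auto",
                            weighting = c("uniform", "relative"),
                            force = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(curve, "vct_curve"))
  nd <- function(reason) {
    structure(list(S0 = NA_real_, S0_se = NA_real_,
                   TCH = NA_real_, TCH_se = NA_real_,
                   T1rhoH = NA_real_, T1rhoH_se = NA_real_,
                   covariance = matrix(NA_real_, 3, 3),
                   r_squared = NA_real_, n_points = length(curve$contact_times),
                   converged = FALSE, status = "n.d.", reason = reason,
                   assignment = curve$assignment, center = curve$center),
              class = "cp_fit")
  }
  if (curve$contaminated && !force) return(nd("overlapping signal"))
  tc <- curve$contact_times
  y <- curve$intensities
  if (length(tc) < 5) return(nd("fewer than 5 points"))
  if (all(y <= 0)) return(nd("no positive intensities"))

  start <- if (identical(init, "auto")) auto_init(tc, y) else {
    c(S0 = unname(init["S0"]), TCH = unname(init["TCH"]),
      T1rhoH = unname(init["T1rhoH"]))
  }
  lower <- c(S0 = 0, TCH = 1, T1rhoH = 0.1)
  upper <- c(S0 = Inf, TCH = 1e5, T1rhoH = 1e4)
  start <- pmin(pmax(start, lower + c(1e-9, 0, 0)), c(1e12, upper[2:3]))

  resid_fn <- function(p) {
    r <- y - cp_signal(tc, p[1], p[2], p[3])
    if (weighting == "relative") {
      r / pmax(abs(cp_signal(tc, p[1], p[2], p[3])), 1e-12 * max(abs(y)))
    } else r
  }
  jac_fn <- function(p) {
    S0 <- p[1]; TCH <- p[2]; T1 <- p[3] * US_PER_MS
    grow <- 1 - exp(-tc / TCH)
    decay <- exp(-tc / T1)
    dS0 <- grow * decay
    dTCH <- -S0 * decay * exp(-tc / TCH) * tc / TCH^2
    dT1 <- S0 * grow * decay * tc / T1^2 * US_PER_MS
    if (weighting == "relative") {
      w <- pmax(abs(S0 * grow * decay), 1e-12 * max(abs(y)))
      # treat weights as fixed at the current iterate
      return(-cbind(dS0, dTCH, dT1) / w)
    }
    -cbind(dS0, dTCH, dT1)
  }

  run_lm <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
  }
  ok_info <- function(fit) {
    !is.null(fit) && fit$info %in% 1:4
  }
  fit <- run_lm(start)
  tries <- 0
  while (!ok_info(fit) && tries < 3) {
    tries <- tries + 1
    jitter <- c(1.2, 0.7, 1.5)[tries]
    fit2 <- run_lm(pmin(pmax(start * jitter, lower + 1e-9), upper))
    if (ok_info(fit2)) fit <- fit2
  }
  if (!ok_info(fit)) return(nd("optimizer did not converge"))

  p <- unname(fit$par)
  n <- length(tc); npar <- 3
  dof <- max(n - npar, 1)
  sigma2 <- fit$deviance / dof
  covm <- tryCatch(sigma2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(covm), 0))
  fitted <- cp_signal(tc, p[1], p[2], p[3])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - fitted)^2) / ss_tot else NA_real_

  status <- "ok"
  if (any(!is.finite(covm))) status <- "n.d."
  else if (p[3] >= upper["T1rhoH"] * (1 - 1e-6)) status <- "poor_fit"
  else if (!is.finite(se[3]) || se[3] / p[3] >= 1) status <- "n.d."

  structure(list(S0 = p[1], S0_se = se[1],
                 TCH = p[2], TCH_se = se[2],
                 T1rhoH = p[3], T1rhoH_se = se[3],
                 covariance = covm, r_squared = r2, n_points = n,
                 converged = TRUE, status = status, reason = NULL,
                 assignment = curve$assignment, center = curve$center),
            class = "cp_fit")
}

# Auto-initialization: S0 from the curve maximum; TCH from the first
# half-maximum crossing on the rising limb; T1rhoH from the log-linear
# decay slope past the maximum.
auto_init <- function(tc, y) {
  imax <- which.max(y)
  S0 <- 1.1 * max(y)
  half <- y[imax] / 2
  cross <- which(y[seq_len(imax)] >= half)
  TCH <- if (length(cross)) {
    i <- cross[1]
    if (i == 1) tc[1] else {
      # linear interpolation between the bracketing points
      f <- (half - y[i - 1]) / (y[i] - y[i - 1])
      tc[i - 1] + f * (tc[i] - tc[i - 1])
    }
  } else tc[imax] / 2
  tail_idx <- which(seq_along(tc) > imax & y > 0)
  T1 <- if (length(tail_idx) >= 2) {
    sl <- stats::coef(stats::lm(log(y[tail_idx]) ~ tc[tail_idx]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl / US_PER_MS else 100
  } else 100
  c(S0 = S0, TCH = max(TCH, 1.5), T1rhoH = min(max(T1, 0.2), 9e3))
}

#' @export
print.cp_fit <- function(x, ...) {
  if (x$status == "ok" || x$status == "poor_fit") {
    cat(sprintf(
      "<cp_fit %s> S0 %.3g +/- %.2g; TCH %.4g +/- %.2g us; T1rhoH %.4g +/- %.2g ms; R2 %.4f [%s]\n",
      x$assignment, x$S0, x$S0_se, x$TCH, x$TCH_se, x$T1rhoH, x$T1rhoH_se,
      x$r_squared, x$status))
  } else {
    cat(sprintf("<cp_fit %s> n.d. (%s)\n", x$assignment,
                if (is.null(x$reason)) "" else x$reason))
  }
  invisible(x)
}

#' Fit every peak of a table against a spectral series
#'
#' Applies [extract_vct_curve()] + [fit_cp_dynamics()] per peak.
#' Overlap-flagged peaks are emitted with status `"n.d."`; per-peak
#' failures become statuses, never aborts.
#'
#' @param series a [spectrum_series].
#' @param table a [peak_table], non-empty.
#' @param readout_mode `"area"` or `"height"`.
#' @return a data frame (class `cp_fit_table`), one row per peak, ordered
#'   as the input: assignment, delta_ppm, S0, TCH_us, TCH_se, T1rhoH_ms,
#'   T1rhoH_se, r2, status, plus a `component` column if the table has one.
#' @export
fit_sample_table <- function(series, table, readout_mode = c("area", "height")) {
  readout_mode <- match.arg(readout_mode)
  stopifnot(inherits(series, "spectrum_series"))
  if (!inherits(table, "peak_table") || nrow(table) == 0) {
    stop("peak table must be non-empty", call. = FALSE)
  }
  if (length(series$spectra) == 0) stop("empty series", call. = FALSE)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    pk <- table[i, , drop = FALSE]
    fit <- tryCatch(
      fit_cp_dynamics(extract_vct_curve(series, pk, readout_mode)),
      error = function(e) NULL)
    data.frame(
      assignment = pk$assignment, delta_ppm = pk$center,
      S0 = if (is.null(fit)) NA_real_ else fit$S0,
      TCH_us = if (is.null(fit)) NA_real_ else fit$TCH,
      TCH_se = if (is.null(fit)) NA_real_ else fit$TCH_se,
      T1rhoH_ms = if (is.null(fit)) NA_real_ else fit$T1rhoH,
      T1rhoH_se = if (is.null(fit)) NA_real_ else fit$T1rhoH_se,
      r2 = if (is.null(fit)) NA_real_ else fit$r_squared,
      status = if (is.null(fit)) "n.d." else fit$status,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("component" %in% names(table)) out$component <- table$component
  class(out) <- c("cp_fit_table", "data.frame")
  out
}
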