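# Mixing-state inference: chemical-shift change/splitting analysis and
# the proton spin-diffusion criterion. In a rigid solid, fast 1H spin
# diffusion homogenizes T1rhoH over distances of several nanometers, so
# drug carbons in an intimately mixed complex relax with resin-like
# T1rhoH, while in a physical mixture each component keeps its own value.

#' Reference chemical-shift tables for the drug/resin system
#'
#' Per-carbon 13C shift lists for the pure drug in the solid state
#' (`MQ_solid`), the drug in DMSO solution (`MQ_dmso`), the resinate
#' complex (`MQ-R`, drug carbons; aliphatics buried under the resin
#' envelope are flagged `overlap/R`), and the pure resin (`R`). Several
#' centers per assignment encode unfolded signals.
#'
#' @return named list of data frames with columns `assignment`, `center`,
#'   `overlap_group`.
#' @export
default_shift_tables <- function() {
  tab <- function(assignment, center, overlap = NA_character_) {
    data.frame(assignment = assignment, center = center,
               overlap_group = rep_len(overlap, length(center)),
               stringsAsFactors = FALSE)
  }
  mq_solid <- tab(
    c("C4", "C4", "C2", "C8a", "C7", "C5", "C5", "C6", "C6", "C8", "8-CF3",
      "C4a", "2-CF3", "C3", "C11", "C12", "C12", "C14", "C14", "C15",
      "C16", "C17"),
    c(148.5, 148.1, 145.2, 143.8, 130.1, 127.1, 126.5, 125.6, 125.2, 123.1,
      122.7, 121.9, 119.0, 114.4, 67.8, 59.5, 59.0, 47.7, 47.3, 22.3,
      21.0, 21.5))
  mq_dmso <- tab(
    c("C4", "C2", "C8a", "C7", "C5", "C6", "C8", "8-CF3", "C4a", "2-CF3",
      "C3", "C11", "C12", "C14", "C15", "C16", "C17"),
    c(151.71, 147.13, 143.22, 130.39, 129.72, 128.83, 127.57, 124.12,
      126.85, 121.65, 115.84, 68.01, 59.19, 44.69, 22.02, 21.27, 21.56))
  mqr <- rbind(
    tab(c("C4", "C4", "C2", "C2", "C8a", "C8a", "C7", "C5", "C6", "C8",
          "8-CF3", "C4a", "2-CF3", "C3", "C11", "C11", "C11", "C12", "C12"),
        c(155.0, 151.6, 148.1, 147.2, 144.2, 143.3, 128.0, 128.0, 126.6,
          122.9, 122.9, 122.9, 120.0, 115.2, 70.2, 68.6, 66.9, 58.9, 58.0)),
    tab(c("C14", "C15", "C16", "C17"), c(47.0, 22.0, 21.0, 21.5),
        overlap = "overlap/R"))
  resin <- tab(
    c("C1 (CO2-K+)", "C1 (CO2-K+)", "C1'arom.", "C2'arom.", "C2'arom.",
      "CH/CH2 ~57", "CH/CH2 ~47", "C6 (CH3)"),
    c(186.5, 185.6, 148.4, 129.6, 127.8, 57, 47, 20))
  list("MQ_solid" = mq_solid, "MQ_dmso" = mq_dmso, "MQ-R" = mqr,
       "R" = resin)
}

shift_columns <- function(x) {
  if (inherits(x, "peak_table") || is.data.frame(x)) {
    stopifnot(all(c("assignment", "center") %in% names(x)))
    og <- if ("overlap_group" %in% names(x)) x$overlap_group else
      rep(NA_character_, nrow(x))
    data.frame(assignment = x$assignment, center = x$center,
               overlap_group = og, stringsAsFactors = FALSE)
  } else stop("expected a peak table or data frame", call. = FALSE)
}

#' Per-carbon chemical-shift changes between a reference and a complex
#'
#' Computes delta = (shift in complex) - (shift in reference) per
#' assignment; positive means deshielded (moved to higher frequency).
#' Assignments with equal multiplicity in both tables are paired by
#' descending-shift rank (unfolded components keep their order); with
#' unequal multiplicity each reference line is paired to the
#' nearest-center same-assignment line. Classification: `unchanged` when
#' |delta| <= `threshold`, else `deshielded`/`shielded`; `split` when the
#' complex shows more lines than the reference; `overlap` when the complex
#' entry is overlap-flagged; `new` for assignments absent from the
#' reference. Assignments present in neither table are omitted.
#'
#' @param ref,complex peak tables or data frames with `assignment`,
#'   `center` (ppm) and optionally `overlap_group`.
#' @param threshold unchanged-band half width (ppm), > 0.
#' @return data frame: `assignment`, `delta_ref`, `delta_complex`,
#'   `delta_shift`, `classification`.
#' @export
delta_shifts <- function(ref, complex, threshold = 1.0) {
  stopifnot(threshold > 0)
  rtab <- shift_columns(ref)
  ctab <- shift_columns(complex)
  out <- list()
  for (a in unique(rtab$assignment)) {
    rc <- sort(rtab$center[rtab$assignment == a], decreasing = TRUE)
    sel <- ctab$assignment == a
    cc <- ctab$center[sel]
    cov <- ctab$overlap_group[sel]
    ord <- order(cc, decreasing = TRUE)
    cc <- cc[ord]; cov <- cov[ord]
    if (length(cc) == 0) {
      message("assignment absent from complex table, omitted: ", a)
      next
    }
    split_flag <- length(cc) > length(rc)
    for (i in seq_along(rc)) {
      j <- if (length(cc) == length(rc)) i else which.min(abs(cc - rc[i]))
      delta <- cc[j] - rc[i]
      cls <- if (!is.na(cov[j])) "overlap"
      else if (split_flag) "split"
      else if (abs(delta) <= threshold) "unchanged"
      else if (delta > 0) "deshielded" else "shielded"
      out[[length(out) + 1]] <- data.frame(
        assignment = a, delta_ref = rc[i], delta_complex = cc[j],
        delta_shift = delta, classification = cls, stringsAsFactors = FALSE)
    }
  }
  new_a <- setdiff(unique(ctab$assignment), unique(rtab$assignment))
  for (a in new_a) {
    for (cc in ctab$center[ctab$assignment == a]) {
      out[[length(out) + 1]] <- data.frame(
        assignment = a, delta_ref = NA_real_, delta_complex = cc,
        delta_shift = NA_real_, classification = "new",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Signal multiplicity around each reference carbon
#'
#' For every assignment in the reference table, counts the
#' same-assignment lines lying within `window` ppm of the assignment's
#' mean reference position, in both tables — the multiplicity change that
#' reveals splitting on complexation.
#'
#' @param ref,complex peak tables or shift data frames.
#' @param window half width (ppm), > 0.
#' @return data frame: `assignment`, `multiplicity_ref`,
#'   `multiplicity_complex`.
#' @export
detect_splitting <- function(ref, complex, window = 8) {
  stopifnot(window > 0)
  rtab <- shift_columns(ref)
  ctab <- shift_columns(complex)
  res <- lapply(unique(rtab$assignment), function(a) {
    center <- mean(rtab$center[rtab$assignment == a])
    m_ref <- sum(rtab$assignment == a &
                   abs(rtab$center - center) <= window)
    m_cpx <- sum(ctab$assignment == a &
                   abs(ctab$center - center) <= window)
    data.frame(assignment = a, multiplicity_ref = m_ref,
               multiplicity_complex = m_cpx, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

usable_t1rho <- function(fits, component = NULL) {
  if (is.numeric(fits)) {
    return(data.frame(assignment = names(fits) %||% rep("", length(fits)),
                      T1rhoH_ms = unname(fits), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(fits), "T1rhoH_ms" %in% names(fits))
  ok <- if ("status" %in% names(fits)) fits$status == "ok" else
    !is.na(fits$T1rhoH_ms)
  if (!is.null(component) && "component" %in% names(fits)) {
    ok <- ok & fits$component == component
  }
  data.frame(assignment = fits$assignment[ok],
             T1rhoH_ms = fits$T1rhoH_ms[ok], stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a sample as complex or physical mixture from T1rhoH values
#'
#' Implements the spin-diffusion criterion. With medians over carbons
#' whose fits are usable (status `"ok"`): the verdict is `complex` when
#' the sample's drug-carbon median T1rhoH has dropped to at most
#' 1/`reduction_factor` of the pure drug's median AND has converged to
#' within `convergence_factor` of the sample's resin-carbon median; it is
#' `physical_mixture` when the drug median is within `reduction_factor`
#' of the pure drug AND the resin median within `reduction_factor` of the
#' pure resin (each component keeps its own relaxation); anything else —
#' including fewer than 2 usable drug fits — is `indeterminate`.
#'
#' @param sample_fits a [fit_sample_table()] result (needs a `component`
#'   column distinguishing drug and resin carbons), or a named numeric
#'   vector of drug T1rhoH values in ms (then supply `sample_resin_fits`).
#' @param pure_drug_fits,pure_resin_fits fit tables or numeric vectors of
#'   T1rhoH (ms) for the pure components.
#' @param sample_resin_fits resin-carbon values for the sample when
#'   `sample_fits` is a bare numeric vector of drug values.
#' @param convergence_factor maximum drug/resin median ratio within the
#'   sample for the complex verdict.
#' @param reduction_factor minimum fold-drop of the drug median (and the
#'   within-factor band for the mixture verdict).
#' @return an object of class `mixing_report`: values used, medians,
#'   ratios, per-rule booleans (`evidence`), and
#'   `verdict` in `{"complex", "physical_mixture", "indeterminate"}`.
#' @export
classify_mixing <- function(sample_fits, pure_drug_fits, pure_resin_fits,
                            sample_resin_fits = NULL,
                            convergence_factor = 5, reduction_factor = 2) {
  stopifnot(convergence_factor > 0, reduction_factor >= 1)
  if (is.numeric(sample_fits)) {
    drug <- usable_t1rho(sample_fits)
    resin <- usable_t1rho(sample_resin_fits %||% numeric(0))
  } else {
    drug <- usable_t1rho(sample_fits, component = "drug")
    resin <- usable_t1rho(sample_fits, component = "resin")
  }
  pure_drug <- usable_t1rho(pure_drug_fits)
  pure_resin <- usable_t1rho(pure_resin_fits)

  med <- function(x) if (nrow(x) >= 1) stats::median(x$T1rhoH_ms) else NA_real_
  m_drug <- med(drug); m_resin <- med(resin)
  m_pd <- med(pure_drug); m_pr <- med(pure_resin)

  enough <- nrow(drug) >= 2
  reduced <- enough && is.finite(m_pd) &&
    m_drug <= m_pd / reduction_factor
  converged <- enough && is.finite(m_resin) && m_resin > 0 &&
    (m_drug / m_resin) <= convergence_factor
  drug_unchanged <- enough && is.finite(m_pd) &&
    m_drug >= m_pd / reduction_factor && m_drug <= m_pd * reduction_factor
  resin_unchanged <- is.finite(m_resin) && is.finite(m_pr) &&
    m_resin >= m_pr / reduction_factor && m_resin <= m_pr * reduction_factor

  verdict <- if (!enough) "indeterminate"
  else if (reduced && converged) "complex"
  else if (drug_unchanged && resin_unchanged) "physical_mixture"
  else "indeterminate"

  structure(list(
    drug_T1rho = drug, resin_T1rho = resin, pure_drug_T1rho = pure_drug,
    summary = list(median_drug = m_drug, median_resin = m_resin,
                   median_pure_drug = m_pd, median_pure_resin = m_pr,
                   reduction_ratio = m_pd / m_drug,
                   drug_resin_ratio = m_drug / m_resin),
    evidence = list(enough_drug_fits = enough,
                    drug_T1rho_reduced = reduced,
                    drug_resin_converged = converged,
                    drug_T1rho_unchanged = drug_unchanged,
                    resin_T1rho_unchanged = resin_unchanged),
    thresholds = list(convergence_factor = convergence_factor,
                      reduction_factor = reduction_factor),
    verdict = verdict), class = "mixing_report")
}

#' @export
print.mixing_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mixing_report> verdict: %s\n", x$verdict))
  cat(sprintf("  median T1rhoH (ms): drug-in-sample %.3g | pure drug %.3g | resin-in-sample %.3g | pure resin %.3g\n",
              s$median_drug, s$median_pure_drug, s$median_resin,
              s$median_pure_resin))
  cat(sprintf("  fold reduction %.2f, drug/resin ratio %.2f\n",
              s$reduction_ratio, s$drug_resin_ratio))
  invisible(x)
}

#' Drug loading efficiency
#'
#' Percentage of the drug bound to the resin:
#' `100 * (mass_total - mass_unbound) / mass_total`.
#'
#' @param mass_total total drug mass offered (any mass unit, > 0).
#' @param mass_unbound unbound drug recovered in the supernatant (same
#'   unit, within `[0, mass_total]`).
#' @return loading efficiency in percent.
#' @export
drug_loading_efficiency <- function(mass_total, mass_unbound) {
  if (any(mass_total <= 0)) stop("mass_total must be > 0", call. = FALSE)
  if (any(mass_unbound < 0) || any(mass_unbound > mass_total)) {
    stop("mass_unbound must lie in [0, mass_total]", call. = FALSE)
  }
  100 * (mass_total - mass_unbound) / mass_total
}
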