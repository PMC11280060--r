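#' Construct a peak table
#'
#' A peak table is a data frame with one row per peak: `assignment`,
#' `center` (ppm), `window_lo`/`window_hi` (ppm, lo < hi), `is_sideband`,
#' `sideband_order` (signed integer, 0 for isotropic lines) and
#' `overlap_group` (NA, or a label such as `"overlap/R"` marking peaks
#' contaminated by another component). Duplicate assignments are allowed
#' (unfolded signals); windows of peaks not flagged as overlapping must be
#' pairwise disjoint.
#'
#' @param assignment character labels (may be empty strings, not NA).
#' @param center peak positions (ppm).
#' @param window_lo,window_hi integration window bounds (ppm).
#' @param is_sideband logical; default all FALSE.
#' @param sideband_order signed integers; 0 iff not a sideband.
#' @param overlap_group character or NA.
#' @param sample_id optional sample label stored as an attribute.
#' @return a `data.frame` of class `peak_table`.
#' @export
peak_table <- function(assignment, center, window_lo, window_hi,
                       is_sideband = FALSE, sideband_order = 0L,
                       overlap_group = NA_character_, sample_id = NULL) {
  n <- length(center)
  tab <- data.frame(
    assignment = as.character(assignment),
    center = as.numeric(center),
    window_lo = as.numeric(window_lo),
    window_hi = as.numeric(window_hi),
    is_sideband = rep_len(as.logical(is_sideband), n),
    sideband_order = rep_len(as.integer(sideband_order), n),
    overlap_group = rep_len(as.character(overlap_group), n),
    stringsAsFactors = FALSE
  )
  validate_peak_table(tab)
  class(tab) <- c("peak_table", "data.frame")
  attr(tab, "sample_id") <- sample_id
  tab
}

validate_peak_table <- function(tab) {
  if (nrow(tab) == 0) return(invisible(tab))
  if (any(is.na(tab$assignment))) {
    stop("assignments must be character, not NA", call. = FALSE)
  }
  if (any(tab$window_lo >= tab$window_hi)) {
    stop("every window must satisfy lo < hi", call. = FALSE)
  }
  if (any(tab$center < tab$window_lo | tab$center > tab$window_hi)) {
    stop("every center must lie within its window", call. = FALSE)
  }
  bad <- (tab$sideband_order == 0L) != (!tab$is_sideband)
  if (any(bad)) {
    stop("sideband_order must be 0 exactly for non-sideband peaks",
         call. = FALSE)
  }
  free <- which(is.na(tab$overlap_group))
  if (length(free) > 1) {
    o <- free[order(tab$window_lo[free])]
    if (any(tab$window_lo[o][-1] < tab$window_hi[o][-length(o)])) {
      stop("windows of non-overlap-flagged peaks must be pairwise disjoint",
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' Read a peak table from delimited text
#'
#' Expected columns: `assignment,center_ppm,window_lo,window_hi`, with an
#' optional `overlap_group` column.
#'
#' @param path file path.
#' @param sample_id optional sample label.
#' @return a [peak_table].
#' @export
read_peak_table <- function(path, sample_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("assignment", "center_ppm", "window_lo", "window_hi")
  if (!all(need %in% names(raw))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  peak_table(raw$assignment, raw$center_ppm, raw$window_lo, raw$window_hi,
             overlap_group = if ("overlap_group" %in% names(raw))
               raw$overlap_group else NA_character_,
             sample_id = sample_id)
}

#' Pick peaks in a spectrum
#'
#' Local maxima whose height exceeds `min_prominence` times the spectrum
#' maximum are kept, greedily (tallest first) enforcing a minimum
#' separation; each retained peak's window runs to the nearest flanking
#' local minima. Assignments are left empty, to be joined against a
#' reference table with [assign_peaks()].
#'
#' @param spec an [nmr_spectrum].
#' @param min_prominence height threshold as a fraction of the maximum
#'   intensity, in (0, 1).
#' @param min_separation minimum distance between reported peaks (ppm).
#' @return a [peak_table]; empty for a flat spectrum.
#' @export
pick_peaks <- function(spec, min_prominence = 0.05, min_separation = 0.5) {
  stopifnot(inherits(spec, "nmr_spectrum"),
            min_prominence > 0, min_prominence < 1, min_separation > 0)
  y <- spec$intensity
  x <- spec$ppm
  n <- length(y)
  if (diff(range(y)) == 0) {
    return(peak_table(character(0), numeric(0), numeric(0), numeric(0)))
  }
  interior <- 2:(n - 1)
  is_max <- y[interior] > y[interior - 1] & y[interior] >= y[interior + 1]
  cand <- interior[is_max & y[interior] >= min_prominence * max(y)]
  if (length(cand) == 0) {
    return(peak_table(character(0), numeric(0), numeric(0), numeric(0)))
  }
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(x[i] - x[keep]) >= min_separation)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # window bounds: nearest local minimum (or midpoint to the next kept peak)
  lo <- numeric(length(keep)); hi <- numeric(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    j <- i
    while (j > 1 && y[j - 1] <= y[j]) j <- j - 1          # towards higher ppm
    hi[k] <- x[j]
    j <- i
    while (j < n && y[j + 1] <= y[j]) j <- j + 1          # towards lower ppm
    lo[k] <- x[j]
  }
  # clip neighbouring windows at the midpoint so they stay disjoint
  if (length(keep) > 1) {
    for (k in seq_len(length(keep) - 1)) {
      mid <- (x[keep[k]] + x[keep[k + 1]]) / 2
      lo[k] <- max(lo[k], mid)
      hi[k + 1] <- min(hi[k + 1], mid)
    }
  }
  out <- peak_table(rep("", length(keep)), x[keep], lo, hi,
                    sample_id = spec$meta$sample_id)
  out$height <- y[keep]
  out
}

#' Join picked peaks to reference assignments
#'
#' Nearest-center matching with a gate: each picked peak takes the label of
#' the closest reference peak within `gate` ppm; unmatched peaks keep an
#' empty assignment.
#'
#' @param picked,reference [peak_table]s.
#' @param gate maximum center distance for a match (ppm).
#' @return `picked` with assignments filled in.
#' @export
assign_peaks <- function(picked, reference, gate = 0.5) {
  stopifnot(inherits(picked, "peak_table"), inherits(reference, "peak_table"))
  if (nrow(picked) == 0 || nrow(reference) == 0) return(picked)
  for (i in seq_len(nrow(picked))) {
    d <- abs(reference$center - picked$center[i])
    j <- which.min(d)
    if (d[j] <= gate) picked$assignment[i] <- reference$assignment[j]
  }
  picked
}

#' Integrate or read off one peak
#'
#' `area` is the trapezoidal integral of intensity over the window on the
#' ppm axis; `height` is the maximum intensity inside the window. Both are
#' deterministic functions of the spectrum.
#'
#' @param spec an [nmr_spectrum].
#' @param peak one row of a [peak_table] (or any list with `window_lo`,
#'   `window_hi`).
#' @param mode `"area"` or `"height"`.
#' @return a single intensity value.
#' @export
integrate_peak <- function(spec, peak, mode = c("area", "height")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "nmr_spectrum"))
  lo <- peak$window_lo; hi <- peak$window_hi
  rng <- range(spec$ppm)
  if (hi < rng[1] || lo > rng[2]) {
    stop(sprintf("window [%.3f, %.3f] outside axis range [%.3f, %.3f]",
                 lo, hi, rng[1], rng[2]), call. = FALSE)
  }
  idx <- which(spec$ppm >= lo & spec$ppm <= hi)
  if (length(idx) == 0) stop("window contains no axis points", call. = FALSE)
  if (mode == "height") return(max(spec$intensity[idx]))
  if (length(idx) == 1) return(0)
  x <- rev(spec$ppm[idx])        # ascending for the trapezoid sum
  y <- rev(spec$intensity[idx])
  sum(diff(x) * (head2(y, -1) + y[-1]) / 2)
}

head2 <- function(x, n) utils::head(x, n)

#' Flag spinning sidebands in a peak table
#'
#' A peak is flagged as the order-k sideband of a stronger peak when its
#' center lies within `tol` ppm of that peak's center displaced by
#' k * spin_rate / larmor ppm (1 <= |k| <= `max_order`). Strength is taken
#' from `height` if the table carries one, else stronger means earlier in
#' table order after sorting by |center distance to the candidate parent|.
#' The strongest member of a family is never flagged, and the operation is
#' idempotent.
#'
#' @param table a [peak_table]; a `height` column, if present, ranks peaks.
#' @param spin_rate MAS rate (Hz), > 0.
#' @param larmor observation frequency (MHz), > 0.
#' @param max_order largest sideband order to test.
#' @param tol matching tolerance (ppm).
#' @return the table with `is_sideband`/`sideband_order` filled in.
#' @export
flag_sidebands <- function(table, spin_rate, larmor = DEFAULT_LARMOR_MHZ,
                           max_order = 2L, tol = 0.3) {
  stopifnot(inherits(table, "peak_table"), spin_rate > 0, larmor > 0)
  if (nrow(table) < 2) return(table)
  spacing <- spin_rate / larmor # ppm
  strength <- if ("height" %in% names(table) &&
                  any(is.finite(table$height))) {
    ifelse(is.finite(table$height), table$height, -Inf)
  } else {
    rev(seq_len(nrow(table))) # no heights: earlier rows rank stronger
  }
  ord <- order(strength, decreasing = TRUE)
  flagged <- rep(FALSE, nrow(table))
  for (p in ord) {
    if (flagged[p]) next
    for (k in c(seq_len(max_order), -seq_len(max_order))) {
      target <- table$center[p] + k * spacing
      hits <- which(!flagged & abs(table$center - target) <= tol &
                      strength < strength[p])
      for (h in hits) {
        table$is_sideband[h] <- TRUE
        table$sideband_order[h] <- as.integer(sign(k) * abs(k))
        flagged[h] <- TRUE
      }
    }
  }
  table
}
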