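#' Construct a 1-D NMR spectrum object
#'
#' A spectrum is a ppm axis stored in descending order (the usual NMR
#' display convention), a matched intensity vector, and a metadata list.
#' If the supplied axis is ascending it is re-sorted descending and the
#' intensities are permuted consistently.
#'
#' @param ppm numeric chemical-shift axis (ppm), strictly monotone.
#' @param intensity numeric signal values, same length as `ppm`.
#' @param meta named list; recognised keys include `field_strength` (T),
#'   `larmor_freq` (MHz), `spin_rate` (Hz), `contact_time` (us),
#'   `recycle_delay` (s), `nucleus`, `sample_id`. Missing keys stay absent.
#' @return an object of class `nmr_spectrum` with elements `ppm`,
#'   `intensity`, `meta`.
#' @export
nmr_spectrum <- function(ppm, intensity, meta = list()) {
  if (!is.numeric(ppm) || !is.numeric(intensity)) {
    stop("ppm and intensity must be numeric", call. = FALSE)
  }
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal length", call. = FALSE)
  }
  if (length(ppm) < 2) {
    stop("invalid spectrum: fewer than 2 points", call. = FALSE)
  }
  ord <- order(ppm, decreasing = TRUE)
  ppm <- ppm[ord]
  intensity <- intensity[ord]
  if (any(diff(ppm) >= 0)) {
    stop("ppm axis must be strictly monotone (no duplicated values)",
         call. = FALSE)
  }
  if (!is.null(meta$spin_rate) && meta$spin_rate < 0) {
    stop("spin_rate must be >= 0", call. = FALSE)
  }
  if (!is.null(meta$contact_time) && meta$contact_time <= 0) {
    stop("contact_time must be > 0", call. = FALSE)
  }
  # derive the Larmor frequency from the field when only the field is given
  if (is.null(meta$larmor_freq) && !is.null(meta$field_strength)) {
    meta$larmor_freq <- carbon_larmor(meta$field_strength)
  }
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.2f .. %.2f ppm\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  if (!is.null(x$meta$contact_time)) {
    cat(sprintf("  contact time: %g us\n", x$meta$contact_time))
  }
  if (!is.null(x$meta$sample_id)) cat("  sample:", x$meta$sample_id, "\n")
  invisible(x)
}

#' @export
length.nmr_spectrum <- function(x) length(x$ppm)

#' Read a spectrum from disk
#'
#' Two dialects are supported. `csv`: two numeric columns `ppm,intensity`,
#' with optional leading `# key: value` metadata lines (numeric values are
#' converted). `jcamp`: a single-block JCAMP-DX file whose data table is
#' `##XYDATA=(X++(Y..Y))`; `##FIRSTX`, `##LASTX`, `##NPOINTS`, `##XFACTOR`
#' and `##YFACTOR` are honoured.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"jcamp"`.
#' @return an [nmr_spectrum].
#' @export
load_spectrum <- function(path, dialect = c("csv", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") read_spectrum_csv(path) else read_spectrum_jcamp(path)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  header <- grepl("^\\s*#", lines)
  for (ln in lines[header]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body_idx <- which(!header & nzchar(trimws(lines)))
  if (length(body_idx) < 2) stop("invalid spectrum: fewer than 2 points",
                                 call. = FALSE)
  ppm <- numeric(length(body_idx)); intensity <- numeric(length(body_idx))
  for (i in seq_along(body_idx)) {
    fields <- strsplit(trimws(lines[body_idx[i]]), "[,;\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (length(fields) < 2 || anyNA(vals)) {
      stop(sprintf("parse error at line %d of %s: %s",
                   body_idx[i], path, lines[body_idx[i]]), call. = FALSE)
    }
    ppm[i] <- vals[1]; intensity[i] <- vals[2]
  }
  nmr_spectrum(ppm, intensity, meta)
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    suppressWarnings(as.numeric(sub(paste0("^##", name, "="), "", hit[1])))
  }
  xy <- grep("^##XYDATA=", lines)
  if (length(xy) == 0) stop("no ##XYDATA block in ", path, call. = FALSE)
  end <- grep("^##", lines)
  end <- end[end > xy[1]]
  stop_at <- if (length(end)) end[1] - 1 else length(lines)
  data_lines <- lines[(xy[1] + 1):stop_at]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  xfac <- get_field("XFACTOR"); if (is.null(xfac) || is.na(xfac)) xfac <- 1
  yfac <- get_field("YFACTOR"); if (is.null(yfac) || is.na(yfac)) yfac <- 1
  firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
  npts <- get_field("NPOINTS")
  ys <- numeric(0); xs_start <- numeric(0)
  for (i in seq_along(data_lines)) {
    toks <- suppressWarnings(
      as.numeric(strsplit(trimws(data_lines[i]), "[[:space:]]+")[[1]]))
    if (anyNA(toks) || length(toks) < 2) {
      stop(sprintf("parse error in XYDATA at line %d of %s",
                   xy[1] + i, path), call. = FALSE)
    }
    xs_start <- c(xs_start, toks[1])
    ys <- c(ys, toks[-1])
  }
  n <- length(ys)
  if (!is.null(npts) && !is.na(npts) && npts != n) {
    warning("NPOINTS disagrees with data table; using data table length")
  }
  if (is.null(firstx) || is.null(lastx)) {
    stop("JCAMP block lacks FIRSTX/LASTX", call. = FALSE)
  }
  ppm <- seq(firstx * xfac, lastx * xfac, length.out = n)
  meta <- list()
  spin <- get_field("\\.SPINNINGRATE"); if (!is.null(spin) && !is.na(spin)) {
    meta$spin_rate <- spin
  }
  freq <- get_field("\\.OBSERVEFREQUENCY")
  if (!is.null(freq) && !is.na(freq)) meta$larmor_freq <- freq
  nmr_spectrum(ppm, ys * yfac, meta)
}

#' Write a spectrum as CSV
#'
#' Inverse of `load_spectrum(..., dialect = "csv")`: metadata as
#' `# key: value` lines followed by `ppm,intensity` rows.
#'
#' @param spec an [nmr_spectrum].
#' @param path output file.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  for (key in names(spec$meta)) {
    val <- spec$meta[[key]]
    if (is.numeric(val) || is.character(val)) {
      writeLines(sprintf("# %s: %s", key, format(val, digits = 15)), con)
    }
  }
  writeLines(sprintf("%.10g,%.10g", spec$ppm, spec$intensity), con)
  invisible(path)
}

#' Re-reference the chemical-shift axis against a standard
#'
#' Applies the rigid translation that moves an observed reference position
#' onto its true value — by default the glycine carbonyl at 176.03 ppm.
#' Intensities are untouched; the applied offset is recorded in the
#' metadata under `reference_offset`.
#'
#' @param spec an [nmr_spectrum].
#' @param observed_ref observed position of the reference line (ppm); must
#'   lie within the axis range.
#' @param true_ref true shift of the reference (ppm).
#' @return the translated [nmr_spectrum].
#' @export
reference_shift <- function(spec, observed_ref, true_ref = GLYCINE_CO_PPM) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  rng <- range(spec$ppm)
  if (observed_ref < rng[1] || observed_ref > rng[2]) {
    stop(sprintf("observed_ref %.3f ppm outside axis range [%.3f, %.3f]",
                 observed_ref, rng[1], rng[2]), call. = FALSE)
  }
  offset <- true_ref - observed_ref
  spec$ppm <- spec$ppm + offset
  spec$meta$reference_offset <- offset
  spec
}
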