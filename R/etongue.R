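# Electronic-tongue pattern recognition: feature extraction from
# impedance magnitude spectra, 2-D projection (force scheme or classical
# MDS), silhouette scoring, hierarchical clustering, and single-
# exponential dissolution-release fitting.

#' Build the sample-by-feature matrix from an impedance set
#'
#' One row per (class, replicate); features are the per-sensing-unit
#' log10|Z| vectors concatenated in unit-major, frequency-minor order.
#' `log_z_unitvar` additionally standardizes each feature to zero mean
#' and unit variance across samples (constant features are left at 0).
#'
#' @param set an `impedance_set` (long data frame, see
#'   [generate_etongue_set()]); all spectra must share one frequency grid.
#' @param normalize `"log_z_unitvar"` or `"none"`.
#' @return list with `features` (matrix, rows named `class.replicate`)
#'   and `labels` (character class per row).
#' @export
feature_matrix <- function(set, normalize = c("log_z_unitvar", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(is.data.frame(set),
            all(c("frequency_hz", "magnitude_ohm", "class", "unit",
                  "replicate") %in% names(set)))
  grids <- split(set$frequency_hz,
                 interaction(set$class, set$unit, set$replicate, drop = TRUE))
  ref_grid <- grids[[1]]
  same <- vapply(grids, function(g)
    length(g) == length(ref_grid) && isTRUE(all.equal(g, ref_grid)),
    logical(1))
  if (!all(same)) stop("spectra do not share one frequency grid",
                       call. = FALSE)
  units <- sort(unique(set$unit))
  samples <- unique(set[, c("class", "replicate")])
  samples <- samples[order(samples$class, samples$replicate), ]
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    cls <- samples$class[i]; rep_i <- samples$replicate[i]
    unlist(lapply(units, function(u) {
      sel <- set$class == cls & set$replicate == rep_i & set$unit == u
      sub <- set[sel, ]
      log10(sub$magnitude_ohm[order(sub$frequency_hz)])
    }))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste(samples$class, samples$replicate, sep = ".")
  if (normalize == "log_z_unitvar") {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    sdv[sdv == 0] <- 1
    m <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  }
  list(features = m, labels = samples$class)
}

fastmap_axis <- function(D) {
  # farthest-pair pivots, then the classical Fastmap projection
  n <- nrow(D)
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  a <- far[1]; b <- far[2]
  dab <- D[a, b]
  if (dab == 0) return(list(coord = rep(0, n), a = a, b = b))
  coord <- (D[a, ]^2 + dab^2 - D[b, ]^2) / (2 * dab)
  list(coord = coord, a = a, b = b)
}

#' Project samples to two dimensions
#'
#' `force_scheme`: a Fastmap-style initialization (two successive
#' farthest-pair pivot axes) followed by iterative refinement — each
#' sweep visits every sample in seeded random order and moves all other
#' points along their connecting directions by a step proportional to the
#' difference between the data-space and current 2-D distances. The
#' configuration with the lowest stress seen across sweeps is retained,
#' so the reported stress never increases over sweeps. `mds`: classical
#' metric scaling ([stats::cmdscale]) on the Euclidean distances.
#'
#' Stress is the normalized residual
#' `sqrt(sum((d_data - d_2d)^2) / sum(d_data^2))`; the silhouette
#' coefficient is computed on the projected coordinates with the class
#' labels.
#'
#' @param features numeric matrix (samples x features), >= 3 rows, or the
#'   list returned by [feature_matrix()].
#' @param labels class labels per row (unneeded if `features` carries
#'   them).
#' @param method `"force_scheme"` or `"mds"`.
#' @param seed integer seed for the sweep order.
#' @param sweeps refinement sweeps for the force scheme.
#' @return an object of class `projection_result`: `coords` (n x 2),
#'   `labels`, `stress`, `silhouette`, `intercluster` (Euclidean
#'   distances between class centroids in 2-D), `stress_history`,
#'   `degenerate` flag.
#' @export
project_2d <- function(features, labels = NULL,
                       method = c("force_scheme", "mds"), seed = 1,
                       sweeps = 50) {
  method <- match.arg(method)
  if (is.list(features) && !is.matrix(features)) {
    labels <- labels %||% features$labels
    features <- features$features
  }
  stopifnot(is.matrix(features), nrow(features) >= 3)
  labels <- labels %||% rownames(features)
  D <- as.matrix(stats::dist(features))
  n <- nrow(D)

  if (max(D) == 0) {
    coords <- matrix(0, n, 2)
    rownames(coords) <- rownames(features)
    return(structure(list(coords = coords, labels = labels, stress = 0,
                          silhouette = NA_real_, method = method,
                          intercluster = centroid_distances(coords, labels),
                          stress_history = 0, degenerate = TRUE),
                     class = "projection_result"))
  }

  stress_of <- function(X) {
    d2 <- as.matrix(stats::dist(X))
    lo <- lower.tri(D)
    sqrt(sum((D[lo] - d2[lo])^2) / sum(D[lo]^2))
  }

  if (method == "mds") {
    coords <- stats::cmdscale(D, k = 2)
    if (ncol(coords) < 2) coords <- cbind(coords, 0)
    history <- stress_of(coords)
  } else {
    ax1 <- fastmap_axis(D)
    res2 <- sqrt(pmax(D^2 - outer(ax1$coord, ax1$coord, "-")^2, 0))
    ax2 <- fastmap_axis(res2)
    X <- cbind(ax1$coord, ax2$coord)
    set.seed(as.integer(seed))
    lr <- 0.125
    best <- X; best_stress <- stress_of(X)
    history <- best_stress
    for (s in seq_len(sweeps)) {
      for (i in sample.int(n)) {
        diff_mat <- sweep(X, 2, X[i, ])     # vectors from i to every point
        d2d <- sqrt(rowSums(diff_mat^2))
        move <- which(d2d > 0)
        delta <- (D[i, move] - d2d[move])
        X[move, ] <- X[move, ] +
          lr * delta / d2d[move] * diff_mat[move, , drop = FALSE]
      }
      st <- stress_of(X)
      if (st < best_stress) { best <- X; best_stress <- st }
      history <- c(history, best_stress)
    }
    coords <- best
  }
  rownames(coords) <- rownames(features)
  colnames(coords) <- c("dim1", "dim2")
  sil <- silhouette_coefficient(coords, labels)
  structure(list(coords = coords, labels = labels,
                 stress = history[length(history)], silhouette = sil,
                 intercluster = centroid_distances(coords, labels),
                 method = method, stress_history = history,
                 degenerate = FALSE),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result %s> %d samples, stress %.4f, silhouette %.3f\n",
              x$method, nrow(x$coords), x$stress, x$silhouette))
  print(round(x$intercluster, 3))
  invisible(x)
}

#' Euclidean distances between class centroids
#'
#' @param coords numeric matrix of sample coordinates.
#' @param labels class per row.
#' @return symmetric matrix of centroid distances (zero diagonal).
#' @export
centroid_distances <- function(coords, labels) {
  cls <- unique(labels)
  cent <- t(vapply(cls, function(cl)
    colMeans(coords[labels == cl, , drop = FALSE]), numeric(ncol(coords))))
  m <- as.matrix(stats::dist(cent))
  dimnames(m) <- list(cls, cls)
  m
}

#' Silhouette coefficient of a labelled clustering
#'
#' Mean over samples of `(b - a) / max(a, b)`, where `a` is the mean
#' distance to the sample's own class (excluding itself) and `b` the
#' smallest mean distance to any other class. Samples in singleton
#' classes contribute 0 by convention.
#'
#' @param x sample coordinate matrix, or a `dist`/square distance matrix.
#' @param labels class labels; at least 2 classes, each non-empty.
#' @return value in \[-1, 1\].
#' @export
silhouette_coefficient <- function(x, labels) {
  D <- if (inherits(x, "dist")) as.matrix(x)
  else if (is.matrix(x) && nrow(x) == ncol(x) &&
           isTRUE(all.equal(unname(x), unname(t(x)))) && all(diag(x) == 0)) x
  else as.matrix(stats::dist(x))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least 2 classes", call. = FALSE)
  }
  n <- nrow(D)
  stopifnot(length(labels) == n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Hierarchical clustering with a class-centroid distance table
#'
#' Agglomerative clustering ([stats::hclust]) on Euclidean distances,
#' plus the Euclidean distance table between class centroids in data
#' space.
#'
#' @param features sample-by-feature matrix, or [feature_matrix()] output.
#' @param labels class labels (optional if `features` carries them).
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return list with `tree` (an `hclust`), `heights`, and
#'   `centroid_distances`.
#' @export
hca_distances <- function(features, labels = NULL,
                          linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.list(features) && !is.matrix(features)) {
    labels <- labels %||% features$labels
    features <- features$features
  }
  stopifnot(is.matrix(features), nrow(features) >= 2)
  labels <- labels %||% rownames(features)
  tree <- stats::hclust(stats::dist(features), method = linkage)
  list(tree = tree, heights = tree$height,
       centroid_distances = centroid_distances(features, labels))
}

#' Fit single-exponential release kinetics to a dissolution trace
#'
#' The derived signal — `|Z| - |Z0|` by default, or their ratio — is fit
#' with `s(t) = baseline + amplitude * (1 - exp(-t / tau))` by
#' Levenberg–Marquardt least squares. The release time reported alongside
#' tau is t95 = tau * log(20), the time to 95% of the asymptotic change.
#'
#' @param curve a `dissolution_curve` (columns `time_s`, `z_sample_ohm`,
#'   `z_blank_ohm`), >= 6 time points.
#' @param signal `"difference"` or `"ratio"`.
#' @return an object of class `release_fit`: `tau`, `tau_se`, `t95`,
#'   `amplitude`, `baseline`, `r_squared`, `converged` (FALSE, with a
#'   `reason`, for constant signals or optimizer failure).
#' @export
fit_release <- function(curve, signal = c("difference", "ratio")) {
  signal <- match.arg(signal)
  stopifnot(is.data.frame(curve),
            all(c("time_s", "z_sample_ohm", "z_blank_ohm") %in% names(curve)))
  t <- curve$time_s
  if (length(t) < 6) stop("need at least 6 time points", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time must be strictly increasing",
                              call. = FALSE)
  s <- if (signal == "difference") curve$z_sample_ohm - curve$z_blank_ohm
  else curve$z_sample_ohm / curve$z_blank_ohm

  failed <- function(reason) structure(
    list(tau = NA_real_, tau_se = NA_real_, t95 = NA_real_,
         amplitude = NA_real_, baseline = NA_real_, r_squared = NA_real_,
         converged = FALSE, reason = reason), class = "release_fit")
  if (stats::sd(s) == 0) return(failed("constant signal"))

  tail_mean <- mean(s[t >= stats::quantile(t, 0.9)])
  amp0 <- tail_mean - s[1]
  if (amp0 == 0) amp0 <- diff(range(s))
  # first crossing of 63% of the asymptotic change as a tau guess
  frac <- (s - s[1]) / amp0
  i63 <- which(frac >= 0.632)
  tau0 <- if (length(i63)) max(t[i63[1]], diff(range(t)) / 100) else
    diff(range(t)) / 3
  p0 <- c(baseline = s[1], amplitude = amp0, tau = tau0)
  resid_fn <- function(p) s - (p[1] + p[2] * (1 - exp(-t / p[3])))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn,
                       lower = c(-Inf, -Inf, 1e-9),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(failed("optimizer did not converge"))
  }
  p <- unname(fit$par)
  dof <- max(length(t) - 3, 1)
  covm <- tryCatch(fit$deviance / dof * solve(fit$hessian),
                   error = function(e) matrix(NA_real_, 3, 3))
  fitted <- p[1] + p[2] * (1 - exp(-t / p[3]))
  ss_tot <- sum((s - mean(s))^2)
  structure(list(
    tau = p[3], tau_se = sqrt(max(covm[3, 3], 0)),
    t95 = p[3] * log(20), amplitude = p[2], baseline = p[1],
    r_squared = 1 - sum((s - fitted)^2) / ss_tot,
    converged = TRUE, reason = NULL), class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<release_fit> tau %.3g +/- %.2g s; t95 %.3g s (%.2f min); R2 %.4f\n",
      x$tau, x$tau_se, x$t95, x$t95 / 60, x$r_squared))
  } else {
    cat(sprintf("<release_fit> failed: %s\n", x$reason))
  }
  invisible(x)
}
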