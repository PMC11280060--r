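# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute force, closed forms, naive double loops.

# Brute-force CP-dynamics fit: log grid over (TCH, T1rhoH) with the
# amplitude profiled out linearly at each grid node.
grid_search_cp <- function(tc, y, n_grid = 200,
                           tch_range = c(10, 1e5),
                           t1_range_ms = c(1, 1e3)) {
  tch_grid <- exp(seq(log(tch_range[1]), log(tch_range[2]),
                      length.out = n_grid))
  t1_grid <- exp(seq(log(t1_range_ms[1]), log(t1_range_ms[2]),
                     length.out = n_grid)) * 1000   # us
  best <- list(sse = Inf)
  for (tch in tch_grid) {
    grow <- 1 - exp(-tc / tch)
    for_t1 <- vapply(t1_grid, function(t1) {
      g <- grow * exp(-tc / t1)
      s0 <- sum(g * y) / sum(g * g)
      sum((y - s0 * g)^2)
    }, numeric(1))
    j <- which.min(for_t1)
    if (for_t1[j] < best$sse) {
      g <- grow * exp(-tc / t1_grid[j])
      best <- list(sse = for_t1[j], TCH = tch, T1rhoH = t1_grid[j] / 1000,
                   S0 = sum(g * y) / sum(g * g))
    }
  }
  best$log_step_tch <- diff(log(tch_range)) / (n_grid - 1)
  best$log_step_t1 <- diff(log(t1_range_ms)) / (n_grid - 1)
  best
}

# Naive silhouette: explicit pairwise Euclidean distances, explicit loops.
silhouette_brute <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dmat[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(dmat[i, same])
    b <- Inf
    for (cl in unique(labels)) {
      if (cl == labels[i]) next
      b <- min(b, mean(dmat[i, which(labels == cl)]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# One Lorentzian-line spectrum on a descending axis, amplitude = area.
lorentzian_spectrum <- function(centers, areas, fwhm_ppm,
                                lo = 0, hi = 200, n = 4096, meta = list()) {
  x <- seq(hi, lo, length.out = n)
  y <- numeric(n)
  fwhm_ppm <- rep_len(fwhm_ppm, length(centers))
  for (i in seq_along(centers)) {
    hw <- fwhm_ppm[i] / 2
    y <- y + areas[i] * (hw / pi) / ((x - centers[i])^2 + hw^2)
  }
  nmr_spectrum(x, y, meta)
}

# Printed per-carbon T1rhoH values (ms) used as classifier inputs.
table_t1rho <- function() {
  list(
    mq = c(114, 110, 140, 153, 212, 122, 119, 142, 123, 115, 117, 111,
           123, 121, 124, 117, 118),
    mqr_drug = c(57.3, 22.2, 23.2, 49.1, 35.6, 19.1, 25.1, 21.6, 32.3,
                 27.9, 22.5, 68.4, 14.8),
    mqr_resin = c(8.9, 14.8, 10.5, 9.3),
    r = c(9.7, 9.4, 9.0, 11.7))
}

# Drug carbons buried under the resin envelope in the physical mixture,
# plus resin carbons buried under drug aliphatics.
mixture_overlaps <- function() {
  c("C12", "C14", "C15", "C16", "C17",
    "CH/CH2 ~57", "CH/CH2 ~47", "C6 (CH3)")
}
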