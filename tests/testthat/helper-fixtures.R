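# Shared fixtures and independent brute-force oracles.

# A mosaic with an all-true square mask and cells at given positions (mm).
square_mosaic <- function(x, y, nucleus_area = 100, channel = "brn3a",
                          side_mm = 1, um_per_px = 10, cytoplasm_area = NA,
                          onh = c(side_mm / 2, side_mm / 2), ...) {
  n <- length(x)
  npx <- round(side_mm * 1000 / um_per_px)
  cells <- data.frame(cell_id = seq_len(n),
                      channel = rep_len(channel, n), x = x, y = y,
                      nucleus_area = rep_len(nucleus_area, n),
                      cytoplasm_area = rep_len(cytoplasm_area, n))
  retinal_mosaic(cells, matrix(TRUE, npx, npx), um_per_px, onh = onh, ...)
}

# Small healthy generator configuration used across tests.
small_params <- function(...) {
  healthy_params(retina_radius_mm = 1.2, onh_radius_mm = 0.25, ...)
}

# O(n^2) cross-NND matcher: distance filter first, then the contested-target
# exclusion, mirroring the documented rule but computed pair-by-pair.
brute_force_match <- function(brn3a, rbpms, max_distance_um = 15) {
  nb <- nrow(brn3a); nr <- nrow(rbpms)
  nn_idx <- integer(nr); nn_d <- numeric(nr)
  for (i in seq_len(nr)) {
    d <- sqrt((brn3a$x - rbpms$x[i])^2 + (brn3a$y - rbpms$y[i])^2) * 1000
    nn_idx[i] <- which.min(d)
    nn_d[i] <- min(d)
  }
  plausible <- nn_d <= max_distance_um
  n_claims <- sapply(seq_len(nb), function(j)
    sum(plausible & nn_idx == j))
  contested <- plausible & n_claims[nn_idx] > 1
  keep <- plausible & !contested
  list(brn3a_id = brn3a$cell_id[nn_idx[keep]],
       rbpms_id = rbpms$cell_id[keep],
       distance_um = nn_d[keep],
       excluded_count = sum(contested))
}

# Exhaustive pair-counting AUC: P(pos > neg) + P(pos == neg)/2.
brute_force_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force within-set nearest-neighbour distances.
brute_force_nnd <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d2 <- (x[-i] - x[i])^2 + (y[-i] - y[i])^2
    sqrt(min(d2))
  }, numeric(1))
}

# Spearman rho from the rank definition (average ranks for ties).
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sd2(rx) * sd2(ry))
}
sd2 <- function(v) sqrt(mean((v - mean(v))^2))
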