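library(data.table)

# Minimal valid point table: single-return vegetation pulses at given coords.
make_points <- function(x, y, z, class = "vegetation",
                        pulse_id = seq_along(x)) {
  data.table(x = x, y = y, z = z, return_number = 1L,
             number_of_returns = 1L, pulse_id = pulse_id,
             point_class = class)
}

# Uniform-density cloud in a disc: n per m2, heights uniform in zr.
disc_cloud <- function(radius, density, zr = c(0, 1), seed = 1,
                       truth_layer = NA_integer_, area = pi * radius^2) {
  set.seed(seed)
  n <- rpois(1, density * pi * radius^2)
  r <- radius * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  dt <- make_points(r * cos(th), r * sin(th), runif(n, zr[1], zr[2]))
  dt[, truth_layer := truth_layer]
  point_cloud(dt, height_mode = "above_ground", area = area)
}

# Two vertically separated uniform slabs with truth labels; the deeper slab
# is sparser (occlusion). Single-return pulses.
two_slab_cloud <- function(radius = 10, d1 = 8, d2 = 3,
                           z1 = c(18, 25), z2 = c(5, 10), seed = 1) {
  set.seed(seed)
  mk <- function(density, zr, lab, id0) {
    n <- rpois(1, density * pi * radius^2)
    r <- radius * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    dt <- make_points(r * cos(th), r * sin(th), runif(n, zr[1], zr[2]),
                      pulse_id = id0 + seq_len(n))
    dt[, truth_layer := lab]
    dt
  }
  dt <- rbind(mk(d1, z1, 1L, 0L), mk(d2, z2, 2L, 10^7))
  point_cloud(dt, height_mode = "above_ground", area = pi * radius^2)
}

# Histogram object straight from bin counts (25-cm lattice).
hist_from_counts <- function(counts, bin = 0.25) {
  canopystrat:::new_height_histogram(counts, bin)
}

# Brute-force maximum-total-score matching by enumeration over all
# assignments (independent oracle for the Hungarian path). Scores <= 0 mean
# "no edge". Returns the maximum achievable total score.
brute_force_max_matching <- function(s) {
  nd <- nrow(s); ns <- ncol(s)
  best <- 0
  rec <- function(i, used_cols, total) {
    if (i > nd) { best <<- max(best, total); return(invisible()) }
    rec(i + 1L, used_cols, total)                      # leave row i unmatched
    for (j in seq_len(ns)) {
      if (!used_cols[j] && s[i, j] > 0)
        rec(i + 1L, replace(used_cols, j, TRUE), total + s[i, j])
    }
  }
  rec(1L, logical(ns), 0)
  best
}

# Expected per-layer return counts for a realized pulse grid, by direct
# probability computation on the stand geometry (oracle for simulate_scan).
# For pulse with interceptions ordered top-down, the k-th interception
# yields a return with prob t^(k-1) * q * P(Binom(k-1, q) < max_returns).
enumerate_layer_expectation <- function(stand, pulses, q, t, max_returns) {
  trees <- stand$trees
  exp_by_layer <- numeric(max(trees$layer))
  for (i in seq_len(nrow(pulses))) {
    px <- pulses$x[i]; py <- pulses$y[i]
    d <- sqrt((trees$x - px)^2 + (trees$y - py)^2)
    hit <- which(d <= trees$crown_radius)
    if (!length(hit)) next
    depth <- trees$height[hit] - trees$crown_base[hit]
    ztop <- trees$height[hit] - depth * (d[hit] / trees$crown_radius[hit])^2
    ord <- hit[order(-ztop)]
    for (k in seq_along(ord)) {
      pr <- t^(k - 1) * q * pbinom(max_returns - 1L, k - 1L, q)
      exp_by_layer[trees$layer[ord[k]]] <-
        exp_by_layer[trees$layer[ord[k]]] + pr
    }
  }
  exp_by_layer
}

# Strip ground returns from a simulated flat-terrain plot -> above_ground.
normalize_sim <- function(cloud) canopystrat:::prepare_plot_cloud(cloud)
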