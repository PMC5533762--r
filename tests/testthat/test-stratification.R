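test_that("locale_histogram bins on the fixed lattice", {
  cl <- point_cloud(make_points(rep(0, 10), rep(0, 10), rep(10.1, 10)),
                    height_mode = "above_ground", area = 1)
  h <- locale_histogram(cl, c(0, 0), radius = 5)
  nz <- which(h$counts > 0)
  expect_length(nz, 1L)
  expect_equal(h$edges[nz], 10.0)        # bin [10.0, 10.25)
  expect_equal(sum(h$counts), 10)

  far <- locale_histogram(cl, c(100, 100), radius = 5)
  expect_equal(sum(far$counts), 0)

  slabs <- point_cloud(make_points(runif(100), runif(100),
                                   c(runif(50, 4.8, 5.2),
                                     runif(50, 19.8, 20.2))),
                       height_mode = "above_ground", area = 1)
  h2 <- locale_histogram(slabs, c(0.5, 0.5), radius = 2)
  occ <- rle(h2$counts > 0)
  expect_equal(sum(occ$values), 2L)      # two separated nonzero runs
})

test_that("smooth_histogram: impulse response, flatness, mass", {
  delta <- hist_from_counts(c(rep(0, 40), 100, rep(0, 40)))
  sm <- smooth_histogram(delta, sd = 2)
  expect_equal(which.max(sm$counts), 41L)
  expect_true(all(diff(sm$counts[1:41]) >= 0))
  expect_true(all(diff(sm$counts[41:81]) <= 0))
  expect_equal(sum(sm$counts), 100, tolerance = 1e-9)

  flat <- hist_from_counts(rep(7, 60))
  smf <- smooth_histogram(flat, sd = 5)
  expect_equal(smf$counts, rep(7, 60), tolerance = 1e-9)

  # mass preservation on random histograms (reflection boundary)
  set.seed(8)
  for (i in 1:20) {
    h <- hist_from_counts(rpois(sample(30:150, 1), 5))
    expect_equal(sum(smooth_histogram(h, sd = 5)$counts), sum(h$counts),
                 tolerance = 1e-6 * max(1, sum(h$counts)))
  }
})

test_that("salient_ranges finds negative-curvature runs of modes", {
  bin <- 0.25
  centres <- (seq_len(160) - 0.5) * bin
  # single discretized Gaussian: one range containing the mode, negative
  # second difference within ~1 sd of it (direct curvature oracle)
  g1 <- hist_from_counts(1000 * dnorm(centres, 20, 3))
  r1 <- salient_ranges(g1)
  expect_equal(nrow(r1), 1L)
  expect_true(r1$lower < 20 && 20 < r1$upper)
  expect_true(r1$lower <= 17.5 && r1$upper >= 22.5)

  g2 <- hist_from_counts(1000 * (dnorm(centres, 30, 2.5) +
                                   0.5 * dnorm(centres, 8, 2.5)))
  r2 <- salient_ranges(g2)
  expect_equal(nrow(r2), 2L)
  expect_gt(r2$lower[1], r2$lower[2])     # ordered top-down

  expect_equal(nrow(salient_ranges(hist_from_counts(rep(0, 50)))), 0L)
})

test_that("cell_threshold implements the midpoint rule", {
  two <- data.table(lower = c(18, 6), upper = c(25, 12))
  expect_equal(cell_threshold(two), (18 + 12) / 2)
  one <- data.table(lower = 5, upper = 12)
  expect_equal(cell_threshold(one), 0)
  none <- data.table(lower = numeric(), upper = numeric())
  expect_true(is.na(cell_threshold(none)))
})

test_that("C++ cell thresholds match the R reference path", {
  # points placed at cell centres so cell-level locale membership is exact
  bin <- 0.25
  set.seed(21)
  nx <- 9L; ny <- 9L; nbins <- 120L
  pts <- CJ(ix = 0:(nx - 1L), iy = 0:(ny - 1L))[rep(1:81, each = 30)]
  z <- c(rnorm(nrow(pts) * 0.7, 22, 1.5), rnorm(nrow(pts) * 0.3, 7, 1.5))
  z <- pmax(0, pmin(z[seq_len(nrow(pts))], nbins * bin - 0.01))
  hbin <- as.integer(floor(z / bin))
  kernel <- canopystrat:::gaussian_kernel(5 / bin)
  radius_cells <- 3.2
  thr <- canopystrat:::cell_thresholds_cpp(pts$ix, pts$iy, hbin, nx, ny,
                                           nbins, bin, radius_cells,
                                           kernel, 10L)
  # R reference for a few cells: pool cells within the radius, smooth with
  # the exported R smoother, extract ranges, apply the midpoint rule
  for (cell in list(c(5L, 5L), c(1L, 1L), c(9L, 3L))) {
    cx <- cell[1]; cy <- cell[2]
    sel <- (pts$ix - cx + 1L)^2 + (pts$iy - cy + 1L)^2 <= radius_cells^2
    counts <- tabulate(hbin[sel] + 1L, nbins)
    sm <- smooth_histogram(hist_from_counts(counts, bin), sd = 5)
    want <- cell_threshold(salient_ranges(sm))
    expect_equal(thr[cx, cy], want, tolerance = 1e-10)
  }
})

test_that("stratify recovers two slabs and respects the 4-m rule", {
  cl <- two_slab_cloud(radius = 10, seed = 31)
  layers <- stratify(cl)
  canopy <- Filter(function(l) l$is_canopy, layers)
  expect_equal(length(canopy), 2L)
  # cross-layer assignment accuracy vs truth
  correct <- sum(vapply(seq_along(canopy), function(k)
    sum(as.data.table(canopy[[k]]$points)$truth_layer == k), numeric(1)))
  expect_gte(correct / nrow(cl), 0.95)
  # densities non-increasing with depth on this occluded stand
  expect_true(diff(vapply(canopy, `[[`, numeric(1), "density")) < 0)
  # starting height of the top layer sits between the slabs
  expect_gt(canopy[[1]]$starting_height, 10)
  expect_lt(canopy[[1]]$starting_height, 18)

  low <- point_cloud(make_points(runif(500, -5, 5), runif(500, -5, 5),
                                 runif(500, 0.2, 3.0)),
                     height_mode = "above_ground", area = 100)
  low_layers <- stratify(low)
  expect_true(all(!vapply(low_layers, `[[`, logical(1), "is_canopy")))

  single <- point_cloud(make_points(runif(800, -5, 5), runif(800, -5, 5),
                                    runif(800, 15, 22)),
                        height_mode = "above_ground", area = 100)
  sl <- stratify(single)
  expect_equal(length(Filter(function(l) l$is_canopy, sl)), 1L)
  expect_equal(nrow(sl[[1]]$points), 800L)
})

test_that("stratify partitions the cloud and needs a normalized input", {
  cl <- two_slab_cloud(radius = 6, seed = 41)
  layers <- stratify(cl)
  n_total <- sum(vapply(layers, function(l) nrow(l$points), integer(1)))
  expect_equal(n_total, nrow(cl))
  # per-layer points all at or above that layer's threshold surface
  for (l in layers) {
    thr <- canopystrat:::lookup_grid(l$threshold_surface,
                                     l$points$x, l$points$y)
    expect_true(all(l$points$z >= thr))
  }
  raw <- point_cloud(make_points(1:5, 1:5, 1:5))
  expect_error(stratify(raw), "normalized")
  grounded <- point_cloud(make_points(1:5, 1:5, 1:5, class = "ground"),
                          height_mode = "above_ground", area = 25)
  expect_error(stratify(grounded), "ground")
})

test_that("stratification params are validated", {
  expect_error(stratification_params(histogram_bin = 0), "positive")
  expect_error(stratification_params(smoothing_sd = -1), "positive")
  p <- stratification_params()
  expect_equal(p$locale_min_radius, 1.5)
  expect_equal(p$min_canopy_height, 4.0)
})
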