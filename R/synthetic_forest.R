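#' Configure a synthetic multi-layer forest stand
#'
#' Describes a circular plot of a closed-canopy deciduous stand with up to
#' five vertically stacked canopy layers. Layer 1 is the overstory; deeper
#' layers hold progressively shorter (understory) trees. Defaults emulate a
#' mature mixed mesophytic stand: overstory crowns 20-30 m tall with 2-4 m
#' crown radii, each deeper layer shorter and narrower-crowned.
#'
#' @param plot_radius plot radius in metres (default 15).
#' @param n_layers number of canopy layers, 1-5.
#' @param trees_per_layer integer vector (length `n_layers`) of stem counts;
#'   the default targets a crown-area-to-ground-area ratio of 2.0 for the
#'   overstory (about 86% canopy cover under random placement, matching a
#'   closed canopy) tapering to 0.3 for the deepest layer.
#' @param layer_height_ranges list of `(min, max)` total tree heights per
#'   layer, metres, strictly decreasing with depth.
#' @param crown_shape crown solid of revolution; `"paraboloid"` (default) or
#'   `"ellipsoid"`.
#' @param crown_radius_range `(min, max)` crown radius in metres for layer 1;
#'   deeper layers shrink by 0.8 per layer.
#' @param terrain `"flat"` (ground at z = 0) or `"planar_slope"` (10% grade).
#' @param seed RNG seed for stem placement.
#' @return a `stand_config` list.
#' @export
stand_config <- function(plot_radius = 15, n_layers = 3,
                         trees_per_layer = NULL,
                         layer_height_ranges = NULL,
                         crown_shape = c("paraboloid", "ellipsoid"),
                         crown_radius_range = c(2.5, 4.5),
                         terrain = c("flat", "planar_slope"),
                         seed = 1L) {
  crown_shape <- match.arg(crown_shape)
  terrain <- match.arg(terrain)
  stopifnot(plot_radius > 0, n_layers >= 1L, n_layers <= 5L)
  if (is.null(layer_height_ranges))
    layer_height_ranges <- list(c(20, 30), c(8, 13), c(4, 6.5),
                                c(2.4, 3.8), c(1.2, 2.2))[seq_len(n_layers)]
  stopifnot(length(layer_height_ranges) == n_layers)
  mins <- vapply(layer_height_ranges, min, numeric(1))
  maxs <- vapply(layer_height_ranges, max, numeric(1))
  if (n_layers > 1L && any(maxs[-1L] >= mins[-n_layers]))
    stop("layer height ranges must be strictly decreasing with depth",
         call. = FALSE)
  if (is.null(trees_per_layer)) {
    # stems are placed over the plot plus a 5-m margin; target per-layer
    # crown-area ratios give ~86% overstory cover, thinning with depth
    area <- pi * (plot_radius + 5)^2
    cover <- c(2.0, 1.2, 0.8, 0.5, 0.3)
    r1 <- mean(crown_radius_range)
    trees_per_layer <- vapply(seq_len(n_layers), function(k) {
      rk <- r1 * 0.8^(k - 1L)
      max(3L, as.integer(round(cover[k] * area / (pi * rk^2))))
    }, integer(1))
  }
  stopifnot(length(trees_per_layer) == n_layers, all(trees_per_layer >= 1L))
  structure(list(plot_radius = plot_radius, n_layers = n_layers,
                 trees_per_layer = as.integer(trees_per_layer),
                 layer_height_ranges = layer_height_ranges,
                 crown_shape = crown_shape,
                 crown_radius_range = crown_radius_range,
                 terrain = terrain, seed = as.integer(seed)),
            class = "stand_config")
}

#' Configure a simulated LiDAR scan
#'
#' Nadir pulses on a jittered square grid. Each crown interception emits a
#' return with probability `interception_return_prob` and lets the pulse
#' continue deeper with probability `transmission_prob`; a pulse that
#' survives all crowns and has return budget left yields a ground return.
#' `transmission_prob < 1` is what produces the occlusion effect: deeper
#' layers receive geometrically fewer pulses.
#'
#' @param pulse_density pulses per square metre.
#' @param interception_return_prob probability a crown interception yields a
#'   return (default 0.9).
#' @param transmission_prob probability the pulse continues past an
#'   interception (default 0.3); must be in (0, 1) for occlusion, 0 allowed
#'   for a fully opaque canopy.
#' @param max_returns return budget per pulse (default 4).
#' @param noise_sd Gaussian ranging noise on z, metres (default 0.05).
#' @param seed RNG seed for the scan.
#' @return a `scan_config` list.
#' @export
scan_config <- function(pulse_density, interception_return_prob = 0.9,
                        transmission_prob = 0.3, max_returns = 4L,
                        noise_sd = 0.05, seed = 1L) {
  stopifnot(pulse_density > 0,
            interception_return_prob > 0, interception_return_prob <= 1,
            transmission_prob >= 0, transmission_prob < 1,
            max_returns >= 1L, noise_sd >= 0)
  structure(list(pulse_density = pulse_density,
                 interception_return_prob = interception_return_prob,
                 transmission_prob = transmission_prob,
                 max_returns = as.integer(max_returns),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scan_config")
}

terrain_elevation <- function(config, x, y) {
  if (config$terrain == "planar_slope") 0.1 * (x + config$plot_radius)
  else rep(0, length(x))
}

#' Generate a synthetic stand
#'
#' Places `trees_per_layer[k]` stems uniformly at random in the plot disc
#' plus a 5-m margin (a binomial point process — the count is fixed, the
#' pattern Poisson-like). Tree heights are uniform within the layer's height
#' range; crown depth is 25-45% of tree height (live crown confined to the
#' upper bole, as in closed stands); crown radii are uniform in
#' `crown_radius_range`, shrunk by 0.7 per layer of depth. Crown overlap is
#' permitted (closed canopy). Crown class is drawn dominant/co-dominant for
#' layer 1 and intermediate/overtopped for deeper layers.
#'
#' @param config a [stand_config()].
#' @return a `stand`: list with `trees` (one row per stem: `tree_id`, `x`,
#'   `y`, `height`, `crown_base`, `crown_radius`, `layer`, `crown_class`)
#'   and the `config`. The stem map for evaluation is [stand_stem_map()].
#' @export
generate_stand <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(config$seed)
  margin <- 5
  rmax <- config$plot_radius + margin
  rows <- lapply(seq_len(config$n_layers), function(k) {
    n <- config$trees_per_layer[k]
    # uniform in the disc of radius rmax
    rr <- rmax * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    hr <- config$layer_height_ranges[[k]]
    h <- runif(n, hr[1], hr[2])
    cr <- runif(n, config$crown_radius_range[1],
                config$crown_radius_range[2]) * 0.8^(k - 1L)
    cls <- if (k == 1L)
      sample(c("dominant", "codominant"), n, replace = TRUE, prob = c(.3, .7))
    else
      sample(c("intermediate", "overtopped"), n, replace = TRUE,
             prob = if (k == 2L) c(.7, .3) else c(.3, .7))
    data.table(x = rr * cos(th), y = rr * sin(th), height = h,
               crown_base = h * runif(n, 0.55, 0.75), crown_radius = cr,
               layer = k, crown_class = cls)
  })
  trees <- rbindlist(rows)
  trees[, tree_id := seq_len(.N)]
  setcolorder(trees, c("tree_id", "x", "y", "height", "crown_base",
                       "crown_radius", "layer", "crown_class"))
  structure(list(trees = trees, config = config), class = "stand")
}

#' @rdname generate_stand
#' @param stand a `stand` from [generate_stand()].
#' @return `stand_stem_map()`: data.table `tree_id, x, y, height_m,
#'   crown_class, layer` in the stem-map CSV dialect.
#' @export
stand_stem_map <- function(stand) {
  stand$trees[, .(tree_id, x, y, height_m = height, crown_class, layer)]
}

# Height at which a nadir ray at horizontal distance r from the stem axis
# meets the crown envelope (NA outside the crown).
crown_top_height <- function(height, crown_base, crown_radius, r,
                             shape = "paraboloid") {
  depth <- height - crown_base
  inside <- r <= crown_radius
  z <- rep(NA_real_, length(r))
  frac <- (r[inside] / crown_radius[inside])
  z[inside] <- if (shape == "paraboloid")
    height[inside] - depth[inside] * frac^2
  else
    crown_base[inside] + depth[inside] * sqrt(pmax(0, 1 - frac^2))
  z
}

#' Simulate a LiDAR scan over a stand
#'
#' Pulses are laid out on a jittered square grid covering the plot plus
#' buffer, fired at nadir, and traced top-down through the crown envelopes
#' they pierce. Interceptions are processed in decreasing height; see
#' [scan_config()] for the return/transmission model. Ground returns take
#' the terrain elevation. The output is height-normalized implicitly for
#' flat terrain (`z` is elevation; for flat terrain elevation equals height
#' above ground for vegetation returns).
#'
#' @param stand a `stand`.
#' @param scan a [scan_config()].
#' @param buffer extra metres of scanned margin beyond the plot radius
#'   (default 5, matching the stem placement margin).
#' @return a `lidar_cloud` (`height_mode = "elevation"`, `area` = plot area)
#'   with truth columns `truth_tree_id` and `truth_layer` (NA for ground
#'   returns). The realized pulse table is attached as attribute `"pulses"`.
#' @export
simulate_scan <- function(stand, scan, buffer = 5) {
  stopifnot(inherits(stand, "stand"), inherits(scan, "scan_config"))
  set.seed(scan$seed)
  half <- stand$config$plot_radius + buffer
  spacing <- 1 / sqrt(scan$pulse_density)
  gx <- seq(-half, half, by = spacing)
  grid <- CJ(px = gx, py = gx)
  np <- nrow(grid)
  pulses <- data.table(
    pulse_id = seq_len(np),
    x = grid$px + runif(np, -spacing / 2, spacing / 2),
    y = grid$py + runif(np, -spacing / 2, spacing / 2))
  trees <- stand$trees
  # all pulse-crown interceptions (vectorized per tree)
  hits <- rbindlist(lapply(seq_len(nrow(trees)), function(i) {
    tr <- trees[i]
    r <- sqrt((pulses$x - tr$x)^2 + (pulses$y - tr$y)^2)
    sel <- which(r <= tr$crown_radius)
    if (!length(sel)) return(NULL)
    data.table(pulse_id = pulses$pulse_id[sel],
               z = crown_top_height(rep(tr$height, length(sel)),
                                    rep(tr$crown_base, length(sel)),
                                    rep(tr$crown_radius, length(sel)),
                                    r[sel], stand$config$crown_shape),
               truth_tree_id = tr$tree_id, truth_layer = tr$layer)
  }))
  if (is.null(hits) || nrow(hits) == 0L)
    hits <- data.table(pulse_id = integer(), z = numeric(),
                       truth_tree_id = integer(), truth_layer = integer())
  setorder(hits, pulse_id, -z)
  # sequential survival down each pulse: reach interception k iff all
  # previous interceptions transmitted
  hits[, emit := runif(.N) < scan$interception_return_prob]
  hits[, pass := runif(.N) < scan$transmission_prob]
  hits[, reach := cumprod(c(1, head(pass, -1L))) == 1, by = pulse_id]
  hits <- hits[reach == TRUE]
  hits[, k := cumsum(emit), by = pulse_id]           # running return count
  veg <- hits[emit == TRUE & k <= scan$max_returns]
  veg[, point_class := "vegetation"]
  # ground return: pulse survived every interception it reached and has budget
  surv <- hits[, .(blocked = any(reach & !pass), nveg = sum(emit & k <= scan$max_returns)),
               by = pulse_id]
  open_pulses <- pulses[!pulses$pulse_id %in% hits$pulse_id]
  gr1 <- data.table(pulse_id = open_pulses$pulse_id, nveg = 0L)
  gr2 <- surv[blocked == FALSE & nveg < scan$max_returns, .(pulse_id, nveg)]
  ground <- rbind(gr1, gr2)
  ground <- merge(ground, pulses, by = "pulse_id")
  gz <- terrain_elevation(stand$config, ground$x, ground$y)
  gdt <- data.table(pulse_id = ground$pulse_id, z = gz,
                    truth_tree_id = NA_integer_, truth_layer = NA_integer_,
                    k = ground$nveg + 1L, point_class = "ground")
  veg <- merge(veg[, .(pulse_id, z, truth_tree_id, truth_layer, k,
                       point_class)],
               pulses, by = "pulse_id")
  # vegetation z is height above local ground; add terrain for elevation
  veg[, z := z + terrain_elevation(stand$config, x, y)]
  gdt <- merge(gdt, pulses, by = "pulse_id")
  pts <- rbind(veg, gdt)
  setorder(pts, pulse_id, -z)
  pts[, return_number := seq_len(.N), by = pulse_id]
  pts[, number_of_returns := .N, by = pulse_id]
  if (scan$noise_sd > 0) pts[, z := z + rnorm(.N, 0, scan$noise_sd)]
  pts[, in_buffer := sqrt(x^2 + y^2) > stand$config$plot_radius]
  setcolorder(pts, c("x", "y", "z", "return_number", "number_of_returns",
                     "pulse_id", "point_class", "truth_tree_id",
                     "truth_layer", "in_buffer"))
  pts$k <- NULL
  cloud <- point_cloud(pts, height_mode = "elevation",
                       area = pi * stand$config$plot_radius^2)
  setattr(cloud, "pulses", pulses)
  cloud
}

#' Simulate a sample of synthetic plots
#'
#' Generates `n_plots` independent stands and scans, cycling the layer count
#' through `layer_mix` so the sample spans simple to complex canopy
#' structures, as a closed-canopy forest survey would.
#'
#' @param n_plots number of plots.
#' @param scan_template a [scan_config()] whose seed is re-derived per plot.
#' @param layer_mix integer vector of layer counts to cycle through
#'   (default `c(1, 2, 3, 3, 4)` — most plots with 3 layers).
#' @param plot_radius plot radius, metres.
#' @param seed master seed; per-plot seeds are derived from it.
#' @return list of plots, each a list with `cloud` (truth-labelled
#'   `lidar_cloud`), `stand`, and `stem_map`.
#' @export
generate_plot_sample <- function(n_plots, scan_template,
                                 layer_mix = c(1L, 2L, 3L, 3L, 4L),
                                 plot_radius = 15, seed = 1L) {
  stopifnot(n_plots >= 1L)
  lapply(seq_len(n_plots), function(i) {
    s <- derive_seed(seed, i)
    cfg <- stand_config(plot_radius = plot_radius,
                        n_layers = layer_mix[((i - 1L) %% length(layer_mix)) + 1L],
                        seed = s)
    stand <- generate_stand(cfg)
    scan <- scan_template
    scan$seed <- derive_seed(seed, i + 1000L)
    cloud <- simulate_scan(stand, scan)
    list(cloud = cloud, stand = stand, stem_map = stand_stem_map(stand))
  })
}

# Counter-based sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
               2147483647)
}
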