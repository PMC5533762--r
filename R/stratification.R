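#' Stratification parameters
#'
#' Tunables of the canopy stratification routine. The defaults implement the
#' standard locale-histogram procedure: 25-cm height bins, a Gaussian
#' smoother with a 5-m standard deviation (wide enough to iron out the
#' vertical structure of a single crown), a locale radius of 6 grid cells
#' (about `pi * 6^2` points when the cell width equals the average
#' footprint) lower-bounded at 1.5 m, and a 4-m minimum height below which a
#' completed stratum is regarded as ground-level vegetation rather than a
#' canopy layer.
#'
#' @param histogram_bin height histogram bin width, metres (default 0.25).
#' @param smoothing_sd Gaussian smoothing standard deviation, metres
#'   (default 5).
#' @param locale_factor locale radius as a multiple of the average footprint
#'   (default 6).
#' @param locale_min_radius lower bound on the locale radius, metres
#'   (default 1.5).
#' @param min_canopy_height strata entirely below this height are not canopy
#'   layers, metres (default 4).
#' @param min_locale_points locales with fewer points are degenerate and
#'   inherit a neighbour's threshold (default 10).
#' @param max_layers safety cap on iterations (default 10).
#' @return a `stratification_params` list.
#' @export
stratification_params <- function(histogram_bin = 0.25, smoothing_sd = 5.0,
                                  locale_factor = 6, locale_min_radius = 1.5,
                                  min_canopy_height = 4.0,
                                  min_locale_points = 10L, max_layers = 10L) {
  vals <- c(histogram_bin, smoothing_sd, locale_factor, locale_min_radius,
            min_canopy_height, min_locale_points, max_layers)
  if (any(vals <= 0)) stop("all stratification parameters must be positive",
                           call. = FALSE)
  structure(list(histogram_bin = histogram_bin, smoothing_sd = smoothing_sd,
                 locale_factor = locale_factor,
                 locale_min_radius = locale_min_radius,
                 min_canopy_height = min_canopy_height,
                 min_locale_points = as.integer(min_locale_points),
                 max_layers = as.integer(max_layers)),
            class = "stratification_params")
}

new_height_histogram <- function(counts, bin) {
  structure(list(counts = as.numeric(counts), bin = bin,
                 edges = seq(0, by = bin, length.out = length(counts) + 1L)),
            class = "height_histogram")
}

#' Height histogram of a circular locale
#'
#' Bins the heights of all points within a horizontal distance `radius` of
#' `center` onto the fixed bin lattice anchored at height 0, so histograms
#' from different locales and plots share bin edges.
#'
#' @param cloud a height-normalized `lidar_cloud`.
#' @param center `(x, y)` locale centre, metres.
#' @param radius locale radius, metres.
#' @param bin bin width, metres (default 0.25).
#' @param nbins number of bins; default covers the cloud's maximum height.
#' @return a `height_histogram`: list with `counts`, `bin`, `edges`.
#' @export
locale_histogram <- function(cloud, center, radius, bin = 0.25,
                             nbins = NULL) {
  dt <- as.data.table(cloud)
  if (is.null(nbins))
    nbins <- max(1L, as.integer(ceiling((max(dt$z, 0) + 1e-9) / bin)) + 1L)
  d2 <- (dt$x - center[1])^2 + (dt$y - center[2])^2
  h <- dt$z[d2 <= radius^2]
  idx <- pmin(nbins - 1L, pmax(0L, as.integer(floor(h / bin))))
  counts <- tabulate(idx + 1L, nbins)
  new_height_histogram(counts, bin)
}

#' Gaussian-smooth a height histogram
#'
#' Discrete convolution with a Gaussian kernel of standard deviation
#' `sd / bin` bins, truncated at four standard deviations and normalized to
#' unit sum; boundary handling is half-sample reflection, which preserves
#' total mass exactly for a normalized kernel.
#'
#' @param h a `height_histogram`.
#' @param sd smoothing standard deviation in metres (default 5).
#' @return a smoothed `height_histogram`.
#' @export
smooth_histogram <- function(h, sd = 5.0) {
  stopifnot(inherits(h, "height_histogram"), sd > 0)
  k <- gaussian_kernel(sd / h$bin)
  n <- length(h$counts)
  khalf <- (length(k) - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(b) {
    idx <- fold_indices(b + seq(-khalf, khalf), n)
    sum(k * h$counts[idx])
  }, numeric(1))
  out <- new_height_histogram(sm, h$bin)
  out$smoothed <- TRUE
  out
}

gaussian_kernel <- function(sd_bins) {
  half <- max(1L, as.integer(ceiling(4 * sd_bins)))
  k <- dnorm(seq(-half, half), sd = sd_bins)
  k / sum(k)
}

# Half-sample symmetric reflection of 1-based indices into [1, n].
fold_indices <- function(j, n) {
  vapply(j, function(x) {
    while (x < 1L || x > n) {
      if (x < 1L) x <- 1L - x else x <- 2L * n + 1L - x
    }
    x
  }, numeric(1))
}

#' Salient height ranges of a smoothed histogram
#'
#' The maximal contiguous bin runs over which the discrete second difference
#' of the smoothed histogram is negative — one run per local mode, each
#' taken as one canopy layer in the locale. Boundary bins use one-sided
#' second differences. Ranges are returned top-down (highest first).
#'
#' @param h a smoothed `height_histogram`.
#' @return data.table with columns `lower`, `upper` (metres), ordered by
#'   descending `lower`; zero rows when the histogram has no curvature.
#' @export
salient_ranges <- function(h) {
  stopifnot(inherits(h, "height_histogram"))
  s <- h$counts
  n <- length(s)
  if (n < 3L) return(data.table(lower = numeric(), upper = numeric()))
  d2 <- c(s[1] - 2 * s[2] + s[3],
          s[seq_len(n - 2L)] - 2 * s[seq(2L, n - 1L)] + s[seq(3L, n)],
          s[n - 2L] - 2 * s[n - 1L] + s[n])
  neg <- d2 < 0
  if (!any(neg)) return(data.table(lower = numeric(), upper = numeric()))
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.table(lower = (starts[keep] - 1L) * h$bin,
                    upper = ends[keep] * h$bin)
  setorder(out, -lower)
  out
}

#' Stratification threshold from salient ranges
#'
#' With two or more ranges, the threshold separating the top canopy layer
#' from the rest is the midpoint between the lower edge of the top range and
#' the upper edge of the range below it. A single range means the whole
#' column is one layer (threshold 0). No ranges: `NA` — the cell
#' contributes no threshold and inherits one from its nearest neighbour.
#'
#' @param ranges data.table from [salient_ranges()], ordered top-down.
#' @return threshold height in metres, or `NA_real_`.
#' @export
cell_threshold <- function(ranges) {
  if (nrow(ranges) == 0L) return(NA_real_)
  if (nrow(ranges) == 1L) return(0)
  (ranges$lower[1] + ranges$upper[2]) / 2
}

#' Stratify a point cloud into canopy layers
#'
#' Iteratively peels the top canopy layer off a height-normalized point
#' cloud. Each iteration: (1) the cloud is binned into a horizontal grid
#' with cell width equal to the current average footprint (AFP, from the
#' density of the remaining points); (2) for every occupied cell, the height
#' histogram of a circular locale of radius `locale_factor * AFP` (lower
#' bounded at `locale_min_radius`) is smoothed and analysed for salient
#' ranges, giving a per-cell threshold ([cell_threshold()]); (3) cells
#' without a threshold inherit from the nearest resolved cell; (4) all
#' points at or above their cell's threshold are removed as the next layer,
#' and the AFP is updated from the remainder. Iteration ends when the cloud
#' is empty or `max_layers` is hit. A completed stratum entirely below
#' `min_canopy_height` is kept but flagged `is_canopy = FALSE` (ground-level
#' vegetation).
#'
#' @param cloud a `lidar_cloud` with `height_mode = "above_ground"`, ground
#'   returns excluded, and a known `area`.
#' @param params a [stratification_params()].
#' @return ordered list of `canopy_layer` objects (top layer first). Each
#'   carries `points` (a `lidar_cloud`), `order_index`, `starting_height`
#'   and `thickness` (medians over the grid cells that removed the layer),
#'   `density` (pt/m2 over the plot proper), `is_canopy`, and the
#'   `threshold_surface` (grid origin, cell size, per-cell cut heights).
#' @export
stratify <- function(cloud, params = stratification_params()) {
  if (cloud_height_mode(cloud) != "above_ground")
    stop("stratify() requires a height-normalized cloud", call. = FALSE)
  dt <- as.data.table(cloud)
  if (any(dt$point_class == "ground"))
    stop("ground returns must be excluded before stratification",
         call. = FALSE)
  area <- cloud_area(cloud)
  if (is.null(area) || is.na(area) || area <= 0)
    stop("cloud has no area; stratification needs the AFP", call. = FALSE)
  has_buffer <- "in_buffer" %in% names(dt)
  kernel_cache <- new.env(parent = emptyenv())
  layers <- list()
  remaining <- dt
  iter <- 0L
  while (nrow(remaining) > 0L && iter < params$max_layers) {
    iter <- iter + 1L
    n_core <- if (has_buffer) sum(!remaining$in_buffer) else nrow(remaining)
    pcd <- max(n_core, 1L) / area
    afp <- average_footprint(pcd)
    radius <- max(params$locale_factor * afp, params$locale_min_radius)
    thr_grid <- threshold_surface(remaining, afp, radius, params,
                                  kernel_cache)
    thr_at <- lookup_grid(thr_grid, remaining$x, remaining$y)
    removed <- remaining$z >= thr_at
    if (!any(removed)) removed <- rep(TRUE, nrow(remaining))  # terminate
    layer_pts <- remaining[removed]
    cell_stats <- data.table(thr = thr_at[removed], z = layer_pts$z,
                             cx = floor((layer_pts$x - thr_grid$origin[1]) /
                                          thr_grid$cell_size),
                             cy = floor((layer_pts$y - thr_grid$origin[2]) /
                                          thr_grid$cell_size))
    per_cell <- cell_stats[, .(start = thr[1L], thick = max(z) - thr[1L]),
                           by = .(cx, cy)]
    n_layer <- if (has_buffer) sum(!layer_pts$in_buffer) else nrow(layer_pts)
    layers[[iter]] <- structure(list(
      points = new_cloud(copy(layer_pts), "above_ground", area),
      order_index = iter,
      starting_height = median(per_cell$start),
      thickness = median(per_cell$thick),
      density = n_layer / area,
      is_canopy = max(layer_pts$z) >= params$min_canopy_height,
      threshold_surface = thr_grid), class = "canopy_layer")
    remaining <- remaining[!removed]
  }
  layers
}

#' @export
print.canopy_layer <- function(x, ...) {
  cat(sprintf(
    "<canopy_layer %d> %d points, start %.2f m, thickness %.2f m, %.2f pt/m^2%s\n",
    x$order_index, nrow(x$points), x$starting_height, x$thickness, x$density,
    if (x$is_canopy) "" else " [not canopy]"))
  invisible(x)
}

# One iteration's per-cell threshold surface. Locale membership is resolved
# at cell level (cells whose centre lies within the locale radius), which
# the C++ kernel exploits to share per-cell histograms between locales.
threshold_surface <- function(dt, afp, radius, params, kernel_cache) {
  origin <- c(floor(min(dt$x) / afp) * afp, floor(min(dt$y) / afp) * afp)
  ix <- as.integer(floor((dt$x - origin[1]) / afp))
  iy <- as.integer(floor((dt$y - origin[2]) / afp))
  nx <- max(ix) + 1L
  ny <- max(iy) + 1L
  bin <- params$histogram_bin
  nbins <- max(3L, as.integer(ceiling((max(dt$z) + 1e-9) / bin)) + 1L)
  key <- "k"
  if (is.null(kernel_cache[[key]]))
    kernel_cache[[key]] <- gaussian_kernel(params$smoothing_sd / bin)
  hbin <- pmin(nbins - 1L, pmax(0L, as.integer(floor(dt$z / bin))))
  thr <- cell_thresholds_cpp(ix, iy, hbin, nx, ny, nbins, bin,
                             radius / afp, kernel_cache[[key]],
                             params$min_locale_points)
  occupied <- matrix(FALSE, nx, ny)
  occupied[cbind(ix + 1L, iy + 1L)] <- TRUE
  need <- which(occupied & is.na(thr), arr.ind = TRUE)
  havep <- which(!is.na(thr), arr.ind = TRUE)
  if (nrow(need)) {
    if (nrow(havep) == 0L) {
      thr[need] <- 0  # no cell resolved anywhere: one final layer
    } else {
      nn <- nearest_cell_cpp(need[, 1L], need[, 2L],
                             havep[, 1L], havep[, 2L])
      thr[need] <- thr[havep[nn, , drop = FALSE]]
    }
  }
  list(origin = origin, cell_size = afp, values = thr)
}

lookup_grid <- function(grid, x, y) {
  nx <- nrow(grid$values); ny <- ncol(grid$values)
  ix <- pmax(0L, pmin(nx - 1L,
                      as.integer(floor((x - grid$origin[1]) / grid$cell_size))))
  iy <- pmax(0L, pmin(ny - 1L,
                      as.integer(floor((y - grid$origin[2]) / grid$cell_size))))
  grid$values[cbind(ix + 1L, iy + 1L)]
}
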