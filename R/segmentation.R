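# Simple surface-based individual-tree segmentation for one canopy layer:
# rasterize the layer's upper surface, seed on local maxima, grow crowns by
# descending flood fill. This is a deliberately plain stand-in for the more
# elaborate published surface-based segmenters; it exists so the density
# sweep runs end-to-end, not as a contribution of its own.

#' Rasterize the upper surface of a canopy layer
#'
#' Per-cell maximum point height, with empty cells filled by the mean of
#' their filled 8-neighbours (iterated until full) and a light 3x3 mean
#' smoothing to suppress single-point maxima.
#'
#' @param layer a `canopy_layer` or a height-normalized `lidar_cloud`.
#' @param cell raster cell size, metres.
#' @return a surface grid: list with `origin`, `cell_size`, `values`.
#' @export
rasterize_surface <- function(layer, cell = 0.5) {
  dt <- as.data.table(if (inherits(layer, "canopy_layer")) layer$points
                      else layer)
  if (nrow(dt) == 0L) stop("cannot rasterize an empty layer", call. = FALSE)
  origin <- c(floor(min(dt$x) / cell) * cell, floor(min(dt$y) / cell) * cell)
  ix <- as.integer(floor((dt$x - origin[1]) / cell))
  iy <- as.integer(floor((dt$y - origin[2]) / cell))
  nx <- max(ix) + 1L; ny <- max(iy) + 1L
  m <- matrix(NA_real_, nx, ny)
  mx <- data.table(ix = ix, iy = iy, z = dt$z)[, .(z = max(z)),
                                               by = .(ix, iy)]
  m[cbind(mx$ix + 1L, mx$iy + 1L)] <- mx$z
  observed <- !is.na(m)
  if (anyNA(m)) m <- nn_fill_grid(m)
  m <- mean_smooth_3x3(m)
  list(origin = origin, cell_size = cell, values = m, observed = observed)
}

mean_smooth_3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  if (nx < 3L || ny < 3L) return(m)
  acc <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    sx <- max(1, 1 + dx):min(nx, nx + dx)
    tx <- max(1, 1 - dx):min(nx, nx - dx)
    sy <- max(1, 1 + dy):min(ny, ny + dy)
    ty <- max(1, 1 - dy):min(ny, ny - dy)
    acc[tx, ty] <- acc[tx, ty] + m[sx, sy]
    cnt[tx, ty] <- cnt[tx, ty] + 1
  }
  acc / cnt
}

#' Detect crown apexes on a surface grid
#'
#' Local maxima (8-neighbourhood, ties kept) above `min_height`, greedily
#' thinned so no two apexes lie within `min_separation` of each other — the
#' higher apex wins. Cells that held no point before void filling never
#' seed an apex (filled plateaus would otherwise fake local maxima).
#'
#' @param grid surface grid from [rasterize_surface()].
#' @param min_height minimum apex height, metres (default 4, matching the
#'   canopy-layer minimum).
#' @param min_separation minimum apex spacing, metres (default 1.5).
#' @return data.table `apex_x`, `apex_y`, `apex_height`, ordered by
#'   descending height.
#' @export
detect_apexes <- function(grid, min_height = 4, min_separation = 1.5) {
  m <- grid$values
  nx <- nrow(m); ny <- ncol(m)
  is_max <- matrix(TRUE, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    shifted <- matrix(-Inf, nx, ny)
    sx <- max(1, 1 + dx):min(nx, nx + dx)
    tx <- max(1, 1 - dx):min(nx, nx - dx)
    sy <- max(1, 1 + dy):min(ny, ny + dy)
    ty <- max(1, 1 - dy):min(ny, ny - dy)
    shifted[tx, ty] <- m[sx, sy]
    is_max <- is_max & (m >= shifted)
  }
  if (!is.null(grid$observed)) is_max <- is_max & grid$observed
  idx <- which(is_max & m >= min_height, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.table(apex_x = numeric(), apex_y = numeric(),
                      apex_height = numeric()))
  cand <- data.table(
    apex_x = grid$origin[1] + (idx[, 1L] - 0.5) * grid$cell_size,
    apex_y = grid$origin[2] + (idx[, 2L] - 0.5) * grid$cell_size,
    apex_height = m[idx])
  setorder(cand, -apex_height, apex_x, apex_y)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1L] <- TRUE; next }
    sel <- which(keep)
    d2 <- (cand$apex_x[sel] - cand$apex_x[i])^2 +
      (cand$apex_y[sel] - cand$apex_y[i])^2
    keep[i] <- all(d2 >= min_separation^2)
  }
  cand[keep]
}

#' Grow crowns from apexes and label layer points
#'
#' Marker-based watershed-style growing: grid cells are visited in order of
#' decreasing surface height; every unlabelled cell takes the label of its
#' highest already-labelled 8-neighbour (apex cells are pre-labelled).
#' Points inherit their cell's label; points in cells below `min_height`
#' that never receive a label stay unassigned.
#'
#' @param grid surface grid from [rasterize_surface()].
#' @param apexes apex table from [detect_apexes()].
#' @param layer `canopy_layer` or `lidar_cloud` whose points are labelled.
#' @return list with `trees` (data.table `tree_id`, `apex_x`, `apex_y`,
#'   `apex_height`, `n_points`, `in_buffer`) and `labels` (per-point integer
#'   crown label, NA when unassigned). The apex reported for each tree is
#'   its highest member point.
#' @export
grow_crowns <- function(grid, apexes, layer) {
  dt <- as.data.table(if (inherits(layer, "canopy_layer")) layer$points
                      else layer)
  m <- grid$values
  nx <- nrow(m); ny <- ncol(m)
  lab <- matrix(NA_integer_, nx, ny)
  if (nrow(apexes) == 0L)
    return(list(trees = data.table(tree_id = integer(), apex_x = numeric(),
                                   apex_y = numeric(),
                                   apex_height = numeric(),
                                   n_points = integer(),
                                   in_buffer = logical()),
                labels = rep(NA_integer_, nrow(dt))))
  ax <- pmax(1L, pmin(nx, as.integer(floor((apexes$apex_x - grid$origin[1]) /
                                             grid$cell_size)) + 1L))
  ay <- pmax(1L, pmin(ny, as.integer(floor((apexes$apex_y - grid$origin[2]) /
                                             grid$cell_size)) + 1L))
  lab[cbind(ax, ay)] <- seq_len(nrow(apexes))
  ord <- order(m, decreasing = TRUE)
  for (cell in ord) {
    if (!is.na(lab[cell])) next
    ci <- ((cell - 1L) %% nx) + 1L
    cj <- ((cell - 1L) %/% nx) + 1L
    best <- NA_integer_; besth <- -Inf
    for (dx in -1:1) for (dy in -1:1) {
      qi <- ci + dx; qj <- cj + dy
      if (qi < 1L || qi > nx || qj < 1L || qj > ny) next
      l <- lab[qi, qj]
      if (!is.na(l) && m[qi, qj] > besth) { besth <- m[qi, qj]; best <- l }
    }
    lab[cell] <- best
  }
  pix <- pmax(1L, pmin(nx, as.integer(floor((dt$x - grid$origin[1]) /
                                              grid$cell_size)) + 1L))
  piy <- pmax(1L, pmin(ny, as.integer(floor((dt$y - grid$origin[2]) /
                                              grid$cell_size)) + 1L))
  plab <- lab[cbind(pix, piy)]
  assigned <- !is.na(plab)
  sub <- data.table(lab = plab[assigned], z = dt$z[assigned],
                    x = dt$x[assigned], y = dt$y[assigned],
                    in_buffer = if ("in_buffer" %in% names(dt))
                      dt$in_buffer[assigned] else FALSE)
  trees <- sub[, {
    top <- which.max(z)
    .(apex_x = x[top], apex_y = y[top], apex_height = z[top],
      n_points = .N, in_buffer = in_buffer[top])
  }, by = .(tree_id = lab)]
  setorder(trees, tree_id)
  list(trees = trees, labels = plab)
}

#' Segment one canopy layer into individual trees
#'
#' Convenience wrapper: [rasterize_surface()], [detect_apexes()],
#' [grow_crowns()]. The raster cell defaults to the larger of the layer's
#' average footprint and 0.5 m.
#'
#' @param layer a `canopy_layer` (or height-normalized `lidar_cloud` with a
#'   known area).
#' @param cell raster cell size; `NULL` for the default above.
#' @param min_height minimum apex height, metres.
#' @param min_separation minimum apex spacing, metres.
#' @return the [grow_crowns()] result.
#' @export
segment_layer <- function(layer, cell = NULL, min_height = 4,
                          min_separation = 1.5) {
  pts <- if (inherits(layer, "canopy_layer")) layer$points else layer
  if (is.null(cell)) {
    dens <- tryCatch(point_density(pts), error = function(e) NA_real_)
    cell <- if (is.na(dens) || dens <= 0) 0.5
            else max(average_footprint(dens), 0.5)
  }
  grid <- rasterize_surface(pts, cell)
  apexes <- detect_apexes(grid, min_height, min_separation)
  grow_crowns(grid, apexes, pts)
}
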