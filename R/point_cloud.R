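#' @import data.table
#' @importFrom stats median optimize rnorm runif dnorm sd setNames
#' @importFrom utils head tail
#' @useDynLib canopystrat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Columns every point table must carry; truth columns are optional.
.pc_required_cols <- c("x", "y", "z", "return_number", "number_of_returns",
                       "pulse_id", "point_class")
.pc_truth_cols <- c("truth_tree_id", "truth_layer")

#' Construct a LiDAR point cloud
#'
#' A `lidar_cloud` is a `data.table` of per-point records with two pieces of
#' metadata: `height_mode` (whether `z` is an absolute elevation or a height
#' above ground) and `area` (the footprint in square metres over which point
#' densities are computed, typically the area of a circular plot).
#'
#' Required columns: `x`, `y`, `z` (metres), `return_number`,
#' `number_of_returns` (integers, `1 <= return_number <= number_of_returns <= 4`),
#' `pulse_id` (opaque identifier shared by all returns of one pulse) and
#' `point_class` (`"ground"` or `"vegetation"`). Optional truth columns
#' `truth_tree_id` and `truth_layer` carry simulator ground truth.
#'
#' @param points data.frame or data.table of point records.
#' @param height_mode `"elevation"` (raw `z`) or `"above_ground"`
#'   (height-normalized `z`).
#' @param area footprint in m2, or `NA` if unknown. Required before any
#'   density computation.
#' @param validate check column presence and return-number invariants.
#' @return a `lidar_cloud` object.
#' @export
point_cloud <- function(points, height_mode = c("elevation", "above_ground"),
                        area = NA_real_, validate = TRUE) {
  height_mode <- match.arg(height_mode)
  dt <- as.data.table(points)
  if (validate) validate_points(dt)
  new_cloud(dt, height_mode, area)
}

# Internal constructor: rewraps a data.table without re-validating.
new_cloud <- function(dt, height_mode, area) {
  setattr(dt, "height_mode", height_mode)
  setattr(dt, "area", as.numeric(area))
  setattr(dt, "class", c("lidar_cloud", "data.table", "data.frame"))
  dt
}

validate_points <- function(dt) {
  missing_cols <- setdiff(.pc_required_cols, names(dt))
  if (length(missing_cols))
    stop("point table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(dt) == 0L) return(invisible(dt))
  rn <- dt$return_number
  nr <- dt$number_of_returns
  bad <- which(!(rn >= 1L & rn <= nr & nr <= 4L))
  if (length(bad))
    stop("invalid return numbering at row(s) ",
         paste(head(bad, 5L), collapse = ", "),
         ": need 1 <= return_number <= number_of_returns <= 4", call. = FALSE)
  if (!all(dt$point_class %in% c("ground", "vegetation")))
    stop("point_class must be 'ground' or 'vegetation'", call. = FALSE)
  # within a pulse: one number_of_returns, no duplicated return slot
  chk <- dt[, .(ok = uniqueN(number_of_returns) == 1L &&
                  !anyDuplicated(return_number)), by = pulse_id]
  if (!all(chk$ok))
    stop("pulse(s) with inconsistent return bookkeeping: ",
         paste(head(chk$pulse_id[!chk$ok], 5L), collapse = ", "), call. = FALSE)
  invisible(dt)
}

#' @export
print.lidar_cloud <- function(x, ...) {
  cat(sprintf("<lidar_cloud> %d points, %d pulses, height_mode=%s, area=%s m^2\n",
              nrow(x), uniqueN(x$pulse_id), cloud_height_mode(x),
              format(cloud_area(x))))
  if (nrow(x)) print(as.data.table(head(x, 6L)))
  invisible(x)
}

#' @rdname point_cloud
#' @param cloud a `lidar_cloud`.
#' @export
cloud_area <- function(cloud) attr(cloud, "area", exact = TRUE)

#' @rdname point_cloud
#' @export
cloud_height_mode <- function(cloud) attr(cloud, "height_mode", exact = TRUE)

#' Read a point table from CSV or LAS
#'
#' The canonical interchange format is a headered CSV with columns
#' `x,y,z,return_number,number_of_returns,pulse_id,point_class` and optional
#' `truth_tree_id,truth_layer`. LAS 1.2 (point format 1) is also supported;
#' classification code 2 maps to `"ground"`, everything else to
#' `"vegetation"`, and GPS time serves as the pulse identifier. When a CSV
#' lacks the `pulse_id` column a per-row identifier is synthesized with a
#' warning (every point then counts as a single-return pulse).
#'
#' @param path file to read.
#' @param format `"csv"` or `"las"`; default guesses from the extension.
#' @return a `lidar_cloud` with `height_mode = "elevation"`.
#' @export
read_point_table <- function(path, format = c("auto", "csv", "las")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "las") return(read_las(path))
  dt <- tryCatch(fread(path, header = TRUE),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!"pulse_id" %in% names(dt)) {
    warning("no pulse_id column; synthesizing one pulse per point")
    dt[, pulse_id := seq_len(.N)]
    if (!"return_number" %in% names(dt)) dt[, return_number := 1L]
    if (!"number_of_returns" %in% names(dt)) dt[, number_of_returns := 1L]
  }
  missing_cols <- setdiff(.pc_required_cols, names(dt))
  if (length(missing_cols))
    stop("CSV point table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  point_cloud(dt, height_mode = "elevation")
}

#' Write a point table
#'
#' @param cloud a `lidar_cloud`.
#' @param path output file.
#' @param format `"csv"` or `"las"` (LAS 1.2, point format 1, mm precision).
#' @return `path`, invisibly.
#' @export
write_point_table <- function(cloud, path, format = c("auto", "csv", "las")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "csv"
  if (format == "las") return(write_las(cloud, path))
  fwrite(as.data.table(cloud), path)
  invisible(path)
}

#' Grid a set of ground returns into a digital elevation model
#'
#' Builds a regular elevation grid over the bounding box of the ground
#' points. Each cell takes the mean elevation of the ground points falling in
#' it; cells without ground points are filled from the nearest filled cell
#' (a simplification of natural-neighbour void filling that is adequate for
#' flat-to-planar terrain).
#'
#' @param ground a `lidar_cloud` (only `point_class == "ground"` rows are
#'   used; pass a full cloud and the ground returns are selected).
#' @param cell_size grid resolution in metres (default 1).
#' @return an `elevation_grid`: list with `origin`, `cell_size`, and a
#'   `values` matrix (rows index x cells, columns y cells).
#' @export
build_dem <- function(ground, cell_size = 1.0) {
  stopifnot(cell_size > 0)
  g <- as.data.table(ground)[point_class == "ground"]
  if (nrow(g) < 3L)
    stop("need at least 3 ground points to build a DEM", call. = FALSE)
  origin <- c(floor(min(g$x)), floor(min(g$y)))
  nx <- max(1L, as.integer(floor((max(g$x) - origin[1]) / cell_size)) + 1L)
  ny <- max(1L, as.integer(floor((max(g$y) - origin[2]) / cell_size)) + 1L)
  ix <- pmin(nx - 1L, as.integer(floor((g$x - origin[1]) / cell_size)))
  iy <- pmin(ny - 1L, as.integer(floor((g$y - origin[2]) / cell_size)))
  vals <- matrix(NA_real_, nrow = nx, ncol = ny)
  means <- g[, .(m = mean(z)), by = .(ix = ix, iy = iy)]
  vals[cbind(means$ix + 1L, means$iy + 1L)] <- means$m
  if (anyNA(vals)) vals <- nn_fill_grid(vals)
  structure(list(origin = origin, cell_size = cell_size, values = vals),
            class = "elevation_grid")
}

#' Look up DEM elevation at planimetric positions
#'
#' Positions outside the grid extent are clamped to the nearest edge cell
#' (nearest-cell extrapolation).
#'
#' @param dem an `elevation_grid`.
#' @param x,y coordinate vectors (metres).
#' @return elevations in metres.
#' @export
dem_elevation <- function(dem, x, y) {
  nx <- nrow(dem$values); ny <- ncol(dem$values)
  ix <- pmax(0L, pmin(nx - 1L, as.integer(floor((x - dem$origin[1]) / dem$cell_size))))
  iy <- pmax(0L, pmin(ny - 1L, as.integer(floor((y - dem$origin[2]) / dem$cell_size))))
  dem$values[cbind(ix + 1L, iy + 1L)]
}

#' Convert elevations to heights above ground
#'
#' Subtracts the DEM elevation under each point, drops ground-class points,
#' and clamps small negative residual heights (DEM noise) to zero. Points
#' outside the DEM extent use the nearest edge cell.
#'
#' @param cloud a `lidar_cloud` with `height_mode = "elevation"`.
#' @param dem an `elevation_grid` from [build_dem()].
#' @return a `lidar_cloud` with `height_mode = "above_ground"` and ground
#'   points removed.
#' @export
normalize_heights <- function(cloud, dem) {
  if (cloud_height_mode(cloud) != "elevation")
    stop("cloud is already height-normalized", call. = FALSE)
  dt <- copy(as.data.table(cloud))[point_class != "ground"]
  if (nrow(dt)) {
    dt[, z := pmax(0, z - dem_elevation(dem, x, y))]
  }
  new_cloud(dt, "above_ground", cloud_area(cloud))
}

#' Clip a point cloud to a circular plot
#'
#' Retains points within `radius + buffer` of `center` and tags points in the
#' buffer ring (`in_buffer`). The plot `area` recorded on the result is
#' `pi * radius^2` — the buffer exists only so border tree crowns are
#' complete; buffered points do not enter density denominators.
#'
#' @param cloud a `lidar_cloud`.
#' @param center length-2 numeric `(x, y)` in metres.
#' @param radius plot radius in metres.
#' @param buffer extra ring width in metres (default 0).
#' @return a `lidar_cloud` with an `in_buffer` logical column.
#' @export
clip_circular <- function(cloud, center, radius, buffer = 0) {
  stopifnot(radius > 0, buffer >= 0, length(center) == 2L)
  dt <- as.data.table(cloud)
  d <- sqrt((dt$x - center[1])^2 + (dt$y - center[2])^2)
  keep <- d <= radius + buffer
  out <- copy(dt[keep])
  out[, in_buffer := d[keep] > radius]
  new_cloud(out, cloud_height_mode(cloud), pi * radius^2)
}

#' Point-cloud density
#'
#' Count of points divided by the recorded footprint area. With
#' `first_return_only = TRUE` only `return_number == 1` points are counted.
#' Points tagged `in_buffer` are excluded: the density refers to the plot
#' proper. PCD in this package always means the all-return density.
#'
#' @param cloud a `lidar_cloud` with known `area`.
#' @param first_return_only count only first returns.
#' @return density in points per square metre.
#' @export
point_density <- function(cloud, first_return_only = FALSE) {
  a <- cloud_area(cloud)
  if (is.null(a) || is.na(a) || a <= 0)
    stop("cloud has no area set; cannot compute a density", call. = FALSE)
  dt <- as.data.table(cloud)
  if ("in_buffer" %in% names(dt)) dt <- dt[in_buffer == FALSE]
  n <- if (first_return_only) sum(dt$return_number == 1L) else nrow(dt)
  n / a
}

# Fill NA cells of a matrix from the nearest (euclidean, cell units) non-NA
# cell. Brute force over filled cells; grids here are small.
nn_fill_grid <- function(m) {
  na_idx <- which(is.na(m), arr.ind = TRUE)
  ok_idx <- which(!is.na(m), arr.ind = TRUE)
  if (nrow(ok_idx) == 0L) stop("cannot fill an all-empty grid", call. = FALSE)
  if (nrow(na_idx) == 0L) return(m)
  near <- nearest_cell_cpp(na_idx[, 1L], na_idx[, 2L],
                           ok_idx[, 1L], ok_idx[, 2L])
  m[na_idx] <- m[ok_idx[near, , drop = FALSE]]
  m
}
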