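#' Average footprint of a point density
#'
#' The side length of a square grid cell containing on average one point:
#' `1 / sqrt(pcd)`.
#'
#' @param pcd point density in pt/m2, must be positive.
#' @return cell width in metres.
#' @export
average_footprint <- function(pcd) {
  if (any(pcd <= 0)) stop("point density must be positive", call. = FALSE)
  1 / sqrt(pcd)
}

#' Decimate a point cloud to a target density, preserving pulses
#'
#' Reproduces the density-sweep thinning protocol: bin the cloud into a
#' horizontal grid with cell width equal to the average footprint of the
#' target density, select one first-return point uniformly at random in each
#' occupied cell, and keep *all* returns of the pulses that generated the
#' selected first returns. Pulse integrity is therefore exact: a pulse is
#' either fully present or fully absent from the output. Cells containing no
#' first return contribute nothing, so the realized density can undershoot
#' the target in sparse areas.
#'
#' @param cloud a `lidar_cloud` with `pulse_id` and `return_number` set.
#' @param target_pcd desired density in pt/m2.
#' @param seed RNG seed; the same cloud, target and seed give identical
#'   output (cells are processed in deterministic order).
#' @return a `lidar_cloud` subset of `cloud`.
#' @export
decimate_to_density <- function(cloud, target_pcd, seed = 1L) {
  stopifnot(target_pcd > 0)
  dt <- as.data.table(cloud)
  if (!all(c("pulse_id", "return_number") %in% names(dt)))
    stop("decimation requires pulse_id and return_number", call. = FALSE)
  afp <- average_footprint(target_pcd)
  ox <- floor(min(dt$x)); oy <- floor(min(dt$y))
  fr <- dt[return_number == 1L]
  if (nrow(fr) == 0L)
    return(new_cloud(dt[0L], cloud_height_mode(cloud), cloud_area(cloud)))
  fr[, cell := paste(floor((x - ox) / afp), floor((y - oy) / afp))]
  setorder(fr, cell, pulse_id)          # deterministic order before sampling
  set.seed(seed)
  picked <- fr[, .(pulse_id = pulse_id[sample.int(.N, 1L)]), by = cell]
  keep <- unique(picked$pulse_id)
  out <- dt[pulse_id %in% keep]
  new_cloud(copy(out), cloud_height_mode(cloud), cloud_area(cloud))
}
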