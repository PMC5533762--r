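#' Fraction survey: stratify many plots and fit the occlusion model
#'
#' For every plot: stratify, record the canopy-layer point fractions padded
#' with zeros to `max_n` ([layer_fractions()]), then fit the
#' logarithmic-series model to all `(n, p_n)` pairs pooled over plots.
#' Plots that yield no canopy layer are excluded from the fit (they carry no
#' information about the layer-fraction decay).
#'
#' @param plots list of height-normalized `lidar_cloud`s (ground excluded)
#'   with known areas, or of plot lists as from [generate_plot_sample()].
#' @param params a [stratification_params()].
#' @param max_n pad fractions to this many layers (default 5).
#' @return list with `samples` (pooled fraction table), `model`
#'   (`log_series_model`) and `layers_per_plot`.
#' @export
run_fraction_survey <- function(plots, params = stratification_params(),
                                max_n = 5L) {
  clouds <- lapply(plots, function(p) if (is.list(p) && !is.null(p$cloud))
    p$cloud else p)
  res <- lapply(seq_along(clouds), function(i) {
    cl <- clouds[[i]]
    layers <- stratify(cl, params)
    n_canopy <- sum(vapply(layers, function(l) isTRUE(l$is_canopy),
                           logical(1)))
    smp <- if (n_canopy > 0L)
      layer_fractions(layers, point_density(cl), max_n, plot_id = i)
    else NULL
    list(samples = smp, n_canopy = n_canopy)
  })
  samples <- rbindlist(lapply(res, `[[`, "samples"))
  if (nrow(samples) == 0L)
    stop("no plot produced a canopy layer; cannot fit", call. = FALSE)
  list(samples = samples, model = fit_log_series(samples),
       layers_per_plot = vapply(res, `[[`, integer(1), "n_canopy"))
}

# height-normalize a simulated plot cloud for flat terrain: drop ground
# returns (z of vegetation returns already equals height above ground)
prepare_plot_cloud <- function(cloud) {
  dt <- as.data.table(cloud)[point_class != "ground"]
  dt[, z := pmax(0, z)]
  new_cloud(dt, "above_ground", cloud_area(cloud))
}

#' Density sweep: segmentation accuracy versus point-cloud density
#'
#' Runs the density experiment on truth-labelled plots: for every target
#' density, decimate the plot ([decimate_to_density()]), stratify, segment
#' each canopy layer ([segment_layer()]), and evaluate detections against
#' the stem map ([match_trees()]), separately for the overstory (detections
#' from layer 1 vs layer-1 stems) and the understory (detections from
#' deeper layers vs deeper stems). Results are averaged across plots.
#'
#' @param plots list of plot lists (`cloud` with truth labels, `stem_map`
#'   with a `layer` column) as from [generate_plot_sample()].
#' @param densities target densities, pt/m2.
#' @param seed master seed; per-plot, per-density decimation seeds are
#'   derived from it, so results are reproducible under any loop order.
#' @param params a [stratification_params()].
#' @param buffer buffer-ring width used for the commission rule, metres
#'   (default 4.7).
#' @param min_height minimum apex height passed to the segmenter; default 2
#'   so short understory stems remain detectable.
#' @return a data.table (`sweep_result`): one row per `(target_pcd,
#'   stratum)` with mean `recall`, `precision`, `f_score` and `n_plots`.
#'   Per-plot rows are attached as attribute `"per_plot"`.
#' @export
run_density_sweep <- function(plots, densities, seed = 1L,
                              params = stratification_params(),
                              buffer = 4.7, min_height = 2) {
  rows <- list()
  for (pi in seq_along(plots)) {
    plot <- plots[[pi]]
    cloud <- prepare_plot_cloud(plot$cloud)
    src_pcd <- point_density(cloud)
    # evaluate against in-plot stems only; margin stems exist to complete
    # border crowns, as a field stem map would
    plot_radius <- sqrt(cloud_area(cloud) / pi)
    stems <- as.data.table(plot$stem_map)
    stems <- stems[sqrt(x^2 + y^2) <= plot_radius]
    for (di in seq_along(densities)) {
      target <- densities[di]
      if (target > src_pcd) {
        message(sprintf("plot %d: target %.1f pt/m^2 exceeds source %.1f; skipped",
                        pi, target, src_pcd))
        next
      }
      dec <- decimate_to_density(cloud, target,
                                 seed = derive_seed(seed, pi * 1000L + di))
      layers <- stratify(dec, params)
      layers <- Filter(function(l) isTRUE(l$is_canopy), layers)
      dets <- rbindlist(lapply(seq_along(layers), function(k) {
        tr <- segment_layer(layers[[k]], min_height = min_height)$trees
        if (nrow(tr)) tr[, layer := k]
        tr
      }), fill = TRUE)
      for (stratum in c("overstory", "understory")) {
        st <- if (stratum == "overstory") stems[layer == 1L]
              else stems[layer >= 2L]
        dt <- if (nrow(dets) == 0L) dets
              else if (stratum == "overstory") dets[layer == 1L]
              else dets[layer >= 2L]
        if (nrow(st) == 0L) next
        m <- match_trees(dt, st)
        sc <- accuracy_scores(m)
        rows[[length(rows) + 1L]] <- data.table(
          plot = pi, target_pcd = target, stratum = stratum,
          recall = sc$recall, precision = sc$precision,
          f_score = sc$f_score, mt = m$mt, oe = m$oe, ce = m$ce)
      }
    }
  }
  per_plot <- rbindlist(rows)
  if (nrow(per_plot) == 0L) stop("density sweep produced no results",
                                 call. = FALSE)
  out <- per_plot[, .(recall = mean(recall, na.rm = TRUE),
                      precision = mean(precision, na.rm = TRUE),
                      f_score = mean(f_score, na.rm = TRUE),
                      n_plots = .N),
                  by = .(target_pcd, stratum)]
  setorder(out, target_pcd, stratum)
  setattr(out, "per_plot", per_plot)
  setattr(out, "class", c("sweep_result", class(out)))
  out
}
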