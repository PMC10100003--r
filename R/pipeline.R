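# End-to-end orchestration: synthetic scene -> L-VOD stream -> filtered
# annual indices -> calibrated AGC series -> land-cover engine -> bookkeeping
# fluxes -> trends and comparison statistics.

#' AGC grid from the scene's true density series
#'
#' The zero-observation-noise limit of the retrieval: the true per-cell AGC
#' density series cast into the AGC-grid schema (agc_sd = 0, nothing
#' masked). Used to exercise the bookkeeping and residual attribution
#' independently of the satellite limb.
#'
#' @param scene A [generate_scene()] result.
#' @return AGC grid data.table (cell_id, year, agc_mean, agc_sd, masked).
#' @export
truth_agc_grid <- function(scene) {
  g <- scene$truth$agc_density[, .(cell_id, year, agc_mean = density,
                                   agc_sd = 0, masked = FALSE)]
  data.table::setkey(g, cell_id, year)
  g[]
}

#' Run the full pipeline on a synthetic scene
#'
#' Generates the scene and its daily L-VOD stream, filters and decomposes
#' the stream into annual indices, calibrates each index method against the
#' reference-year AGC field, converts indices to an AGC series (masking
#' anomalous cells), re-derives land-cover states, books per-process fluxes
#' with residual old-growth attribution, and computes per-cell Theil-Sen
#' trends plus the modelled-vs-satellite comparison statistics.
#'
#' @param config A [scene_config()].
#' @param scene Optionally a pre-generated scene (must match `config`).
#' @param agc_source `"lvod"` (full satellite limb) or `"truth"` (the
#'   zero-noise retrieval limit from [truth_agc_grid()]).
#' @param calibration `"fit"` (calibrate each index method against the
#'   reference-year truth AGC field, as with a reference biomass map) or
#'   `"true"` (use the configured true curve for all methods; only sensible
#'   with zero seasonal amplitude).
#' @param calibration_year Reference year for curve fitting; defaults to
#'   2017 when available, else the middle year.
#' @param calibration_min_cells Minimum calibration pairs (relax for small
#'   test scenes).
#' @param keep_series Keep per-cell fitted VOD series.
#' @return List: scene, obs (NULL for `"truth"`), lvod (indices + log),
#'   curves, agc, lc, delta_lvod, fluxes, trends (modeled/lvod per cell),
#'   comparison, report.
#' @export
run_full_pipeline <- function(config, scene = NULL,
                              agc_source = c("lvod", "truth"),
                              calibration = c("fit", "true"),
                              calibration_year = NULL,
                              calibration_min_cells = 20L,
                              keep_series = FALSE) {
  agc_source <- match.arg(agc_source)
  calibration <- match.arg(calibration)
  if (is.null(scene)) scene <- generate_scene(config)

  obs <- NULL; lvod <- NULL; curves <- NULL
  if (agc_source == "truth") {
    agc <- truth_agc_grid(scene)
  } else {
    obs <- generate_lvod_series(scene, config)
    lvod <- process_lvod(obs, scene$inundation, years = config$years,
                         keep_series = keep_series)
    if (calibration == "true") {
      curves <- do.call(calibration_curve, config$calib_params)
    } else {
      if (is.null(calibration_year)) {
        calibration_year <- if (2017L %in% config$years) 2017L else
          config$years[ceiling(length(config$years) / 2)]
      }
      ref <- scene$truth$agc_density[year == calibration_year]
      idx_cal <- lvod$indices[year == calibration_year]
      cal <- merge(idx_cal, ref, by = "cell_id")
      curves <- list(
        max_smooth = fit_vod_agc_curve(cal$idx_max_smooth, cal$density,
                                       "max_smooth",
                                       min_cells = calibration_min_cells),
        mean_smooth = fit_vod_agc_curve(cal$idx_mean_smooth, cal$density,
                                        "mean_smooth",
                                        min_cells = calibration_min_cells),
        mean_trend = fit_vod_agc_curve(cal$idx_mean_trend, cal$density,
                                       "mean_trend",
                                       min_cells = calibration_min_cells)
      )
    }
    agc <- build_agc_series(lvod$indices, curves)
    agc <- mask_anomalous_cells(agc)
  }

  lc <- run_landcover(scene)
  delta_lvod <- lvod_change(agc, scene$cell_area_ha)
  fluxes <- compute_fluxes(lc, scene, delta_lvod)

  # per-cell trends: satellite AGC density vs modelled cumulative density
  lvod_tr <- cell_trends(agc[masked == FALSE], "agc_mean")
  ct <- data.table::copy(fluxes$totals$cell_totals)
  data.table::setorder(ct, cell_id, year)
  ct[, dens := cumsum(delta_mgc) / scene$cell_area_ha, by = cell_id]
  model_tr <- cell_trends(ct, "dens")

  final_year <- max(config$years)
  fr_final <- lc$fractions[year == final_year, .(cell_id, f_oldgrowth)]
  tr <- merge(merge(fr_final,
                    model_tr[, .(cell_id, slope_model = slope)],
                    by = "cell_id", all.x = TRUE),
              lvod_tr[, .(cell_id, slope_lvod = slope)],
              by = "cell_id", all.x = TRUE)
  comparison <- tryCatch(
    compare_trend_fields(tr$slope_model, tr$slope_lvod, tr$f_oldgrowth),
    error = function(e) NULL)

  report <- make_report(fluxes$totals, comparison, fluxes$flux)
  list(scene = scene, obs = obs, lvod = lvod, curves = curves, agc = agc,
       lc = lc, delta_lvod = delta_lvod, fluxes = fluxes,
       trends = tr, comparison = comparison, report = report)
}

utils::globalVariables(c("dens", "slope_model", "slope_lvod"))
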