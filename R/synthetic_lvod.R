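# Daily L-VOD observation stream for a synthetic scene: the inverse
# calibration curve applied to the interpolated true AGC density, plus a
# seasonal cycle, Gaussian noise, a constant ascending-orbit offset, injected
# RFI (VOD spikes with high TB-RMSE) and quality flags.

#' Generate a synthetic daily L-VOD observation stream
#'
#' For each coarse cell, annual true AGC densities are anchored at 1 March
#' (the midpoint of the January-April reporting window), interpolated
#' piecewise-linearly to a daily grid and pushed through the inverse of the
#' true calibration curve. Ascending and descending passes are emitted every
#' `revisit_days` on a common day grid (so same-day orbit pairs occur), with:
#' a sinusoidal seasonal term peaking in the wet season, i.i.d. Gaussian
#' noise, a constant VOD offset on ascending passes, RFI events (additive VOD
#' spikes with TB-RMSE drawn from Uniform(threshold, 20) K so the 8 K filter
#' is exercised on both sides), and a configurable fraction of flagged
#' observations. Clean TB-RMSE is drawn from Uniform(1.5, 6) K.
#'
#' @param scene A [generate_scene()] result.
#' @param config Scene configuration; defaults to `scene$config`.
#' @return data.table with columns cell_id, date (Date), orbit ("ASC"/"DESC"),
#'   vod, tb_rmse, flag (0 clean, 1 flagged).
#' @export
generate_lvod_series <- function(scene, config = scene$config) {
  curve <- do.call(calibration_curve, config$calib_params)
  dens <- scene$truth$agc_density
  lo <- min(curve$d, curve$a); hi <- max(curve$d, curve$a)
  if (any(dens$density <= lo + 0.5 | dens$density >= hi - 0.5)) {
    stop("calibration curve not invertible over the scene's AGC range; ",
         "densities approach the curve asymptotes")
  }
  with_seed(config$seed + 1L, {
    years <- config$years
    day0 <- as.Date(paste0(min(years), "-01-01"))
    day1 <- as.Date(paste0(max(years), "-12-31"))
    all_days <- seq(day0, day1, by = "day")
    obs_days <- all_days[seq(1L, length(all_days), by = config$revisit_days)]
    anchor <- as.Date(paste0(years, "-03-01"))
    doy <- as.integer(format(obs_days, "%j"))
    seasonal <- config$noise$seasonal_amplitude *
      cos(2 * pi * (doy - 46) / 365.25)

    n_cells <- scene$n_coarse_x * scene$n_coarse_y
    out <- vector("list", n_cells)
    nd <- length(obs_days)
    for (cell in seq_len(n_cells)) {
      d_cell <- dens[.(cell)]$density
      daily <- stats::approx(as.numeric(anchor), d_cell,
                             xout = as.numeric(obs_days), rule = 2)$y
      vod_clean <- agc_to_vod(curve, daily)
      base <- data.table::data.table(
        cell_id = cell,
        date = rep(obs_days, 2L),
        orbit = rep(c("ASC", "DESC"), each = nd),
        vod = rep(vod_clean + seasonal, 2L)
      )
      base[, vod := vod + stats::rnorm(.N, 0, config$noise$vod_sd)]
      base[orbit == "ASC", vod := vod + config$noise$orbit_offset]
      base[, tb_rmse := stats::runif(.N, 1.5, 6)]
      rfi <- stats::runif(nrow(base)) < config$noise$rfi_rate
      if (any(rfi)) {
        base[rfi, tb_rmse := stats::runif(sum(rfi), config$noise$rfi_tb_rmse, 20)]
        base[rfi, vod := vod + stats::runif(sum(rfi), 0.1, 0.5)]
      }
      base[, flag := as.integer(stats::runif(.N) < config$noise$flag_rate)]
      out[[cell]] <- base
    }
    obs <- data.table::rbindlist(out)
    data.table::setkey(obs, cell_id, date, orbit)
    obs[]
  })
}

#' Write an observation stream to CSV
#'
#' Columns cell_id, date (ISO-8601), orbit, vod, tb_rmse, flag; the same
#' schema is accepted for real L-VOD extracts.
#'
#' @param obs Observation data.table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  data.table::fwrite(obs, path)
  invisible(path)
}

#' Read an observation stream from CSV
#' @param path CSV written by [write_observations()] (or an equivalently
#'   shaped real-data extract).
#' @return Observation data.table keyed by (cell_id, date, orbit).
#' @export
read_observations <- function(path) {
  obs <- data.table::fread(path)
  need <- c("cell_id", "date", "orbit", "vod", "tb_rmse", "flag")
  if (!all(need %in% names(obs))) {
    stop("observation file must have columns: ", paste(need, collapse = ", "))
  }
  obs[, date := as.Date(date)]
  data.table::setkey(obs, cell_id, date, orbit)
  obs[]
}

#' Write a flux table to CSV
#' @param flux data.table with cell_id, year, process, delta_mgc (and
#'   optionally sigma_mgc).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(flux, path) {
  data.table::fwrite(flux, path)
  invisible(path)
}

#' Read a flux table from CSV
#' @param path CSV written by [write_flux_table()].
#' @return Flux data.table keyed by (cell_id, year, process).
#' @export
read_flux_table <- function(path) {
  flux <- data.table::fread(path)
  data.table::setkey(flux, cell_id, year, process)
  flux[]
}

utils::globalVariables(c("vod", "orbit", "tb_rmse", "flag", "date",
                         "delta_mgc", "process", "density", "year"))
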