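# L-VOD pre-processing: quality masks, RFI filtering, ascending/descending
# orbit reconciliation, trimester outlier rejection, seasonal-trend curve
# fitting and annual wet-season indices.
#
# All thresholds are strict inequalities as worded: observations are removed
# when TB-RMSE > 8 K, when the trimester orbit-mean difference > 0.05 (and
# TB-RMSE > 5 K), when |VOD - trimester mean| > 2 SD, and cells are masked
# when the inundated fraction > 0.25.

#' Drop flagged observations and observations of inundated cells
#'
#' Removes every observation whose quality bitmask is nonzero (water, urban,
#' terrain flags) and every observation belonging to a cell whose inundated
#' fraction exceeds 0.25 (strictly more than 25% inundated at high water).
#'
#' @param obs Observation data.table (cell_id, date, orbit, vod, tb_rmse,
#'   flag).
#' @param cell_inundation_fraction Named numeric vector (names = cell_id) or
#'   data.table/data.frame with columns cell_id, frac; fractions in `[0, 1]`.
#' @param max_inundation Masking threshold (default 0.25, strict).
#' @return Filtered observation data.table.
#' @export
apply_quality_masks <- function(obs, cell_inundation_fraction,
                                max_inundation = 0.25) {
  inund <- cell_inundation_fraction
  if (is.data.frame(inund)) {
    frac <- inund$frac
    names(frac) <- inund$cell_id
    inund <- frac
  }
  stopifnot(all(inund >= 0 & inund <= 1))
  miss <- setdiff(unique(obs$cell_id), as.integer(names(inund)))
  if (length(miss) > 0L) {
    stop("no inundation fraction for cell(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  wet_cells <- as.integer(names(inund))[inund > max_inundation]
  obs[flag == 0L & !(cell_id %in% wet_cells)]
}

#' Exclude RFI-contaminated observations
#'
#' Retains exactly the observations with TB-RMSE <= `max_tb_rmse`; values
#' strictly greater than the threshold indicate radio-frequency interference.
#'
#' @param obs Observation data.table.
#' @param max_tb_rmse Exclusion threshold in Kelvin (default 8, strict).
#' @return Filtered observation data.table.
#' @export
filter_rfi <- function(obs, max_tb_rmse = 8) {
  if (any(obs$tb_rmse < 0)) stop("negative tb_rmse in observation stream")
  obs[tb_rmse <= max_tb_rmse]
}

#' Reconcile ascending and descending orbit streams
#'
#' Per (cell, trimester): if the absolute difference between the ascending and
#' descending mean VOD exceeds `diff_threshold`, observations in that
#' trimester with TB-RMSE > `tb_threshold` are discarded. `mode` resolves the
#' ambiguity of which data are "respective": `"both"` (default) removes
#' offending observations from both orbits; `"farther"` only from the orbit
#' whose mean is farther from the pooled two-orbit mean. Afterwards, days
#' carrying both an ascending and a descending record keep only the record
#' with the lower TB-RMSE (ties broken toward ascending).
#'
#' Trimesters are calendar quarters (JFM/AMJ/JAS/OND). Trimesters observed by
#' a single orbit skip the difference test with a warning.
#'
#' @param obs Observation data.table.
#' @param diff_threshold Orbit-mean difference triggering removal (0.05,
#'   strict).
#' @param tb_threshold TB-RMSE above which triggered observations are removed
#'   (5 K, strict).
#' @param mode `"both"` or `"farther"`.
#' @return Filtered observation data.table with at most one record per
#'   (cell, date).
#' @export
reconcile_orbits <- function(obs, diff_threshold = 0.05, tb_threshold = 5,
                             mode = c("both", "farther")) {
  mode <- match.arg(mode)
  o <- data.table::copy(obs)
  o[, trimester := paste0(format(date, "%Y"), "Q", data.table::quarter(date))]
  gm <- o[, .(m = mean(vod), n = .N), by = .(cell_id, trimester, orbit)]
  wide <- data.table::dcast(gm, cell_id + trimester ~ orbit, value.var = "m")
  if (!"ASC" %in% names(wide)) wide[, ASC := NA_real_]
  if (!"DESC" %in% names(wide)) wide[, DESC := NA_real_]
  single <- wide[is.na(ASC) | is.na(DESC)]
  if (nrow(single) > 0L) {
    warning(nrow(single), " cell-trimester group(s) observed by a single ",
            "orbit; orbit-difference test skipped there")
  }
  bad <- wide[!is.na(ASC) & !is.na(DESC) & abs(ASC - DESC) > diff_threshold]
  if (nrow(bad) > 0L) {
    if (mode == "both") {
      o[bad[, .(cell_id, trimester)], on = c("cell_id", "trimester"),
        offending := TRUE]
      o <- o[is.na(offending) | tb_rmse <= tb_threshold]
      o[, offending := NULL]
    } else {
      bad[, farther := ifelse(abs(ASC - (ASC + DESC) / 2) >=
                                abs(DESC - (ASC + DESC) / 2), "ASC", "DESC")]
      o[bad[, .(cell_id, trimester, farther)], on = c("cell_id", "trimester"),
        offending_orbit := i.farther]
      o <- o[is.na(offending_orbit) | orbit != offending_orbit |
               tb_rmse <= tb_threshold]
      o[, offending_orbit := NULL]
    }
  }
  # same-day orbit pairs: keep the record with the lower TB-RMSE
  data.table::setorder(o, cell_id, date, tb_rmse, orbit)
  o <- o[, utils::head(.SD, 1L), by = .(cell_id, date)]
  o[, trimester := NULL]
  data.table::setkey(o, cell_id, date, orbit)
  o[]
}

#' Remove trimester outliers
#'
#' Per (cell, trimester) with at least `min_n` observations, removes
#' observations farther than 2 standard deviations from the trimester mean.
#' Mean and SD are computed once on the incoming set (not iteratively);
#' smaller groups pass through unchanged.
#'
#' @param obs Observation data.table.
#' @param n_sd Rejection multiple (default 2, strict).
#' @param min_n Minimum group size for the SD to be meaningful (default 3).
#' @return Filtered observation data.table.
#' @export
remove_outliers <- function(obs, n_sd = 2, min_n = 3L) {
  o <- data.table::copy(obs)
  o[, trimester := paste0(format(date, "%Y"), "Q", data.table::quarter(date))]
  o[, `:=`(g_n = .N, g_m = mean(vod), g_sd = stats::sd(vod)),
    by = .(cell_id, trimester)]
  o <- o[g_n < min_n | abs(vod - g_m) <= n_sd * g_sd]
  o[, c("trimester", "g_n", "g_m", "g_sd") := NULL]
  o[]
}

# Frequency-domain low-pass filter: sixth-order response
# H(f) = 1 / (1 + (f / fc)^6) with fc = 1 / cutoff_days (50% attenuation at
# the cutoff). The series is mirror-padded on both ends before the FFT so
# the implicit circular wraparound does not ring into the first and last
# years (whose Jan-Apr windows feed the annual indices).
fft_lowpass <- function(x, cutoff_days) {
  n <- length(x)
  if (n < 4L) return(x)
  pad <- x[c(seq(n, 2L), seq_len(n), seq(n - 1L, 1L))]
  m <- length(pad)
  k <- 0:(m - 1L)
  f <- pmin(k, m - k) / m
  fc <- 1 / cutoff_days
  H <- 1 / (1 + (f / fc)^6)
  sm <- Re(stats::fft(stats::fft(pad) * H, inverse = TRUE) / m)
  sm[(n - 1L) + seq_len(n)]
}

#' Fit the seasonal + trend decomposition of a daily VOD series
#'
#' Curve-fitting in the spirit of the classic CO2-record decomposition: an
#' ordinary least-squares fit of a quadratic polynomial in time plus the
#' first two annual harmonics, with the fit residuals interpolated to a
#' complete daily grid and low-pass filtered. The `smoothed` series is the
#' full fit (polynomial + harmonics) plus the short-cutoff-filtered residual;
#' the `trend` series is the polynomial plus the long-cutoff-filtered
#' residual, i.e. with seasonality removed.
#'
#' @param obs Observation data.table for a single cell (at most one record
#'   per day; duplicates are averaged).
#' @param poly_order Polynomial order in time (default 2).
#' @param n_harmonics Number of annual harmonics (default 2).
#' @param cutoff_short Low-pass cutoff for the smoothed series, days
#'   (default 80).
#' @param cutoff_long Low-pass cutoff for the trend series, days
#'   (default 667).
#' @return Object of class `smoothed_series`: list with `cell_id`, `dates`
#'   (complete daily grid over the observed calendar years), `smoothed`,
#'   `trend`, `n_obs`.
#' @export
fit_seasonal_trend <- function(obs, poly_order = 2L, n_harmonics = 2L,
                               cutoff_short = 80, cutoff_long = 667) {
  cell <- unique(obs$cell_id)
  if (length(cell) != 1L) stop("fit_seasonal_trend expects a single cell")
  d <- obs[, .(vod = mean(vod)), by = date]
  if (nrow(d) < 8L) stop("fewer than 8 distinct observation dates")
  span_days <- as.numeric(max(d$date) - min(d$date))
  if (span_days < 365) stop("need at least 2 years of data")
  d0 <- min(d$date)
  tt <- as.numeric(d$date - d0) / 365.25
  X <- stats::poly(tt, degree = poly_order, raw = TRUE, simple = TRUE)
  X <- cbind(`(Intercept)` = 1, X)
  for (h in seq_len(n_harmonics)) {
    X <- cbind(X, cos(2 * pi * h * tt), sin(2 * pi * h * tt))
  }
  fit <- stats::lm.fit(X, d$vod)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0

  y0 <- as.integer(format(min(d$date), "%Y"))
  y1 <- as.integer(format(max(d$date), "%Y"))
  grid <- seq(as.Date(paste0(y0, "-01-01")), as.Date(paste0(y1, "-12-31")),
              by = "day")
  tg <- as.numeric(grid - d0) / 365.25
  Xg_poly <- cbind(1, stats::poly(tg, degree = poly_order, raw = TRUE,
                                  simple = TRUE))
  Xg_harm <- NULL
  for (h in seq_len(n_harmonics)) {
    Xg_harm <- cbind(Xg_harm, cos(2 * pi * h * tg), sin(2 * pi * h * tg))
  }
  n_poly <- poly_order + 1L
  poly_g <- drop(Xg_poly %*% cf[seq_len(n_poly)])
  harm_g <- drop(Xg_harm %*% cf[-seq_len(n_poly)])

  resid_g <- stats::approx(as.numeric(d$date), fit$residuals,
                           xout = as.numeric(grid), rule = 2)$y
  smoothed <- poly_g + harm_g + fft_lowpass(resid_g, cutoff_short)
  trend <- poly_g + fft_lowpass(resid_g, cutoff_long)

  structure(list(cell_id = cell, dates = grid, smoothed = smoothed,
                 trend = trend, n_obs = nrow(d)),
            class = "smoothed_series")
}

#' Annual wet-season indices from a fitted series
#'
#' Over the closed January 1 - April 30 window of `year`: (1) maximum of the
#' smoothed curve, (2) mean of the smoothed curve, (3) mean of the trend
#' curve. A cell-year with fewer than `min_obs` retained daily observations
#' inside the window is flagged missing (indices NA, never zero).
#'
#' @param series A [fit_seasonal_trend()] result.
#' @param year Calendar year.
#' @param obs Retained observations for this cell (used for `n_obs_used`).
#' @param min_obs Minimum retained observations in the window (default 20).
#' @return One-row data.table: cell_id, year, idx_max_smooth,
#'   idx_mean_smooth, idx_mean_trend, n_obs_used.
#' @export
annual_indices <- function(series, year, obs = NULL, min_obs = 20L) {
  w0 <- as.Date(paste0(year, "-01-01"))
  w1 <- as.Date(paste0(year, "-04-30"))
  if (w0 < min(series$dates) || w1 > max(series$dates)) {
    stop("window ", year, " Jan-Apr not covered by the fitted series span")
  }
  win <- series$dates >= w0 & series$dates <= w1
  n_used <- if (is.null(obs)) {
    NA_integer_
  } else {
    nrow(obs[date >= w0 & date <= w1])
  }
  missing <- !is.na(n_used) && n_used < min_obs
  data.table::data.table(
    cell_id = series$cell_id, year = as.integer(year),
    idx_max_smooth = if (missing) NA_real_ else max(series$smoothed[win]),
    idx_mean_smooth = if (missing) NA_real_ else mean(series$smoothed[win]),
    idx_mean_trend = if (missing) NA_real_ else mean(series$trend[win]),
    n_obs_used = n_used
  )
}

#' Run the full L-VOD pre-processing pipeline
#'
#' Applies the filters in the documented order (quality/inundation masks,
#' RFI, orbit reconciliation, trimester outliers), fits the seasonal-trend
#' decomposition per cell, and derives the three annual indices per
#' cell-year, logging the number of observations removed at each stage.
#'
#' @param obs Raw observation data.table.
#' @param cell_inundation_fraction As in [apply_quality_masks()].
#' @param years Years for which to derive indices.
#' @param min_obs Minimum retained observations per Jan-Apr window.
#' @param reconcile_mode Passed to [reconcile_orbits()].
#' @param keep_series Keep the per-cell fitted series in the result.
#' @param ... Passed to [fit_seasonal_trend()].
#' @return List: `indices` (data.table cell_id x year), `log` (per-stage
#'   observation counts), `series` (if requested).
#' @export
process_lvod <- function(obs, cell_inundation_fraction, years,
                         min_obs = 20L, reconcile_mode = "both",
                         keep_series = FALSE, ...) {
  stages <- list()
  n0 <- nrow(obs)
  o <- apply_quality_masks(obs, cell_inundation_fraction)
  stages[["quality_masks"]] <- c(n0, nrow(o))
  n0 <- nrow(o); o <- filter_rfi(o)
  stages[["rfi"]] <- c(n0, nrow(o))
  n0 <- nrow(o); o <- reconcile_orbits(o, mode = reconcile_mode)
  stages[["orbit_reconciliation"]] <- c(n0, nrow(o))
  n0 <- nrow(o); o <- remove_outliers(o)
  stages[["outliers"]] <- c(n0, nrow(o))
  log <- data.table::data.table(
    stage = names(stages),
    n_in = vapply(stages, `[`, numeric(1), 1L),
    n_out = vapply(stages, `[`, numeric(1), 2L)
  )
  log[, n_removed := n_in - n_out]

  cells <- sort(unique(o$cell_id))
  series_list <- list()
  idx <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    oc <- o[cell_id == cells[i]]
    ser <- tryCatch(fit_seasonal_trend(oc, ...), error = function(e) e)
    if (inherits(ser, "error")) {
      warning("cell ", cells[i], ": ", conditionMessage(ser),
              "; indices set missing")
      idx[[i]] <- data.table::data.table(
        cell_id = cells[i], year = as.integer(years),
        idx_max_smooth = NA_real_, idx_mean_smooth = NA_real_,
        idx_mean_trend = NA_real_, n_obs_used = 0L)
      next
    }
    if (keep_series) series_list[[as.character(cells[i])]] <- ser
    idx[[i]] <- data.table::rbindlist(
      lapply(years, function(y) annual_indices(ser, y, oc, min_obs)))
  }
  indices <- data.table::rbindlist(idx)
  data.table::setkey(indices, cell_id, year)
  out <- list(indices = indices, log = log)
  if (keep_series) out$series <- series_list
  out
}

utils::globalVariables(c(
  "trimester", "ASC", "DESC", "offending", "offending_orbit", "farther",
  "i.farther", "g_n", "g_m", "g_sd", "n_in", "n_out", "n_removed",
  "idx_max_smooth", "idx_mean_smooth", "idx_mean_trend", "n_obs_used"
))
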