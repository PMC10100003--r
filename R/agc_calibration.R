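# Calibration of annual L-VOD indices to above-ground carbon density against
# a reference biomass map, conversion of index series to an AGC series (mean
# and SD over the three index methods), and masking of anomalous cells.

INDEX_METHODS <- c("max_smooth", "mean_smooth", "mean_trend")

#' Fit the four-parameter VOD-to-AGC calibration curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the saturating
#' four-parameter form to (index, reference AGC) pairs for the calibration
#' year, with 8 deterministic multi-starts spanning the data range to guard
#' against local minima of the saturating form. Non-finite curve evaluations
#' are replaced by the overflow sentinel 1e10 during fitting.
#'
#' @param vod Annual index values (one per cell).
#' @param agc Reference AGC densities for the same cells, Mg C ha^-1
#'   (reference map aggregated to the coarse grid).
#' @param index_method Which index the pairs come from (see `INDEX_METHODS`).
#' @param min_cells Minimum number of complete pairs (default 20).
#' @return A [calibration_curve()] with standard errors from the fit
#'   covariance and a `fit` attribute (rss, r_squared, n, starts_tried).
#' @export
fit_vod_agc_curve <- function(vod, agc, index_method = "mean_trend",
                              min_cells = 20L) {
  keep <- is.finite(vod) & is.finite(agc)
  vod <- vod[keep]; agc <- agc[keep]
  if (length(vod) < min_cells) {
    stop("need at least ", min_cells, " cells with both an index value and ",
         "a reference AGC; got ", length(vod))
  }
  if (stats::sd(vod) == 0) stop("degenerate input: constant index")
  if (stats::sd(agc) == 0) {
    # flat solution: curve predicts the constant target everywhere
    k <- agc[1L]
    curve <- calibration_curve(a = k, b = 1, c = mean(vod), d = k,
                               se = c(a = 0, b = NA, c = NA, d = 0),
                               index_method = index_method)
    attr(curve, "fit") <- list(rss = 0, r_squared = NA_real_,
                               n = length(vod), starts_tried = 0L)
    return(curve)
  }

  pred <- function(vod, a, b, c, d) {
    p <- d + (a - d) / (1 + exp(-b * (vod - c)))
    p[!is.finite(p)] <- OVERFLOW_SENTINEL
    p
  }
  qs <- stats::quantile(vod, c(0.25, 0.75), names = FALSE)
  starts <- expand.grid(
    b = c(2, 6, 15, 40) / max(diff(range(vod)), 0.05) * 0.8,
    c = qs
  )
  dat <- data.frame(vod = vod, agc = agc)
  a0 <- max(agc) + 0.05 * diff(range(agc))
  d0 <- min(agc) - 0.05 * diff(range(agc))
  best <- NULL
  tried <- 0L
  for (i in seq_len(nrow(starts))) {
    tried <- tried + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(
        agc ~ pred(vod, a, b, c, d), data = dat,
        start = list(a = a0, b = starts$b[i], c = starts$c[i], d = d0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("calibration fit did not converge after ", tried, " starts")
  }
  cf <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))), error = function(e) {
    stats::setNames(rep(NA_real_, 4L), names(cf))
  })
  curve <- calibration_curve(cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]],
                             se = se, index_method = index_method)
  rss <- stats::deviance(best)
  attr(curve, "fit") <- list(
    rss = rss,
    r_squared = 1 - rss / sum((agc - mean(agc))^2),
    n = length(vod), starts_tried = tried
  )
  curve
}

#' Convert annual index sets to an AGC series
#'
#' Applies each index method's independently calibrated curve to its own
#' index and records the mean and standard deviation over the three
#' per-method AGC estimates. Cell-years missing any index are flagged masked
#' (missing propagates, never imputed as zero).
#'
#' @param index_sets data.table from [process_lvod()]: cell_id, year,
#'   idx_max_smooth, idx_mean_smooth, idx_mean_trend.
#' @param curves_by_method Named list of [calibration_curve()] objects with
#'   names `max_smooth`, `mean_smooth`, `mean_trend`. A single curve is
#'   recycled to all three methods (matched-parameter closed-loop use).
#' @return AGC grid data.table: cell_id, year, agc_mean, agc_sd (Mg C ha^-1),
#'   masked.
#' @export
build_agc_series <- function(index_sets, curves_by_method) {
  if (inherits(curves_by_method, "calibration_curve")) {
    curves_by_method <- stats::setNames(
      rep(list(curves_by_method), 3L), INDEX_METHODS)
  }
  if (!all(INDEX_METHODS %in% names(curves_by_method))) {
    stop("curves_by_method needs one curve per index method: ",
         paste(INDEX_METHODS, collapse = ", "))
  }
  out <- data.table::copy(index_sets)
  est <- matrix(NA_real_, nrow(out), 3L)
  cols <- paste0("idx_", INDEX_METHODS)
  for (j in seq_along(INDEX_METHODS)) {
    v <- out[[cols[j]]]
    ok <- is.finite(v)
    if (any(ok)) {
      est[ok, j] <- suppressWarnings(
        vod_to_agc(curves_by_method[[INDEX_METHODS[j]]], v[ok]))
    }
  }
  out[, agc_mean := rowMeans(est)]
  out[, agc_sd := apply(est, 1L, stats::sd)]
  out[, masked := !stats::complete.cases(est)]
  out[masked == TRUE, `:=`(agc_mean = NA_real_, agc_sd = NA_real_)]
  out[, .(cell_id, year, agc_mean, agc_sd, masked)]
}

#' Mask cells with anomalous year-over-year AGC increases
#'
#' A cell showing an `agc_mean` increase of strictly more than
#' `max_increase` Mg C ha^-1 in any single year is masked for all years.
#' The default 20 Mg C ha^-1 is permissive relative to the biome's maximum
#' plausible accumulation (about 6 Mg C ha^-1 yr^-1), so only genuinely
#' anomalous retrievals are removed; decreases never trigger the mask.
#'
#' @param agc AGC grid data.table from [build_agc_series()].
#' @param max_increase Masking threshold, Mg C ha^-1 (default 20, strict).
#' @return AGC grid with the `masked` flag updated.
#' @export
mask_anomalous_cells <- function(agc, max_increase = 20) {
  out <- data.table::copy(agc)
  data.table::setorder(out, cell_id, year)
  if (out[, .N, by = cell_id][, any(N < 2L)]) {
    stop("mask_anomalous_cells needs at least 2 years per cell")
  }
  anom <- out[, .(anomalous = any(diff(agc_mean) > max_increase,
                                  na.rm = TRUE)), by = cell_id]
  out[anom, on = "cell_id", masked := masked | i.anomalous]
  data.table::setkey(out, cell_id, year)
  out[]
}

utils::globalVariables(c("agc_mean", "agc_sd", "masked", "i.anomalous", "N"))
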