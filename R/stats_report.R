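# Trend estimation (Theil-Sen slope with Mann-Kendall significance),
# model-vs-retrieval comparison statistics, uncertainty propagation and
# regional aggregation.

#' Theil-Sen trend with Mann-Kendall significance
#'
#' Robust slope = median of all pairwise slopes between observations.
#' Significance is the two-sided Mann-Kendall test at the 95% level, with
#' the standard tie-corrected variance and continuity correction; it is only
#' defined for series of at least 4 years.
#'
#' @param year Numeric vector of years (no duplicates).
#' @param value Numeric vector of the same length.
#' @return One-row data.table: slope, intercept, s (MK statistic), p_value,
#'   significant, n_years.
#' @export
theil_sen <- function(year, value) {
  ok <- is.finite(year) & is.finite(value)
  year <- year[ok]; value <- value[ok]
  n <- length(year)
  if (anyDuplicated(year)) stop("duplicate years in trend series")
  if (n < 3L) {
    return(data.table::data.table(slope = NA_real_, intercept = NA_real_,
                                  s = NA_real_, p_value = NA_real_,
                                  significant = NA, n_years = n))
  }
  o <- order(year)
  year <- year[o]; value <- value[o]
  dy <- outer(value, value, "-")
  dx <- outer(year, year, "-")
  low <- lower.tri(dx)
  slope <- stats::median(dy[low] / dx[low])
  intercept <- stats::median(value - slope * year)

  s <- sum(sign(dy[low]))
  ties <- table(value)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s <= 0 || s == 0) 0 else (s - sign(s)) / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  data.table::data.table(
    slope = slope, intercept = intercept, s = as.numeric(s), p_value = p,
    significant = if (n >= 4L) p < 0.05 else NA, n_years = n
  )
}

#' Per-cell Theil-Sen trends of a cell x year field
#'
#' @param dt data.table with columns cell_id, year and `value_col`.
#' @param value_col Name of the value column.
#' @return data.table: cell_id, slope, p_value, significant, n_years.
#' @export
cell_trends <- function(dt, value_col) {
  d <- dt[is.finite(dt[[value_col]])]
  d[, theil_sen(year, .SD[[1L]]), by = cell_id,
    .SDcols = value_col][, .(cell_id, slope, p_value, significant, n_years)]
}

#' Compare modelled and satellite trend fields
#'
#' Restricted to cells with old-growth fraction below `max_og_frac` (the
#' mixed, land-use-affected cells) and finite values in both fields:
#' Pearson's r and r-squared, the mean absolute deviation, and the fraction
#' of cells whose trends agree in strict sign (zeros only agree with zeros).
#'
#' @param modeled,lvod Numeric vectors aligned by cell (e.g. Theil-Sen
#'   slopes, or total-period changes).
#' @param og_fraction Old-growth fraction per cell (final analysis year).
#' @param max_og_frac Eligibility threshold (default 0.90, strict).
#' @return List: pearson_r, r_squared, mad, agreement_fraction, n_cells.
#' @export
compare_trend_fields <- function(modeled, lvod, og_fraction,
                                 max_og_frac = 0.90) {
  stopifnot(length(modeled) == length(lvod),
            length(modeled) == length(og_fraction))
  keep <- og_fraction < max_og_frac & is.finite(modeled) & is.finite(lvod)
  if (sum(keep) < 3L) stop("fewer than 3 eligible cells for comparison")
  m <- modeled[keep]; v <- lvod[keep]
  r <- stats::cor(m, v)
  list(
    pearson_r = r, r_squared = r^2,
    mad = mean(abs(m - v)),
    agreement_fraction = mean(sign(m) == sign(v)),
    n_cells = sum(keep)
  )
}

#' Combine annual uncertainties
#'
#' Default: root sum of squares of the per-source sigmas (independent
#' errors). The conservative alternative, plain summation, is exposed as
#' `method = "sum"`.
#'
#' @param sigmas Non-negative numeric vector of 1-SD uncertainties.
#' @param method `"rss"` (default) or `"sum"`.
#' @return Combined sigma.
#' @export
#' @examples
#' propagate_uncertainty(c(3, 4))                  # 5
#' propagate_uncertainty(c(3, 4), method = "sum")  # 7
propagate_uncertainty <- function(sigmas, method = c("rss", "sum")) {
  method <- match.arg(method)
  stopifnot(all(sigmas >= 0))
  if (method == "rss") sqrt(sum(sigmas^2)) else sum(sigmas)
}

#' Aggregate fluxes to regions with per-cell weights
#'
#' Region totals = sum over cells of weight x flux, per process. Also
#' reports, per region: the net change, the gross loss (sum of the negative
#' loss processes: deforestation, edge and non-edge degradation) and the
#' degradation share of gross loss (edge + non-edge over gross loss).
#'
#' @param flux FluxTable data.table (cell_id, year, process, delta_mgc).
#' @param weights data.table (cell_id, region, weight); weights in `[0, 1]`
#'   and summing to at most 1 over regions per cell.
#' @return List: `process_totals` (region x process, Mg and Tg C),
#'   `summary` (region: net_mgc, gross_loss_mgc, degradation_share).
#' @export
aggregate_region <- function(flux, weights) {
  if (any(weights$weight < 0 | weights$weight > 1)) {
    stop("region weights must lie in [0, 1]")
  }
  tot_w <- weights[, .(w = sum(weight)), by = cell_id]
  if (any(tot_w$w > 1 + 1e-9)) {
    stop("region weights sum to more than 1 for some cell(s)")
  }
  d <- merge(flux, weights, by = "cell_id", allow.cartesian = TRUE)
  process_totals <- d[, .(delta_mgc = sum(weight * delta_mgc)),
                      by = .(region, process)]
  process_totals[, delta_tgc := delta_mgc / 1e6]
  loss_proc <- c("deforestation", "edge_degradation", "nonedge_degradation")
  summary <- process_totals[, .(
    net_mgc = sum(delta_mgc),
    gross_loss_mgc = sum(delta_mgc[process %in% loss_proc]),
    degradation_share = {
      gl <- sum(delta_mgc[process %in% loss_proc])
      dg <- sum(delta_mgc[process %in% loss_proc[2:3]])
      if (gl == 0) NA_real_ else dg / gl
    }
  ), by = region]
  list(process_totals = process_totals, summary = summary)
}

#' Assemble a run report
#'
#' Bundles the biome series, per-process series, optional per-region table,
#' trend comparison statistics and combined uncertainties into a single
#' list, writable as JSON + CSV by [write_report()].
#'
#' @param totals [total_modeled_change()] result.
#' @param comparison [compare_trend_fields()] result (or NULL).
#' @param flux FluxTable with sigma_mgc.
#' @param regions [aggregate_region()] result (or NULL).
#' @param uncertainty_method Passed to [propagate_uncertainty()].
#' @return List of class `vodcarbon_report`.
#' @export
make_report <- function(totals, comparison = NULL, flux = NULL,
                        regions = NULL, uncertainty_method = "rss") {
  unc <- NULL
  if (!is.null(flux) && "sigma_mgc" %in% names(flux)) {
    annual <- flux[, .(sigma_mgc = propagate_uncertainty(
      sigma_mgc[is.finite(sigma_mgc)], uncertainty_method)), by = year]
    unc <- list(
      annual = annual,
      total_sigma_mgc = propagate_uncertainty(
        annual$sigma_mgc, uncertainty_method),
      method = uncertainty_method
    )
  }
  structure(list(
    biome_total = totals$biome_total,
    biome_process = totals$biome_process,
    comparison = comparison,
    regions = regions,
    uncertainty = unc
  ), class = "vodcarbon_report")
}

#' Write a report bundle to disk
#'
#' @param report A [make_report()] result.
#' @param dir Output directory (created if needed): writes
#'   `report.json` plus `biome_total.csv`, `biome_process.csv` and, when
#'   present, `region_process_totals.csv`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(report$biome_total, file.path(dir, "biome_total.csv"))
  data.table::fwrite(report$biome_process,
                     file.path(dir, "biome_process.csv"))
  if (!is.null(report$regions)) {
    data.table::fwrite(report$regions$process_totals,
                       file.path(dir, "region_process_totals.csv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         na = "null")
  }
  invisible(dir)
}

utils::globalVariables(c("slope", "p_value", "significant", "n_years",
                         "weight", "region", "w"))
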