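# Bookkeeping core: converts annual land-cover transitions into per-process
# AGC stock changes using reference densities and response curves, extracts
# spatial reference values with circular median filters, and attributes
# old-growth forest change as the residual between the satellite (L-VOD)
# change and the modelled process fluxes in old-growth-dominated cells.
#
# Sign convention: losses (deforestation, edge and non-edge degradation) are
# carried as negative stock changes, secondary growth as positive, so the
# residual is delta_LVOD - (delta_def + delta_deg + delta_SF).

#' Non-edge degradation biomass loss factor
#'
#' Fractional AGC reduction associated with canopy disturbance events that
#' leave the pixel forested, from the old-growth and degraded reference
#' medians: `(ref_og - ref_deg) / ref_og`. With the reference medians
#' 126.4 and 81.78 Mg C ha^-1 this gives 0.353.
#'
#' @param ref_og_median Old-growth reference AGC median, Mg C ha^-1 (> 0).
#' @param ref_deg_median Degraded reference AGC median, Mg C ha^-1
#'   (> 0, < ref_og_median).
#' @return Loss fraction in (0, 1).
#' @export
#' @examples
#' loss_factor(126.4, 81.78)   # 0.353...
loss_factor <- function(ref_og_median, ref_deg_median) {
  if (ref_og_median <= 0 || ref_deg_median <= 0) {
    stop("reference medians must be positive")
  }
  if (ref_deg_median >= ref_og_median) {
    stop("degraded reference must be below the old-growth reference")
  }
  (ref_og_median - ref_deg_median) / ref_og_median
}

#' Regional old-growth reference AGC by circular median filter
#'
#' Per coarse cell: the median, over cells with old-growth cover above
#' `min_og_frac` within `radius_deg` (circular, planar degrees, inclusive),
#' of the old-growth-masked mean biomass of those cells. Cells with no
#' eligible neighbour in range are retried at `widen_deg` and flagged
#' no-reference if still empty.
#'
#' @param biomass Fine-grid biomass matrix, Mg C ha^-1.
#' @param og_mask Fine-grid logical matrix: old-growth pixels in the
#'   reference year.
#' @param fine_per_coarse Subdivision factor.
#' @param cell_deg Coarse cell size in degrees.
#' @param radius_deg Primary filter radius, degrees (default 1).
#' @param widen_deg Fallback radius, degrees (default 2).
#' @param min_og_frac Old-growth cover fraction defining reference cells
#'   (default 0.9, strict).
#' @return data.table: cell_id, ref_og (Mg C ha^-1), flagged.
#' @export
regional_reference_agc <- function(biomass, og_mask, fine_per_coarse,
                                   cell_deg = 0.25, radius_deg = 1,
                                   widen_deg = 2, min_og_frac = 0.9) {
  f <- fine_per_coarse
  ncy <- nrow(biomass) %/% f; ncx <- ncol(biomass) %/% f
  ids <- cell_id_grid(ncy, ncx)
  og_count <- block_sum(og_mask, f)
  og_frac <- og_count / f^2
  masked_sum <- block_sum(biomass * og_mask, f)
  cell_val <- ifelse(og_count > 0, masked_sum / og_count, NA_real_)

  eligible <- og_frac > min_og_frac & !is.na(cell_val)
  vals <- as.vector(cell_val)[order(as.vector(ids))]
  elig <- as.vector(eligible)[order(as.vector(ids))]
  src <- stats::setNames(vals[elig], which(elig))
  centers <- cell_centers_deg(ncy, ncx, cell_deg)
  ref <- circular_median(centers, src, radius_deg)
  nas <- is.na(ref)
  if (any(nas)) {
    ref2 <- circular_median(centers, src, widen_deg)
    ref[nas] <- ref2[nas]
  }
  data.table::data.table(cell_id = centers$cell_id, ref_og = unname(ref),
                         flagged = is.na(ref))
}

#' Per-cell L-VOD AGC stock change series
#'
#' Year-over-year change of the retrieved AGC density times the cell area.
#' Masked or missing cell-years propagate as NA (never zero).
#'
#' @param agc_grid data.table from [build_agc_series()] /
#'   [mask_anomalous_cells()].
#' @param cell_area_ha Cell area in hectares (scalar or per-cell named
#'   vector).
#' @return data.table: cell_id, year, delta_mgc (stock change from the
#'   previous year, Mg C).
#' @export
lvod_change <- function(agc_grid, cell_area_ha) {
  g <- data.table::copy(agc_grid)
  data.table::setorder(g, cell_id, year)
  if (length(cell_area_ha) == 1L) {
    g[, area_ha := cell_area_ha]
  } else {
    g[, area_ha := cell_area_ha[as.character(cell_id)]]
  }
  g[masked == TRUE, agc_mean := NA_real_]
  g[, delta_mgc := (agc_mean - data.table::shift(agc_mean)) * area_ha,
    by = cell_id]
  g[!is.na(year) & year > min(year), .(cell_id, year, delta_mgc)]
}

#' Old-growth AGC change reference field (residual attribution)
#'
#' In reference cells (old-growth fraction above `min_og_frac`), old-growth
#' change is the residual of the satellite stock change and the modelled
#' process fluxes, expressed as density change per old-growth area; by
#' construction the combined processes there equal the satellite change.
#' Every other cell receives the circular median of the reference-cell
#' residual densities within `radius_deg`, widened to `widen_deg` where
#' still undefined, and is flagged (excluded from the old-growth flux) if no
#' reference cell lies within the widened radius.
#'
#' @param delta_lvod data.table (cell_id, year, delta_mgc) from
#'   [lvod_change()].
#' @param modeled data.table (cell_id, year, delta_mgc): summed modelled
#'   deforestation + degradation + secondary-growth fluxes.
#' @param fractions FractionStack data.table (for old-growth area).
#' @param cell_deg Coarse cell size in degrees.
#' @param radius_deg Primary filter radius, degrees (default 2.5).
#' @param widen_deg Fallback radius, degrees (default 5).
#' @param min_og_frac Reference-cell old-growth fraction (default 0.9,
#'   strict).
#' @return data.table: cell_id, year, dref_og (Mg C ha^-1 of old-growth
#'   area), is_reference, flagged.
#' @export
lvod_oldgrowth_change_reference <- function(delta_lvod, modeled, fractions,
                                            cell_deg = 0.25,
                                            radius_deg = 2.5, widen_deg = 5,
                                            min_og_frac = 0.9,
                                            ncx = NULL, ncy = NULL) {
  fr <- fractions[, .(cell_id, year, og_area = f_oldgrowth * area_ha)]
  d <- merge(delta_lvod, modeled[, .(cell_id, year, modeled_mgc = delta_mgc)],
             by = c("cell_id", "year"), all.x = TRUE)
  d[is.na(modeled_mgc), modeled_mgc := 0]
  d <- merge(d, fr, by = c("cell_id", "year"), all.x = TRUE)
  d <- merge(d, fractions[, .(cell_id, year, f_oldgrowth)],
             by = c("cell_id", "year"), all.x = TRUE)
  d[, residual_mgc := delta_mgc - modeled_mgc]
  d[, is_reference := f_oldgrowth > min_og_frac & !is.na(residual_mgc) &
      og_area > 0]

  n_cells <- length(unique(fractions$cell_id))
  if (is.null(ncx)) ncx <- guess_grid_ncx(seq_len(n_cells))
  if (is.null(ncy)) ncy <- n_cells %/% ncx
  centers <- cell_centers_deg(ncy, ncx, cell_deg)
  out <- vector("list", 0L)
  for (y in sort(unique(d$year))) {
    dy <- d[year == y]
    dy[, dref_og := NA_real_]
    dy[is_reference == TRUE, dref_og := residual_mgc / og_area]
    src <- dy[is_reference == TRUE]
    vals <- stats::setNames(src$dref_og, src$cell_id)
    fill <- circular_median(centers, vals, radius_deg)
    still <- is.na(fill)
    if (any(still) && length(vals) > 0L) {
      fill2 <- circular_median(centers, vals, widen_deg)
      fill[still] <- fill2[still]
    }
    need <- dy$is_reference == FALSE | is.na(dy$dref_og)
    dy[need, dref_og := fill[as.character(cell_id)]]
    dy[, flagged := is.na(dref_og)]
    out[[as.character(y)]] <- dy[, .(cell_id, year, dref_og, is_reference,
                                     flagged)]
  }
  res <- data.table::rbindlist(out)
  data.table::setkey(res, cell_id, year)
  res[]
}

# Infer the number of grid columns from a row-major id sequence; cells are
# numbered row-major on a regular grid, so ncx is the largest factor pair
# closest to a square unless annotated. For package-generated scenes the
# caller passes geometry explicitly; this fallback assumes a square grid.
guess_grid_ncx <- function(ids) {
  n <- length(ids)
  s <- round(sqrt(n))
  if (s * s == n) return(s)
  # fall back to the most square factorization
  f <- which(n %% seq_len(n) == 0)
  f[which.min(abs(f - sqrt(n)))]
}

#' Deforestation flux
#'
#' Stock loss per cell-year from newly deforested areas, split by the prior
#' state of the cleared pixels: old-growth areas lose the old-growth
#' reference density; non-edge degraded areas the degraded reference
#' `ref_og * (1 - loss_factor)`; edge areas the edge-adjusted reference
#' `ref_og * (1 - edge_loss(age))` (with the degradation loss as a floor for
#' previously degraded edge pixels); secondary areas lose `growth(age)`.
#'
#' @param defor data.table (year, cell_id, prior_state, age, wasdeg,
#'   area_ha) from [run_landcover()].
#' @param refs data.table (cell_id, ref_og, flagged) from
#'   [regional_reference_agc()].
#' @param gcurve A [growth_curve()].
#' @param ecurve An [edge_loss_curve()].
#' @param lf Non-edge degradation loss factor.
#' @return data.table: cell_id, year, process = "deforestation", delta_mgc
#'   (<= 0; NA where the cell has no reference value).
#' @export
deforestation_flux <- function(defor, refs, gcurve, ecurve, lf) {
  if (is.null(defor) || nrow(defor) == 0L) {
    return(data.table::data.table(cell_id = integer(), year = integer(),
                                  process = character(),
                                  delta_mgc = numeric()))
  }
  d <- merge(defor, refs[, .(cell_id, ref_og, flagged)], by = "cell_id",
             all.x = TRUE)
  if (any(d$flagged | is.na(d$ref_og))) {
    warning("deforestation in cell(s) without a reference AGC value; ",
            "those cell-years are flagged NA")
  }
  d[, density := NA_real_]
  d[prior_state == "oldgrowth", density := ref_og]
  d[prior_state == "degraded", density := ref_og * (1 - lf)]
  d[prior_state == "edge",
    density := ref_og * (1 - edge_loss(ecurve, age, ifelse(wasdeg, lf, 0)))]
  d[prior_state == "secondary", density := growth_agc(gcurve, age)]
  d[, delta := -area_ha * density]
  out <- d[, .(delta_mgc = sum(delta)), by = .(cell_id, year)]
  out[, process := "deforestation"]
  out[, .(cell_id, year, process, delta_mgc)]
}

#' Non-edge degradation flux
#'
#' Loss = -area x ref_og x loss_factor for new non-edge degradation areas.
#'
#' @param nonedge data.table (year, cell_id, area_ha).
#' @inheritParams deforestation_flux
#' @return data.table rows with process = "nonedge_degradation".
#' @export
nonedge_degradation_flux <- function(nonedge, refs, lf) {
  if (is.null(nonedge) || nrow(nonedge) == 0L) {
    return(data.table::data.table(cell_id = integer(), year = integer(),
                                  process = character(),
                                  delta_mgc = numeric()))
  }
  d <- merge(nonedge, refs[, .(cell_id, ref_og)], by = "cell_id",
             all.x = TRUE)
  out <- d[, .(delta_mgc = sum(-area_ha * ref_og * lf)),
           by = .(cell_id, year)]
  out[, process := "nonedge_degradation"]
  out[, .(cell_id, year, process, delta_mgc)]
}

#' Edge degradation flux
#'
#' Per edge area at age a, the annual loss increment is
#' `-ref_og x (loss(a) - loss(a - 1)) x area`; previously degraded edge
#' pixels use the degradation loss factor as a floor so increments only
#' accrue beyond the loss already incurred. Cumulative increments over ages
#' 1..A telescope to `-ref_og x loss(A) x area`.
#'
#' @param edge data.table (year, cell_id, age, wasdeg, area_ha).
#' @inheritParams deforestation_flux
#' @return data.table rows with process = "edge_degradation" (delta <= 0).
#' @export
edge_degradation_flux <- function(edge, refs, ecurve, lf) {
  if (is.null(edge) || nrow(edge) == 0L) {
    return(data.table::data.table(cell_id = integer(), year = integer(),
                                  process = character(),
                                  delta_mgc = numeric()))
  }
  if (any(edge$age < 1L)) stop("edge areas must have age >= 1")
  d <- merge(edge, refs[, .(cell_id, ref_og)], by = "cell_id", all.x = TRUE)
  d[, fl := ifelse(wasdeg, lf, 0)]
  d[, inc := edge_loss(ecurve, age, fl) - edge_loss(ecurve, age - 1L, fl)]
  out <- d[, .(delta_mgc = sum(-ref_og * inc * area_ha)),
           by = .(cell_id, year)]
  out[, process := "edge_degradation"]
  out[, .(cell_id, year, process, delta_mgc)]
}

#' Secondary-forest growth flux
#'
#' Gain = area x (growth(age) - growth(age - 1)) for persisting stands and
#' growth(1) x area for new age-1 stands (the same formula with age = 1,
#' since growth(0) = 0). Losses from cleared secondary forest are booked
#' under deforestation, not here.
#'
#' @param secondary data.table (year, cell_id, age, area_ha).
#' @param gcurve A [growth_curve()].
#' @return data.table rows with process = "secondary_growth" (delta >= 0).
#' @export
secondary_growth_flux <- function(secondary, gcurve) {
  if (is.null(secondary) || nrow(secondary) == 0L) {
    return(data.table::data.table(cell_id = integer(), year = integer(),
                                  process = character(),
                                  delta_mgc = numeric()))
  }
  d <- data.table::copy(secondary)
  d[, inc := growth_agc(gcurve, age) - growth_agc(gcurve, age - 1L)]
  out <- d[, .(delta_mgc = sum(area_ha * inc)), by = .(cell_id, year)]
  out[, process := "secondary_growth"]
  out[, .(cell_id, year, process, delta_mgc)]
}

#' Old-growth flux from the residual reference field
#'
#' Flux = dref_og x old-growth area of the cell; flagged cells (no reference
#' within the widened radius) are excluded with a warning.
#'
#' @param dref data.table from [lvod_oldgrowth_change_reference()].
#' @param fractions FractionStack data.table.
#' @return data.table rows with process = "old_growth".
#' @export
old_growth_flux <- function(dref, fractions) {
  d <- merge(dref, fractions[, .(cell_id, year,
                                 og_area = f_oldgrowth * area_ha)],
             by = c("cell_id", "year"))
  n_flag <- sum(d$flagged)
  if (n_flag > 0L) {
    warning(n_flag, " cell-year(s) without an old-growth change reference ",
            "excluded from the old-growth flux")
  }
  out <- d[flagged == FALSE,
           .(cell_id, year, process = "old_growth",
             delta_mgc = dref_og * og_area)]
  out[]
}

#' Totals of the modelled per-process fluxes
#'
#' @param flux FluxTable data.table (cell_id, year, process, delta_mgc).
#' @return List: `cell_totals` (per cell-year sum over processes),
#'   `biome_process` (per year x process totals in Mg, Tg and Pg C),
#'   `biome_total` (per year totals).
#' @export
total_modeled_change <- function(flux) {
  if (nrow(flux) == 0L) {
    empty <- data.table::data.table(year = integer(), delta_mgc = numeric(),
                                    delta_tgc = numeric(),
                                    delta_pgc = numeric())
    return(list(cell_totals = data.table::data.table(
      cell_id = integer(), year = integer(), delta_mgc = numeric()),
      biome_process = empty, biome_total = empty))
  }
  cell_totals <- flux[, .(delta_mgc = sum(delta_mgc)), by = .(cell_id, year)]
  biome_process <- flux[, .(delta_mgc = sum(delta_mgc)),
                        by = .(year, process)]
  biome_total <- flux[, .(delta_mgc = sum(delta_mgc)), by = year]
  for (dt in list(biome_process, biome_total)) {
    dt[, delta_tgc := delta_mgc / 1e6]
    dt[, delta_pgc := delta_mgc / 1e9]
  }
  data.table::setkey(cell_totals, cell_id, year)
  list(cell_totals = cell_totals, biome_process = biome_process,
       biome_total = biome_total)
}

#' Run the full bookkeeping model over engine outputs
#'
#' Extracts reference densities, books the four land-cover process fluxes,
#' attributes old-growth change by residual against the supplied L-VOD AGC
#' change, and attaches per-process uncertainties (configurable relative
#' sigmas for the bookkeeping terms; the spread of the reference-cell
#' residual densities for the old-growth term).
#'
#' @param lc [run_landcover()] result.
#' @param scene The scene (for biomass, geometry).
#' @param delta_lvod data.table from [lvod_change()].
#' @param gcurve,ecurve Response curves; default from the scene config.
#' @param lf Loss factor; default from the scene config reference medians.
#' @param rel_sigma Named relative uncertainties for the bookkeeping
#'   processes.
#' @return List: `flux` (FluxTable with sigma_mgc), `refs`, `dref`,
#'   `totals` (see [total_modeled_change()]).
#' @export
compute_fluxes <- function(lc, scene, delta_lvod,
                           gcurve = do.call(growth_curve,
                                            scene$config$growth_params),
                           ecurve = do.call(edge_loss_curve,
                                            scene$config$edge_params),
                           lf = loss_factor(scene$config$ref_og,
                                            scene$config$ref_deg),
                           rel_sigma = c(deforestation = 0.216,
                                         nonedge_degradation = 0.30,
                                         edge_degradation = 0.25,
                                         secondary_growth = 0.20)) {
  refs <- regional_reference_agc(
    scene$biomass, lc$states[, , 1L] == ST_OLDGROWTH,
    scene$fine_per_coarse, cell_deg = scene$cell_deg)

  fx <- data.table::rbindlist(list(
    deforestation_flux(lc$deforestation, refs, gcurve, ecurve, lf),
    nonedge_degradation_flux(lc$nonedge_degradation, refs, lf),
    edge_degradation_flux(lc$edge, refs, ecurve, lf),
    secondary_growth_flux(lc$secondary, gcurve)
  ))
  modeled <- fx[, .(delta_mgc = sum(delta_mgc)), by = .(cell_id, year)]

  dref <- lvod_oldgrowth_change_reference(
    delta_lvod, modeled, lc$fractions, cell_deg = scene$cell_deg,
    ncx = scene$n_coarse_x, ncy = scene$n_coarse_y)
  og <- old_growth_flux(dref, lc$fractions)

  fx[, sigma_mgc := abs(delta_mgc) * rel_sigma[process]]
  og_spread <- dref[is_reference == TRUE,
                    .(sig_dens = stats::mad(dref_og)), by = year]
  og <- merge(og, og_spread, by = "year", all.x = TRUE)
  og <- merge(og, lc$fractions[, .(cell_id, year,
                                   og_area = f_oldgrowth * area_ha)],
              by = c("cell_id", "year"), all.x = TRUE)
  og[, sigma_mgc := sig_dens * og_area]
  og <- og[, .(cell_id, year, process, delta_mgc, sigma_mgc)]

  flux <- rbind(fx[, .(cell_id, year, process, delta_mgc, sigma_mgc)], og)
  data.table::setkey(flux, cell_id, year, process)
  list(flux = flux, refs = refs, dref = dref,
       totals = total_modeled_change(flux))
}

utils::globalVariables(c(
  "ref_og", "flagged", "density", "delta", "inc", "fl", "og_area",
  "modeled_mgc", "residual_mgc", "is_reference", "dref_og", "sig_dens",
  "sigma_mgc", "delta_tgc", "delta_pgc"
))
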