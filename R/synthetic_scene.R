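# Synthetic-scene generator: annual fine-grid land-cover histories,
# degradation events, a static biomass map and per-process AGC flux ground
# truth. The truth bookkeeping uses the same reference densities and response
# curves the flux model is configured with, so closed-loop recovery tests
# have an exact expected value.

# Land-cover class codes (Mapbiomas-like, remappable via a vocabulary).
CLASS_FOREST <- 1L
CLASS_PASTURE <- 2L
CLASS_AGRICULTURE <- 3L
CLASS_BARE <- 4L

# Derived forest-state codes.
ST_NONFOREST <- 0L
ST_OLDGROWTH <- 1L
ST_DEGRADED <- 2L
ST_EDGE <- 3L
ST_SECONDARY <- 4L

#' Land-cover class vocabulary
#'
#' Maps semantic class names to raster codes. Real land-cover products use
#' different integer codes; supplying a remapped vocabulary (e.g. from
#' [read_class_vocabulary()]) adapts the engine without code changes.
#'
#' @return Named list: `forest` (integer vector of forest codes), `cleared`
#'   (codes counting as deforestation targets: pasture, agriculture, bare).
#' @export
class_vocabulary <- function() {
  list(forest = CLASS_FOREST,
       cleared = c(CLASS_PASTURE, CLASS_AGRICULTURE, CLASS_BARE))
}

#' Read a class vocabulary from YAML
#' @param path YAML file with `forest:` and `cleared:` integer arrays.
#' @return Vocabulary list as in [class_vocabulary()].
#' @export
read_class_vocabulary <- function(path) {
  v <- yaml::read_yaml(path)
  stopifnot(!is.null(v$forest), !is.null(v$cleared))
  list(forest = as.integer(v$forest), cleared = as.integer(v$cleared))
}

#' Scene configuration
#'
#' Defines the synthetic study conditions: grid geometry, annual land-cover
#' transition rates, the response-curve parameters used as ground truth, and
#' the observation noise model of the daily L-VOD stream.
#'
#' @param n_coarse_x,n_coarse_y Coarse (L-VOD analog) grid dimensions.
#' @param fine_per_coarse Fine pixels per coarse cell edge (>= 4).
#' @param years Consecutive calendar years (length >= 2).
#' @param pixel_edge_m Fine pixel edge length in metres (30 m analog).
#' @param cell_deg Coarse cell size in planar degrees (0.25 deg analog).
#' @param deforestation_rate Fraction of forest pixels cleared per year.
#' @param degradation_rate Fraction of forest pixels receiving a canopy
#'   disturbance event per year.
#' @param regrowth_rate Fraction of non-forest pixels returning to forest
#'   (secondary regrowth) per year.
#' @param initial_nonforest_frac Fraction of pixels non-forest in year 1.
#' @param ref_og Old-growth reference AGC density, Mg C ha^-1.
#' @param ref_deg Non-edge degraded reference AGC density, Mg C ha^-1; the
#'   implied loss factor is `(ref_og - ref_deg) / ref_og`.
#' @param og_drift Uniform old-growth AGC density drift, Mg C ha^-1 yr^-1
#'   (the "other processes" signal the residual attribution must recover).
#' @param growth_params Chapman-Richards regrowth parameters (A, k, theta).
#' @param edge_params Edge-loss parameters (L_inf, r).
#' @param calib_params True VOD->AGC curve parameters (a, b, c, d).
#' @param edge_buffer_m Edge influence distance from cleared land, metres.
#' @param noise List: vod_sd (per-observation Gaussian sd), seasonal_amplitude
#'   (VOD units), rfi_rate (fraction of observations hit by RFI),
#'   rfi_tb_rmse (threshold above which injected RFI TB-RMSE is drawn),
#'   orbit_offset (constant VOD offset added to ascending passes),
#'   flag_rate (fraction of observations carrying a quality flag).
#' @param inundation_frac Per-cell inundated fraction; scalar recycled to all
#'   cells or vector of length n_cells.
#' @param revisit_days Days between successive acquisitions per orbit.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(n_coarse_x = 8L, n_coarse_y = 8L,
                         fine_per_coarse = 64L, years = 2011:2019,
                         pixel_edge_m = 30, cell_deg = 0.25,
                         deforestation_rate = 0.01,
                         degradation_rate = 0.005,
                         regrowth_rate = 0.02,
                         initial_nonforest_frac = 0.15,
                         ref_og = 126.4, ref_deg = 81.78,
                         og_drift = -0.5,
                         growth_params = list(A = 110, k = 0.035, theta = 1.6),
                         edge_params = list(L_inf = 0.36, r = 0.2),
                         calib_params = list(a = 180, b = 12, c = 0.45, d = 0),
                         edge_buffer_m = 120,
                         noise = list(),
                         inundation_frac = 0,
                         revisit_days = 2L,
                         seed = 42L) {
  noise_default <- list(vod_sd = 0.02, seasonal_amplitude = 0.05,
                        rfi_rate = 0.02, rfi_tb_rmse = 8,
                        orbit_offset = 0.02, flag_rate = 0.01)
  noise <- utils::modifyList(noise_default, noise)
  cfg <- list(
    n_coarse_x = as.integer(n_coarse_x), n_coarse_y = as.integer(n_coarse_y),
    fine_per_coarse = as.integer(fine_per_coarse), years = as.integer(years),
    pixel_edge_m = pixel_edge_m, cell_deg = cell_deg,
    deforestation_rate = deforestation_rate,
    degradation_rate = degradation_rate,
    regrowth_rate = regrowth_rate,
    initial_nonforest_frac = initial_nonforest_frac,
    ref_og = ref_og, ref_deg = ref_deg, og_drift = og_drift,
    growth_params = growth_params, edge_params = edge_params,
    calib_params = calib_params,
    edge_buffer_m = edge_buffer_m, noise = noise,
    inundation_frac = inundation_frac,
    revisit_days = as.integer(revisit_days),
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  rates <- c(cfg$deforestation_rate, cfg$degradation_rate, cfg$regrowth_rate,
             cfg$initial_nonforest_frac, cfg$noise$rfi_rate,
             cfg$noise$flag_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_coarse_x < 1L || cfg$n_coarse_y < 1L) stop("zero-area scene")
  if (cfg$fine_per_coarse < 4L) stop("fine_per_coarse must be >= 4")
  if (length(cfg$years) < 2L) stop("need at least 2 years")
  if (any(diff(cfg$years) != 1L)) stop("years must be consecutive")
  if (cfg$ref_deg >= cfg$ref_og) stop("ref_deg must be < ref_og")
  n_cells <- cfg$n_coarse_x * cfg$n_coarse_y
  if (!length(cfg$inundation_frac) %in% c(1L, n_cells)) {
    stop("inundation_frac must be scalar or one value per coarse cell")
  }
  invisible(cfg)
}

# Clustered patch placement: repeatedly seeds a square patch at a
# weight-sampled candidate pixel until ~n_target pixels are selected.
place_patches <- function(n_target, candidate, weights, halfwidths = 1:3) {
  nr <- nrow(candidate); nc <- ncol(candidate)
  chosen <- matrix(FALSE, nr, nc)
  if (n_target <= 0L) return(chosen)
  placed <- 0L
  idx <- which(candidate)
  if (length(idx) == 0L) return(chosen)
  w <- weights[idx]
  guard <- 0L
  while (placed < n_target && guard < 50L * ceiling(n_target / 4)) {
    guard <- guard + 1L
    seed_px <- if (length(idx) == 1L) idx else sample(idx, 1L, prob = w)
    i <- ((seed_px - 1L) %% nr) + 1L
    j <- ((seed_px - 1L) %/% nr) + 1L
    h <- sample(halfwidths, 1L)
    rows <- max(1L, i - h):min(nr, i + h)
    cols <- max(1L, j - h):min(nc, j + h)
    block <- candidate[rows, cols, drop = FALSE] &
      !chosen[rows, cols, drop = FALSE]
    if (!any(block)) next
    chosen[rows, cols][block] <- TRUE
    placed <- placed + sum(block)
  }
  chosen
}

#' Generate a synthetic scene with known flux ground truth
#'
#' Forward-simulates annual land cover on the fine grid: clustered
#' deforestation patches (spatially biased so a deforestation arc and
#' old-growth-dominated interior both exist), secondary regrowth, canopy
#' disturbance events inside forest, edge zones around cleared land, and a
#' uniform old-growth density drift. Per-process AGC stock changes are booked
#' per coarse cell and year with the configured reference densities and
#' curves, and the per-cell true AGC density series accumulates them.
#'
#' @param config A [scene_config()].
#' @return Object of class `vodcarbon_scene`: list with `config`, `years`,
#'   `classes` (fine int array year-stacked), `events` (logical array),
#'   `biomass` (year-1 density map, Mg C ha^-1), `inundation` (per-cell
#'   fraction), geometry fields, and `truth` (flux table, AGC density series,
#'   state/age arrays for oracle recounts).
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  ncx <- cfg$n_coarse_x; ncy <- cfg$n_coarse_y; f <- cfg$fine_per_coarse
  nxf <- ncx * f; nyf <- ncy * f
  n_years <- length(cfg$years)
  a_px <- (cfg$pixel_edge_m / 100)^2          # ha per fine pixel
  cell_area <- a_px * f^2                     # ha per coarse cell
  lf <- (cfg$ref_og - cfg$ref_deg) / cfg$ref_og
  gcurve <- do.call(growth_curve, cfg$growth_params)
  ecurve <- do.call(edge_loss_curve, cfg$edge_params)
  r_px <- cfg$edge_buffer_m / cfg$pixel_edge_m

  # spatial bias: clearing pressure increases toward the south-east corner
  # (a deforestation-arc analog); the steeper initial-cover gradient leaves
  # an intact interior of >90% old-growth reference cells while spanning a
  # wide cross-cell biomass range for the calibration fit
  rowfrac <- matrix(seq_len(nyf) / nyf, nyf, nxf)
  colfrac <- matrix(rep(seq_len(nxf) / nxf, each = nyf), nyf, nxf)
  u <- (rowfrac + colfrac) / 2
  wbias <- exp(7 * u)
  wbias_init <- exp(9 * u)

  classes <- array(CLASS_FOREST, dim = c(nyf, nxf, n_years))
  events <- array(FALSE, dim = c(nyf, nxf, n_years))

  # year 1: initial non-forest (long-cleared pasture, never observed forest)
  n_init <- round(cfg$initial_nonforest_frac * nyf * nxf)
  init_nf <- place_patches(n_init, matrix(TRUE, nyf, nxf), wbias_init,
                           halfwidths = 2:5)
  cls <- matrix(CLASS_FOREST, nyf, nxf)
  cls[init_nf] <- CLASS_PASTURE
  classes[, , 1L] <- cls

  state <- matrix(ST_NONFOREST, nyf, nxf)
  state[cls == CLASS_FOREST] <- ST_OLDGROWTH
  sec_age <- matrix(0L, nyf, nxf)
  edge_age <- matrix(0L, nyf, nxf)
  wasdeg <- matrix(FALSE, nyf, nxf)
  deg_ever <- matrix(FALSE, nyf, nxf)
  ever_forest <- cls == CLASS_FOREST

  states_arr <- array(ST_NONFOREST, dim = c(nyf, nxf, n_years))
  sec_age_arr <- array(0L, dim = c(nyf, nxf, n_years))
  edge_age_arr <- array(0L, dim = c(nyf, nxf, n_years))
  states_arr[, , 1L] <- state

  processes <- c("deforestation", "edge_degradation", "nonedge_degradation",
                 "secondary_growth", "old_growth")
  flux <- array(0, dim = c(ncy, ncx, n_years, length(processes)),
                dimnames = list(NULL, NULL, NULL, processes))

  cleared_classes <- c(CLASS_PASTURE, CLASS_AGRICULTURE, CLASS_BARE)

  for (t in 2:n_years) {
    prev_cls <- classes[, , t - 1L]
    forest_prev <- prev_cls == CLASS_FOREST
    cls <- prev_cls

    # clustered deforestation in forest, biased toward the clearing arc
    n_def <- round(cfg$deforestation_rate * sum(forest_prev))
    def_px <- place_patches(n_def, forest_prev, wbias)
    if (any(def_px)) {
      cls[def_px] <- sample(cleared_classes, sum(def_px), replace = TRUE,
                            prob = c(0.7, 0.2, 0.1))
    }

    # secondary regrowth on non-forest
    nf_prev <- !forest_prev
    n_reg <- round(cfg$regrowth_rate * sum(nf_prev))
    reg_px <- place_patches(n_reg, nf_prev, wbias, halfwidths = 1:2)
    cls[reg_px] <- CLASS_FOREST

    classes[, , t] <- cls
    forest_now <- cls == CLASS_FOREST

    # 1) deforestation losses from the prior state's density
    newly_def <- forest_prev & !forest_now
    dloss <- matrix(0, nyf, nxf)
    sel <- newly_def & state == ST_OLDGROWTH
    dloss[sel] <- cfg$ref_og
    sel <- newly_def & state == ST_DEGRADED
    dloss[sel] <- cfg$ref_og * (1 - lf)
    sel <- newly_def & state == ST_EDGE
    if (any(sel)) {
      dloss[sel] <- cfg$ref_og *
        (1 - edge_loss(ecurve, edge_age[sel], ifelse(wasdeg[sel], lf, 0)))
    }
    sel <- newly_def & state == ST_SECONDARY
    if (any(sel)) dloss[sel] <- growth_agc(gcurve, sec_age[sel])
    flux[, , t, "deforestation"] <- -block_sum(dloss, f) * a_px

    # 2) secondary forest: new regrowth + aging of persisting stands
    new_sec <- !forest_prev & forest_now
    persist_sec <- state == ST_SECONDARY & forest_now
    sgain <- matrix(0, nyf, nxf)
    if (any(persist_sec)) {
      a1 <- sec_age[persist_sec]
      sgain[persist_sec] <- growth_agc(gcurve, a1 + 1L) - growth_agc(gcurve, a1)
    }
    sgain[new_sec] <- growth_agc(gcurve, 1L)
    flux[, , t, "secondary_growth"] <- block_sum(sgain, f) * a_px
    sec_age[persist_sec] <- sec_age[persist_sec] + 1L
    sec_age[new_sec] <- 1L
    sec_age[!forest_now] <- 0L

    # 3) edge zones around currently cleared, previously forested land
    src <- !forest_now & ever_forest
    zone <- dilate_disk(src, r_px)
    is_sec <- sec_age > 0L
    still_edge <- state == ST_EDGE & forest_now
    new_edge <- forest_now & !is_sec & zone & !still_edge &
      (state == ST_OLDGROWTH | state == ST_DEGRADED)
    wasdeg[new_edge] <- state[new_edge] == ST_DEGRADED
    edge_age[still_edge] <- edge_age[still_edge] + 1L
    edge_age[new_edge] <- 1L
    edge_age[!forest_now] <- 0L
    edge_now <- still_edge | new_edge
    eloss <- matrix(0, nyf, nxf)
    if (any(edge_now)) {
      aa <- edge_age[edge_now]
      fl <- ifelse(wasdeg[edge_now], lf, 0)
      eloss[edge_now] <- cfg$ref_og *
        (edge_loss(ecurve, aa, fl) - edge_loss(ecurve, aa - 1L, fl))
    }
    flux[, , t, "edge_degradation"] <- -block_sum(eloss, f) * a_px

    # 4) canopy disturbance events (only inside forest); new non-edge
    #    degradation is counted on old-growth only
    n_ev <- round(cfg$degradation_rate * sum(forest_now))
    ev <- matrix(FALSE, nyf, nxf)
    if (n_ev > 0L) {
      cand <- which(forest_now)
      ev[sample(cand, min(n_ev, length(cand)), prob = wbias[cand])] <- TRUE
    }
    events[, , t] <- ev
    new_deg <- ev & forest_now & !is_sec & !edge_now & !deg_ever
    deg_ever <- deg_ever | new_deg
    flux[, , t, "nonedge_degradation"] <-
      -block_sum(new_deg, f) * a_px * cfg$ref_og * lf

    # 5) recompose states
    state <- matrix(ST_NONFOREST, nyf, nxf)
    state[forest_now] <- ST_OLDGROWTH
    state[forest_now & deg_ever] <- ST_DEGRADED
    state[edge_now] <- ST_EDGE
    state[is_sec & forest_now] <- ST_SECONDARY
    wasdeg[!edge_now] <- FALSE

    # 6) uniform old-growth drift (the residual-attribution target signal)
    og_now <- state == ST_OLDGROWTH
    flux[, , t, "old_growth"] <- block_sum(og_now, f) * a_px * cfg$og_drift

    ever_forest <- ever_forest | forest_now
    states_arr[, , t] <- state
    sec_age_arr[, , t] <- sec_age
    edge_age_arr[, , t] <- edge_age
  }

  # per-cell true AGC density series: year-1 stocks + accumulated fluxes
  dens1 <- block_sum((states_arr[, , 1L] == ST_OLDGROWTH) * cfg$ref_og, f) / f^2
  ids <- cell_id_grid(ncy, ncx)
  dens <- matrix(NA_real_, ncy * ncx, n_years)
  dens[as.vector(ids), 1L] <- as.vector(dens1)
  total_by_year <- apply(flux, c(1, 2, 3), sum)
  for (t in 2:n_years) {
    dens[as.vector(ids), t] <- dens[as.vector(ids), t - 1L] +
      as.vector(total_by_year[, , t]) / cell_area
  }

  flux_dt <- data.table::rbindlist(lapply(2:n_years, function(t) {
    data.table::rbindlist(lapply(processes, function(p) {
      data.table::data.table(
        cell_id = as.vector(ids), year = cfg$years[t], process = p,
        delta_mgc = as.vector(flux[, , t, p])
      )
    }))
  }))
  data.table::setkey(flux_dt, cell_id, year, process)

  agc_dt <- data.table::data.table(
    cell_id = rep(seq_len(ncy * ncx), n_years),
    year = rep(cfg$years, each = ncy * ncx),
    density = as.vector(dens)
  )
  data.table::setkey(agc_dt, cell_id, year)

  inund <- rep(cfg$inundation_frac, length.out = ncy * ncx)
  names(inund) <- seq_len(ncy * ncx)

  structure(list(
    config = cfg, years = cfg$years,
    classes = classes, events = events,
    biomass = (states_arr[, , 1L] == ST_OLDGROWTH) * cfg$ref_og,
    inundation = inund,
    n_coarse_x = ncx, n_coarse_y = ncy, fine_per_coarse = f,
    pixel_area_ha = a_px, cell_area_ha = cell_area,
    pixel_edge_m = cfg$pixel_edge_m, cell_deg = cfg$cell_deg,
    origin = c(x = 0, y = 0),
    truth = list(flux = flux_dt, agc_density = agc_dt,
                 states = states_arr, sec_age = sec_age_arr,
                 edge_age = edge_age_arr, loss_factor = lf)
  ), class = "vodcarbon_scene")
}

#' @export
print.vodcarbon_scene <- function(x, ...) {
  cat("<vodcarbon_scene> ", x$n_coarse_y, "x", x$n_coarse_x,
      " coarse cells, ", x$fine_per_coarse, "x subdivision, years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  invisible(x)
}
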