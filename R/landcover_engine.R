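# Land-cover engine: derives annual deforestation, secondary-forest age,
# 120 m edge zones with age, non-edge degradation and the old-growth layer
# from fine-grid class and disturbance-event rasters, then aggregates states
# to fractional covers on the coarse grid.
#
# State rules (applied in this per-year order, all changes booked to the
# detection year):
#   1. deforestation: forest -> pasture/agriculture/bare;
#   2. secondary forest: non-forest for >= 1 year, then forest; age = run of
#      consecutive forest years (pixels forested since the first history
#      year are never secondary);
#   3. edge zones: non-secondary forest within the buffer distance of
#      currently cleared, previously forested land; edge age ratchets while
#      the pixel remains forest (edge history is never erased);
#   4. non-edge degradation: disturbance events on old-growth pixels only
#      (events on edge, secondary or already-degraded pixels are ignored
#      with counters); the degraded-ever baseline is a ratchet.
# Precedence for non-secondary forest: edge > degraded > old-growth.
# Secondary forest keeps its state inside edge buffers so regrowth is
# accounted by the growth curve, not double-booked as edge loss.

#' Detect newly deforested pixels between two annual class rasters
#'
#' TRUE exactly where the previous class is forest and the current class is
#' pasture, agriculture or bare ground.
#'
#' @param classes_prev,classes_cur Co-registered integer class matrices.
#' @param vocab Class vocabulary (see [class_vocabulary()]).
#' @return Logical matrix of newly deforested pixels.
#' @export
detect_deforestation <- function(classes_prev, classes_cur,
                                 vocab = class_vocabulary()) {
  stopifnot(identical(dim(classes_prev), dim(classes_cur)))
  known <- c(vocab$forest, vocab$cleared)
  bad <- setdiff(unique(c(classes_prev, classes_cur)), known)
  if (length(bad) > 0L) {
    stop("unknown class code(s): ", paste(bad, collapse = ", "))
  }
  res <- (classes_prev %in% vocab$forest) & (classes_cur %in% vocab$cleared)
  matrix(res, nrow(classes_prev), ncol(classes_prev))
}

#' Secondary-forest extent and age from a class history
#'
#' A pixel is secondary in year t if it was non-forest in some earlier year
#' and forest continuously since; its age is the run of consecutive forest
#' years (age 1 in the first forest year). Clearing resets the age to 0; a
#' later return to forest restarts at age 1. Pixels forest in every history
#' year can never be identified as secondary.
#'
#' @param class_history Integer array (ny, nx, n_years) of class rasters.
#' @param vocab Class vocabulary.
#' @return Integer array (ny, nx, n_years) of secondary ages (0 = not
#'   secondary).
#' @export
update_secondary_forest <- function(class_history,
                                    vocab = class_vocabulary()) {
  dims <- dim(class_history)
  if (length(dims) != 3L || dims[3L] < 2L) {
    stop("need a class history of at least 2 years")
  }
  ages <- array(0L, dim = dims)
  forest_prev <- matrix(class_history[, , 1L] %in% vocab$forest,
                        dims[1L], dims[2L])
  age <- matrix(0L, dims[1L], dims[2L])
  for (t in 2:dims[3L]) {
    forest_now <- matrix(class_history[, , t] %in% vocab$forest,
                         dims[1L], dims[2L])
    new_sec <- forest_now & !forest_prev
    persist <- forest_now & age > 0L
    age[persist] <- age[persist] + 1L
    age[new_sec] <- 1L
    age[!forest_now] <- 0L
    ages[, , t] <- age
    forest_prev <- forest_now
  }
  ages
}

#' Forest-edge zones and edge age
#'
#' Eligible forest pixels within the Euclidean buffer distance (pixel
#' centres, inclusive) of any currently cleared, previously forested pixel
#' become edge; a newly exposed edge pixel gets age 1 and existing edge
#' pixels increment their age each year they remain forest (the zone is a
#' ratchet: regrowth of the adjacent clearing does not erase edge history).
#'
#' @param forest Logical matrix: forest this year.
#' @param cleared_source Logical matrix: currently non-forest pixels that
#'   were forest in some earlier year (the deforested edge source).
#' @param prior_edge_age Integer matrix of last year's edge ages.
#' @param eligible Logical matrix of pixels allowed to become edge
#'   (non-secondary forest); defaults to `forest`.
#' @param pixel_edge_m Fine pixel edge length, metres.
#' @param buffer_m Edge influence distance, metres (default 120, inclusive).
#' @return List: `edge` (logical matrix), `edge_age` (integer matrix),
#'   `new_edge` (logical matrix of first-year edge pixels).
#' @export
compute_edge_zones <- function(forest, cleared_source, prior_edge_age,
                               eligible = forest, pixel_edge_m = 30,
                               buffer_m = 120) {
  r_px <- buffer_m / pixel_edge_m
  zone <- dilate_disk(cleared_source, r_px)
  still_edge <- prior_edge_age > 0L & forest
  new_edge <- eligible & zone & !still_edge
  edge_age <- matrix(0L, nrow(forest), ncol(forest))
  edge_age[still_edge] <- prior_edge_age[still_edge] + 1L
  edge_age[new_edge] <- 1L
  list(edge = still_edge | new_edge, edge_age = edge_age,
       new_edge = new_edge)
}

#' Extract new non-edge degradation events
#'
#' Disturbance events in year t on pixels that are still forest, not in the
#' edge zone, not secondary and not already in the degraded baseline become
#' new non-edge degradation and join the baseline permanently. Events on
#' non-forest, edge, secondary or already-degraded pixels are ignored and
#' counted.
#'
#' @param event Logical matrix of disturbance events this year.
#' @param forest Logical matrix: forest this year.
#' @param edge Logical matrix: edge zone this year.
#' @param secondary Logical matrix: secondary forest this year.
#' @param deg_baseline Logical matrix: degraded-ever baseline before this
#'   year (initialized from all event years before the analysis start).
#' @param recurrent_losses If TRUE, repeat events on already-degraded pixels
#'   are returned as additional loss events (default FALSE: not
#'   double-counted).
#' @return List: `new_deg` (logical matrix), `deg_baseline` (updated
#'   ratchet), `ignored` (named counts: non_forest, edge, secondary,
#'   already_degraded).
#' @export
extract_degradation_events <- function(event, forest, edge, secondary,
                                       deg_baseline,
                                       recurrent_losses = FALSE) {
  ignored <- c(
    non_forest = sum(event & !forest),
    edge = sum(event & forest & edge),
    secondary = sum(event & forest & !edge & secondary),
    already_degraded = sum(event & forest & !edge & !secondary & deg_baseline)
  )
  new_deg <- event & forest & !edge & !secondary & !deg_baseline
  if (recurrent_losses) {
    new_deg <- new_deg | (event & forest & !edge & !secondary & deg_baseline)
  }
  list(new_deg = new_deg, deg_baseline = deg_baseline | new_deg,
       ignored = ignored)
}

#' Old-growth forest layer
#'
#' Old-growth = forest, never degraded over the disturbance record, not
#' secondary, and outside the edge zone.
#'
#' @param forest,deg_baseline,secondary,edge Co-registered logical matrices.
#' @return Logical matrix of old-growth pixels.
#' @export
derive_old_growth <- function(forest, deg_baseline, secondary, edge) {
  forest & !deg_baseline & !secondary & !edge
}

#' Aggregate per-pixel states to coarse fractional covers
#'
#' Per coarse cell and year: fraction of pixels in each of the five states
#' (old-growth, degraded non-edge, edge, secondary, non-forest). States tile
#' every pixel, so the fractions sum to 1.
#'
#' @param states Integer array (ny, nx, n_years) of state codes as produced
#'   by [run_landcover()].
#' @param fine_per_coarse Subdivision factor.
#' @param years Calendar years matching the third dimension.
#' @param pixel_area_ha Area of one fine pixel, hectares.
#' @return data.table: cell_id, year, f_oldgrowth, f_degraded, f_edge,
#'   f_secondary, f_nonforest, area_ha.
#' @export
aggregate_fractions <- function(states, fine_per_coarse, years,
                                pixel_area_ha) {
  f <- fine_per_coarse
  dims <- dim(states)
  ncy <- dims[1L] %/% f; ncx <- dims[2L] %/% f
  ids <- cell_id_grid(ncy, ncx)
  n_px <- f^2
  out <- vector("list", dims[3L])
  codes <- c(f_nonforest = ST_NONFOREST, f_oldgrowth = ST_OLDGROWTH,
             f_degraded = ST_DEGRADED, f_edge = ST_EDGE,
             f_secondary = ST_SECONDARY)
  for (t in seq_len(dims[3L])) {
    st <- states[, , t]
    dt <- data.table::data.table(cell_id = as.vector(ids),
                                 year = years[t],
                                 area_ha = n_px * pixel_area_ha)
    for (nm in names(codes)) {
      dt[[nm]] <- as.vector(block_sum(st == codes[[nm]], f)) / n_px
    }
    out[[t]] <- dt
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("cell_id", "year", "f_oldgrowth",
                                 "f_degraded", "f_edge", "f_secondary",
                                 "f_nonforest", "area_ha"))
  data.table::setkey(res, cell_id, year)
  res[]
}

#' Run the land-cover engine over a scene
#'
#' Re-derives the annual forest-state layers from the emitted class and
#' event rasters (independently of the generator's internal simulation) and
#' produces the per-process area tables the flux model consumes. Consistency
#' between datasets is enforced at the fine resolution, before any
#' aggregation to fractional covers.
#'
#' @param scene A [generate_scene()] result, or any list with `classes`,
#'   `events`, `years`, `fine_per_coarse`, `pixel_area_ha`, `pixel_edge_m`.
#' @param vocab Class vocabulary.
#' @param buffer_m Edge influence distance, metres.
#' @param deg_baseline Initial degraded-ever baseline (logical matrix) from
#'   pre-analysis disturbance years; defaults to empty.
#' @param recurrent_degradation_losses Passed to
#'   [extract_degradation_events()].
#' @return List: `states` (int array), `sec_age`, `edge_age` (int arrays),
#'   `fractions` (FractionStack data.table), `deforestation` (year, cell_id,
#'   prior_state, age, wasdeg, area_ha), `nonedge_degradation` (year,
#'   cell_id, area_ha), `edge` (year, cell_id, age, wasdeg, area_ha),
#'   `secondary` (year, cell_id, age, area_ha), `ignored_events` (per-year
#'   counts).
#' @export
run_landcover <- function(scene, vocab = class_vocabulary(), buffer_m = 120,
                          deg_baseline = NULL,
                          recurrent_degradation_losses = FALSE) {
  classes <- scene$classes
  events <- scene$events
  years <- scene$years
  f <- scene$fine_per_coarse
  a_px <- scene$pixel_area_ha
  dims <- dim(classes)
  nyf <- dims[1L]; nxf <- dims[2L]; n_years <- dims[3L]
  ncy <- nyf %/% f; ncx <- nxf %/% f
  px_cells <- pixel_cell_ids(ncy, ncx, f)

  sec_ages <- update_secondary_forest(classes, vocab)

  if (is.null(deg_baseline)) deg_baseline <- matrix(FALSE, nyf, nxf)
  forest_prev <- matrix(classes[, , 1L] %in% vocab$forest, nyf, nxf)
  ever_forest <- forest_prev
  edge_age <- matrix(0L, nyf, nxf)
  wasdeg <- matrix(FALSE, nyf, nxf)
  state <- matrix(ST_NONFOREST, nyf, nxf)
  state[forest_prev] <- ST_OLDGROWTH
  state[forest_prev & deg_baseline] <- ST_DEGRADED

  states <- array(ST_NONFOREST, dim = dims)
  edge_ages <- array(0L, dim = dims)
  states[, , 1L] <- state

  defor_l <- list(); nonedge_l <- list(); edge_l <- list(); sec_l <- list()
  ignored_l <- list()

  count_table <- function(sel, by_list) {
    # aggregate pixel selections to (cell, extra columns) area tables
    if (!any(sel)) return(NULL)
    dt <- data.table::as.data.table(c(list(cell_id = px_cells[sel]), by_list))
    dt <- dt[, .(area_ha = .N * a_px), by = names(dt)]
    dt
  }

  for (t in 2:n_years) {
    cls <- classes[, , t]
    forest_now <- matrix(cls %in% vocab$forest, nyf, nxf)
    newly_def <- detect_deforestation(
      matrix(classes[, , t - 1L], nyf, nxf), matrix(cls, nyf, nxf), vocab)

    # deforested areas split by prior state (ages from year t-1)
    prior <- state
    dd <- NULL
    if (any(newly_def)) {
      sel <- newly_def
      pr_state <- c("nonforest", "oldgrowth", "degraded", "edge",
                    "secondary")[prior[sel] + 1L]
      age_prev <- ifelse(prior[sel] == ST_EDGE, edge_age[sel],
                         ifelse(prior[sel] == ST_SECONDARY,
                                sec_ages[, , t - 1L][sel], 0L))
      dd <- data.table::data.table(
        cell_id = px_cells[sel], prior_state = pr_state,
        age = as.integer(age_prev), wasdeg = wasdeg[sel]
      )
      dd <- dd[, .(area_ha = .N * a_px),
               by = .(cell_id, prior_state, age, wasdeg)]
      dd[, year := years[t]]
    }
    defor_l[[t]] <- dd

    sec_age_now <- matrix(sec_ages[, , t], nyf, nxf)
    is_sec <- sec_age_now > 0L

    # edge zones around currently cleared, previously forested land
    src <- !forest_now & ever_forest
    ez <- compute_edge_zones(forest_now, src, edge_age,
                             eligible = forest_now & !is_sec &
                               (state == ST_OLDGROWTH | state == ST_DEGRADED),
                             pixel_edge_m = scene$pixel_edge_m,
                             buffer_m = buffer_m)
    wasdeg[ez$new_edge] <- state[ez$new_edge] == ST_DEGRADED
    edge_age <- ez$edge_age
    edge_now <- ez$edge
    wasdeg[!edge_now] <- FALSE
    ee <- count_table(edge_now, list(age = edge_age[edge_now],
                                     wasdeg = wasdeg[edge_now]))
    if (!is.null(ee)) ee[, year := years[t]]
    edge_l[[t]] <- ee

    # new non-edge degradation from this year's disturbance events
    ev <- extract_degradation_events(
      matrix(events[, , t], nyf, nxf), forest_now, edge_now, is_sec,
      deg_baseline, recurrent_losses = recurrent_degradation_losses)
    deg_baseline <- ev$deg_baseline
    nd <- count_table(ev$new_deg, list())
    if (!is.null(nd)) nd[, year := years[t]]
    nonedge_l[[t]] <- nd
    ignored_l[[t]] <- data.table::data.table(
      year = years[t], t(ev$ignored))

    # secondary stands by age (new age-1 + persisting)
    ss <- count_table(is_sec, list(age = sec_age_now[is_sec]))
    if (!is.null(ss)) ss[, year := years[t]]
    sec_l[[t]] <- ss

    # recompose the state partition
    state <- matrix(ST_NONFOREST, nyf, nxf)
    og <- derive_old_growth(forest_now, deg_baseline, is_sec, edge_now)
    state[og] <- ST_OLDGROWTH
    state[forest_now & deg_baseline & !is_sec & !edge_now] <- ST_DEGRADED
    state[edge_now] <- ST_EDGE
    state[is_sec] <- ST_SECONDARY
    states[, , t] <- state
    edge_ages[, , t] <- edge_age

    ever_forest <- ever_forest | forest_now
    forest_prev <- forest_now
  }

  list(
    states = states, sec_age = sec_ages, edge_age = edge_ages,
    fractions = aggregate_fractions(states, f, years, a_px),
    deforestation = data.table::rbindlist(defor_l, use.names = TRUE),
    nonedge_degradation = data.table::rbindlist(nonedge_l, use.names = TRUE),
    edge = data.table::rbindlist(edge_l, use.names = TRUE),
    secondary = data.table::rbindlist(sec_l, use.names = TRUE),
    ignored_events = data.table::rbindlist(ignored_l, use.names = TRUE)
  )
}

utils::globalVariables(c("area_ha", "prior_state", "age", "wasdeg",
                         "f_oldgrowth"))
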