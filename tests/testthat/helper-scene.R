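# Shared fixtures: small scene configurations and a memo cache so the heavy
# acceptance-scale runs are computed once per test session.

.vc_cache <- new.env(parent = emptyenv())

vc_cached <- function(key, expr) {
  if (!exists(key, envir = .vc_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .vc_cache)
  }
  get(key, envir = .vc_cache, inherits = FALSE)
}

# 4x4 coarse cells, 16x subdivision: fast unit-test world
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_coarse_x = 4L, n_coarse_y = 4L, fine_per_coarse = 16L,
         years = 2011:2016, seed = 42L),
    list(...))
  do.call(scene_config, args)
}

# noise list with everything off (deterministic observation stream)
quiet_noise <- function(...) {
  utils::modifyList(
    list(vod_sd = 0, seasonal_amplitude = 0, rfi_rate = 0,
         rfi_tb_rmse = 8, orbit_offset = 0, flag_rate = 0),
    list(...))
}

# hand-built observation streams for filter unit tests
make_obs <- function(cell_id = 1L, date = as.Date("2015-02-01"),
                     orbit = "ASC", vod = 0.5, tb_rmse = 3, flag = 0L) {
  data.table::data.table(cell_id = as.integer(cell_id),
                         date = as.Date(date), orbit = orbit, vod = vod,
                         tb_rmse = tb_rmse, flag = as.integer(flag))
}

# acceptance-scale runs (8x8 coarse cells, 64x subdivision, 9 years, seed 7)
acceptance_scene <- function() {
  vc_cached("acc_scene", generate_scene(scene_config(seed = 7L)))
}

acceptance_pipeline <- function() {
  vc_cached("acc_pipeline", suppressWarnings(
    run_full_pipeline(scene_config(seed = 7L), scene = acceptance_scene())))
}

acceptance_truth_fluxes <- function() {
  vc_cached("acc_truth_fluxes", {
    sc <- acceptance_scene()
    lc <- vc_cached("acc_lc", run_landcover(sc))
    dl <- lvod_change(truth_agc_grid(sc), sc$cell_area_ha)
    compute_fluxes(lc, sc, dl)
  })
}
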