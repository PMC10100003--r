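test_that("quality masks drop flagged observations and inundated cells", {
  obs <- rbind(
    make_obs(cell_id = 1L, vod = 0.5),
    make_obs(cell_id = 1L, vod = 0.6, flag = 1L),
    make_obs(cell_id = 2L, vod = 0.7),
    make_obs(cell_id = 3L, vod = 0.8)
  )
  inund <- c(`1` = 0, `2` = 0.30, `3` = 0.25)
  out <- apply_quality_masks(obs, inund)
  # cell 2 (30% inundated) fully removed; 25% exactly is retained (strictly
  # "more than"); clean observation passes unchanged
  expect_identical(sort(unique(out$cell_id)), c(1L, 3L))
  expect_identical(out[cell_id == 1L]$vod, 0.5)
  expect_error(apply_quality_masks(make_obs(cell_id = 9L), inund),
               "inundation")
  # idempotent
  expect_identical(apply_quality_masks(out, inund), out)
})

test_that("RFI filter is strict at 8 K and idempotent", {
  obs <- rbind(make_obs(tb_rmse = 9), make_obs(tb_rmse = 8),
               make_obs(tb_rmse = 0.5))
  out <- filter_rfi(obs)
  expect_identical(out$tb_rmse, c(8, 0.5))
  expect_identical(filter_rfi(out), out)
  clean <- make_obs(tb_rmse = c(1, 5, 7.99))
  expect_identical(filter_rfi(clean), clean)
  expect_error(filter_rfi(make_obs(tb_rmse = -1)), "negative")
})

test_that("orbit reconciliation removes high-TB data in offending trimesters", {
  days_a <- as.Date("2015-01-01") + c(0, 4, 8, 12)
  days_d <- as.Date("2015-01-01") + c(2, 6, 10, 14)
  base <- rbind(
    make_obs(date = days_a, orbit = "ASC", vod = 0.80, tb_rmse = 3),
    make_obs(date = days_d, orbit = "DESC", vod = 0.86,
             tb_rmse = c(3, 3, 3, 6))
  )
  out <- reconcile_orbits(base)
  # means differ by 0.06 > 0.05: the 6 K record is removed, 3 K ones stay
  expect_identical(nrow(out), 7L)
  expect_false(any(out$tb_rmse > 5))

  # difference of exactly 0.05 does not trigger removal (strict rule)
  exact <- rbind(
    make_obs(date = days_a, orbit = "ASC", vod = 0.80, tb_rmse = 3),
    make_obs(date = days_d, orbit = "DESC", vod = 0.85,
             tb_rmse = c(3, 3, 3, 6))
  )
  expect_identical(nrow(reconcile_orbits(exact)), 8L)

  # same-day pairs keep the record with the lower TB-RMSE
  pair <- rbind(
    make_obs(date = "2015-02-01", orbit = "ASC", vod = 0.81, tb_rmse = 3),
    make_obs(date = "2015-02-01", orbit = "DESC", vod = 0.83, tb_rmse = 4)
  )
  kept <- reconcile_orbits(pair)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$orbit, "ASC")

  # a trimester observed by a single orbit skips the test with a warning
  solo <- make_obs(date = days_a, orbit = "ASC", vod = 0.8, tb_rmse = 3)
  expect_warning(out_solo <- reconcile_orbits(solo), "single")
  expect_identical(nrow(out_solo), 4L)
})

test_that("trimester outlier rejection matches the hand-computed oracle", {
  days <- as.Date("2015-01-01") + seq(0, 27, by = 3)
  vals <- c(rep(0.8, 9), 1.6)
  obs <- make_obs(date = days, vod = vals)
  # oracle: mean 0.88, sd 0.2530; |1.6 - 0.88| = 0.72 > 2 sd = 0.5060
  m <- mean(vals); s <- sd(vals)
  expect_true(abs(1.6 - m) > 2 * s)
  expect_true(all(abs(0.8 - m) <= 2 * s))
  out <- remove_outliers(obs)
  expect_identical(out$vod, rep(0.8, 9))

  # constant series: SD = 0, nothing removed
  const <- make_obs(date = days, vod = 0.8)
  expect_identical(nrow(remove_outliers(const)), length(days))
  # fewer than 3 observations pass through unchanged
  two <- make_obs(date = days[1:2], vod = c(0.1, 9))
  expect_identical(nrow(remove_outliers(two)), 2L)
})

test_that("seasonal-trend fit recovers constants, sinusoids and ramps", {
  days <- seq(as.Date("2013-01-01"), as.Date("2015-12-31"), by = 2)
  # constant limit
  const <- make_obs(date = days, vod = 0.7)
  ser <- fit_seasonal_trend(const)
  expect_lt(max(abs(ser$smoothed - 0.7)), 1e-8)
  expect_lt(max(abs(ser$trend - 0.7)), 1e-8)

  # pure annual sinusoid: trend flat within 2% of the amplitude
  tt <- as.numeric(days - days[1L]) / 365.25
  sine <- make_obs(date = days, vod = 0.5 + 0.1 * sin(2 * pi * tt))
  ser2 <- fit_seasonal_trend(sine)
  expect_lt(max(abs(ser2$trend - 0.5)), 0.002)
  # the trend carries almost no annual-frequency power relative to smoothed
  tg <- as.numeric(ser2$dates - ser2$dates[1L]) / 365.25
  amp <- function(x) {
    2 * sqrt(mean(x * cos(2 * pi * tg))^2 + mean(x * sin(2 * pi * tg))^2)
  }
  expect_lt(amp(ser2$trend - mean(ser2$trend)),
            0.05 * amp(ser2$smoothed - mean(ser2$smoothed)))

  # linear ramp + sinusoid: trend recovers the ramp slope within 5%
  ramp <- make_obs(date = days,
                   vod = 0.5 + 0.02 * tt + 0.1 * sin(2 * pi * tt))
  ser3 <- fit_seasonal_trend(ramp)
  slope <- coef(lm(ser3$trend ~ tg))[[2L]]
  expect_lt(abs(slope - 0.02) / 0.02, 0.05)

  expect_error(fit_seasonal_trend(make_obs(date = days[1:5], vod = 1)),
               "8 distinct")
  expect_error(
    fit_seasonal_trend(make_obs(date = days[1:30], vod = rnorm(30))),
    "2 years")
})

test_that("annual indices cover the Jan-Apr window with missing handling", {
  days <- seq(as.Date("2013-01-01"), as.Date("2015-12-31"), by = 2)
  const <- make_obs(date = days, vod = 0.9)
  ser <- fit_seasonal_trend(const)
  idx <- annual_indices(ser, 2014L, const)
  expect_equal(idx$idx_max_smooth, 0.9, tolerance = 1e-8)
  expect_equal(idx$idx_mean_smooth, 0.9, tolerance = 1e-8)
  expect_equal(idx$idx_mean_trend, 0.9, tolerance = 1e-8)

  tt <- as.numeric(days - days[1L]) / 365.25
  sine <- make_obs(date = days, vod = 0.8 + 0.1 * sin(2 * pi * tt))
  idx2 <- annual_indices(fit_seasonal_trend(sine), 2014L, sine)
  expect_gt(idx2$idx_max_smooth, idx2$idx_mean_smooth)

  expect_error(annual_indices(ser, 2016L, const), "not covered")
  # too few retained observations in the window: flagged missing, never zero
  sparse <- const[date < as.Date("2014-01-10") | date > as.Date("2014-04-20")]
  idx3 <- annual_indices(ser, 2014L, sparse)
  expect_true(is.na(idx3$idx_mean_trend))
})

test_that("a clean stream passes every filter stage without loss", {
  # static world: without contamination the filters must not eat data (the
  # scale-free 2 SD rule would trim deterministic signal kinks otherwise)
  cfg <- small_cfg(noise = quiet_noise(), deforestation_rate = 0,
                   degradation_rate = 0, regrowth_rate = 0, og_drift = 0)
  sc <- generate_scene(cfg)
  obs <- generate_lvod_series(sc)
  res <- process_lvod(obs, sc$inundation, years = cfg$years)
  lg <- res$log
  # masks, RFI and outlier stages remove nothing
  expect_identical(lg[stage != "orbit_reconciliation", sum(n_removed)], 0)
  # orbit reconciliation only combines same-day pairs: every observed
  # cell-day survives
  days_in <- unique(obs[, .(cell_id, date)])
  expect_identical(lg[stage == "orbit_reconciliation", n_out],
                   as.numeric(nrow(days_in)))
  # monotone data loss across stages
  expect_true(all(lg$n_out <= lg$n_in))
})

test_that("pipeline order and per-stage logging are exposed", {
  cfg <- small_cfg()
  sc <- generate_scene(cfg)
  obs <- generate_lvod_series(sc)
  res <- process_lvod(obs, sc$inundation, years = cfg$years)
  expect_identical(res$log$stage, c("quality_masks", "rfi",
                                    "orbit_reconciliation", "outliers"))
  expect_true(all(res$log$n_removed >= 0))
  expect_identical(
    sort(names(res$indices)),
    sort(c("cell_id", "year", "idx_max_smooth", "idx_mean_smooth",
           "idx_mean_trend", "n_obs_used")))
})
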