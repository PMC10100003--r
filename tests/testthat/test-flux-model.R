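test_that("loss factor arithmetic and preconditions", {
  expect_equal(loss_factor(200, 100), 0.5)
  expect_error(loss_factor(100, 100), "below")
  expect_error(loss_factor(-1, 0.5), "positive")
})

test_that("regional reference medians match a brute-force window oracle", {
  # uniform field: every cell gets the constant
  f <- 4L
  bio <- matrix(130, 5 * f, 5 * f)
  og <- matrix(TRUE, 5 * f, 5 * f)
  refs <- regional_reference_agc(bio, og, f, cell_deg = 0.25, radius_deg = 1)
  expect_true(all(refs$ref_og == 130))
  expect_false(any(refs$flagged))

  # heterogeneous field vs an enumerated in-radius brute force
  set.seed(21)
  vals <- matrix(runif(25, 80, 150), 5, 5, byrow = TRUE)
  bio2 <- vals[rep(1:5, each = f), rep(1:5, each = f)]
  og2 <- matrix(runif(25 * f^2) < 0.95, 5 * f, 5 * f)
  refs2 <- regional_reference_agc(bio2, og2, f, radius_deg = 1)
  og_frac <- t(sapply(1:5, function(r) sapply(1:5, function(c) {
    mean(og2[(r - 1) * f + 1:f, (c - 1) * f + 1:f])
  })))
  cellv <- t(sapply(1:5, function(r) sapply(1:5, function(c) {
    blk_og <- og2[(r - 1) * f + 1:f, (c - 1) * f + 1:f]
    blk_b <- bio2[(r - 1) * f + 1:f, (c - 1) * f + 1:f]
    mean(blk_b[blk_og])
  })))
  for (r in 1:5) for (c in 1:5) {
    cid <- (r - 1) * 5 + c
    dist <- sqrt(outer((1:5 - r)^2, (1:5 - c)^2, "+")) * 0.25
    sel <- dist <= 1 + 1e-12 & og_frac > 0.9
    expected <- if (any(sel)) median(cellv[sel]) else NA
    got <- refs2[cell_id == cid, ref_og]
    if (is.na(expected)) {
      # falls back to the widened radius
      sel2 <- dist <= 2 + 1e-12 & og_frac > 0.9
      expected <- if (any(sel2)) median(cellv[sel2]) else NA
    }
    expect_equal(got, expected, tolerance = 1e-12)
  }

  # simple median sanity: window of {100, 120, 140} -> 120
  expect_identical(median(c(100, 120, 140)), 120)
})

test_that("residual attribution follows the sign convention and fills by median", {
  # single reference cell: delta_lvod = -2.0, modelled = -1.5 -> residual -0.5
  fr <- data.table::data.table(
    cell_id = 1:4, year = 2015L,
    f_oldgrowth = c(0.95, 0.5, 0.95, 0.2),
    f_degraded = 0, f_edge = 0, f_secondary = 0,
    f_nonforest = 1 - c(0.95, 0.5, 0.95, 0.2), area_ha = 100)
  dl <- data.table::data.table(cell_id = 1:4, year = 2015L,
                               delta_mgc = c(-2, -3, -1, -4))
  md <- data.table::data.table(cell_id = 1:4, year = 2015L,
                               delta_mgc = c(-1.5, -2, -0.5, -3))
  dref <- lvod_oldgrowth_change_reference(dl, md, fr, ncx = 2L, ncy = 2L)
  expect_equal(dref[cell_id == 1L, dref_og], -0.5 / 95)
  expect_equal(dref[cell_id == 3L, dref_og], -0.5 / 95)
  # non-reference cells take the median of the reference residual densities
  expect_equal(dref[cell_id == 2L, dref_og],
               median(c(-0.5 / 95, -0.5 / 95)))
  expect_true(all(dref$flagged == FALSE))

  # all processes zero: residual equals the satellite change exactly
  md0 <- data.table::copy(md)[, delta_mgc := 0]
  dref0 <- lvod_oldgrowth_change_reference(dl, md0, fr, ncx = 2L, ncy = 2L)
  expect_equal(dref0[cell_id == 1L, dref_og], -2 / 95)
})

test_that("deforestation flux books prior-state densities", {
  refs <- data.table::data.table(cell_id = 1L, ref_og = 126.4,
                                 flagged = FALSE)
  g <- growth_curve(); e <- edge_loss_curve(); lf <- 0.353
  # 10 ha of old-growth cleared at 126.4 -> -1264 Mg C
  d1 <- data.table::data.table(year = 2015L, cell_id = 1L,
                               prior_state = "oldgrowth", age = 0L,
                               wasdeg = FALSE, area_ha = 10)
  expect_equal(deforestation_flux(d1, refs, g, e, lf)$delta_mgc, -1264)
  # 10 ha of age-5 secondary -> -10 x growth(5)
  d2 <- data.table::copy(d1)[, `:=`(prior_state = "secondary", age = 5L)]
  expect_equal(deforestation_flux(d2, refs, g, e, lf)$delta_mgc,
               -10 * growth_agc(g, 5))
  # edge with age uses the edge-adjusted reference
  d3 <- data.table::copy(d1)[, `:=`(prior_state = "edge", age = 3L)]
  expect_equal(deforestation_flux(d3, refs, g, e, lf)$delta_mgc,
               -10 * 126.4 * (1 - edge_loss(e, 3)))
  # zero deforested area -> zero flux rows
  expect_identical(nrow(deforestation_flux(d1[0], refs, g, e, lf)), 0L)
})

test_that("non-edge degradation flux applies the loss factor", {
  refs <- data.table::data.table(cell_id = 1L, ref_og = 126.4)
  ne <- data.table::data.table(year = 2015L, cell_id = 1L, area_ha = 100)
  out <- nonedge_degradation_flux(ne, refs, 0.353)
  expect_equal(out$delta_mgc, -100 * 126.4 * 0.353, tolerance = 1e-12)
  expect_equal(out$delta_mgc, -4462.0, tolerance = 2e-4)
  expect_identical(nonedge_degradation_flux(ne, refs, 0)$delta_mgc, 0)
})

test_that("edge degradation increments telescope to the cumulative loss", {
  refs <- data.table::data.table(cell_id = 1L, ref_og = 126.4)
  e <- edge_loss_curve(L_inf = 0.36, r = 0.2)
  ages <- 1:12
  tab <- data.table::data.table(year = 2000L + ages, cell_id = 1L,
                                age = ages, wasdeg = FALSE, area_ha = 7)
  out <- edge_degradation_flux(tab, refs, e, 0.353)
  expect_true(all(out$delta_mgc <= 0))
  expect_equal(sum(out$delta_mgc), -126.4 * edge_loss(e, 12) * 7,
               tolerance = 1e-12)
  # a saturated curve gives a zero increment
  esat <- edge_loss_curve(L_inf = 0.36, r = 50)
  old <- data.table::data.table(year = 2015L, cell_id = 1L, age = 30L,
                                wasdeg = FALSE, area_ha = 7)
  expect_lt(abs(edge_degradation_flux(old, refs, esat, 0.353)$delta_mgc),
            1e-9)
  expect_error(edge_degradation_flux(
    data.table::copy(old)[, age := 0L], refs, e, 0.353), "age")
})

test_that("secondary growth books age increments and new stands", {
  g <- growth_curve()
  tab <- data.table::data.table(year = 2015L, cell_id = 1L, age = 4L,
                                area_ha = 3)
  expect_equal(secondary_growth_flux(tab, g)$delta_mgc,
               3 * (growth_agc(g, 4) - growth_agc(g, 3)))
  new1 <- data.table::copy(tab)[, age := 1L]
  expect_equal(secondary_growth_flux(new1, g)$delta_mgc,
               3 * growth_agc(g, 1))
  expect_identical(nrow(secondary_growth_flux(tab[0], g)), 0L)
})

test_that("old-growth flux multiplies the reference field by old-growth area", {
  dref <- data.table::data.table(cell_id = 1:2, year = 2015L,
                                 dref_og = c(-0.5, 0.1),
                                 is_reference = c(TRUE, FALSE),
                                 flagged = c(FALSE, TRUE))
  fr <- data.table::data.table(cell_id = 1:2, year = 2015L,
                               f_oldgrowth = c(1, 0.5), area_ha = 50000)
  expect_warning(out <- old_growth_flux(dref, fr), "excluded")
  expect_equal(out$delta_mgc, -0.5 * 50000)
  expect_identical(nrow(out), 1L)
  # zero old-growth fraction -> zero flux regardless of the reference
  fr0 <- data.table::copy(fr)[, f_oldgrowth := 0]
  dref0 <- data.table::copy(dref)[, flagged := FALSE]
  expect_identical(old_growth_flux(dref0, fr0)$delta_mgc, c(0, 0))
})

test_that("totals are additive and an empty table gives a zero series", {
  fx <- data.table::data.table(
    cell_id = 1L, year = 2015L,
    process = c("deforestation", "edge_degradation", "nonedge_degradation",
                "secondary_growth", "old_growth"),
    delta_mgc = c(-10, -5, -3, 4, -1))
  tot <- total_modeled_change(fx)
  expect_equal(tot$cell_totals$delta_mgc, -15)
  expect_equal(tot$biome_total$delta_mgc, -15)
  expect_equal(tot$biome_total$delta_tgc, -15 / 1e6)
  empty <- total_modeled_change(fx[0])
  expect_identical(nrow(empty$biome_total), 0L)
})

test_that("sign discipline holds across a full synthetic bookkeeping run", {
  sc <- generate_scene(small_cfg())
  lc <- run_landcover(sc)
  dl <- lvod_change(truth_agc_grid(sc), sc$cell_area_ha)
  fx <- compute_fluxes(lc, sc, dl)$flux
  expect_true(all(fx[process == "deforestation", delta_mgc] <= 0))
  expect_true(all(fx[process == "edge_degradation", delta_mgc] <= 0))
  expect_true(all(fx[process == "nonedge_degradation", delta_mgc] <= 0))
  expect_true(all(fx[process == "secondary_growth", delta_mgc] >= 0))
  expect_true(all(is.finite(fx$delta_mgc)))
})
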