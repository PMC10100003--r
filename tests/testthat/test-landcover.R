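test_that("deforestation detection requires a forest-to-cleared transition", {
  prev <- matrix(c(1L, 1L, 2L, 1L), 2, 2)   # forest except one pasture
  cur <- matrix(c(2L, 1L, 4L, 1L), 2, 2)    # forest->pasture, pasture->bare
  out <- detect_deforestation(prev, cur)
  expect_identical(out, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_error(detect_deforestation(prev, matrix(9L, 2, 2)), "unknown class")
})

test_that("secondary age counts consecutive forest years after clearance", {
  # one pixel: non-forest 2012, forest 2013-2016 -> age 4 in 2016
  h <- array(1L, dim = c(1, 1, 6))          # years 2011..2016
  h[1, 1, 2] <- 2L
  ages <- update_secondary_forest(h)
  expect_identical(as.integer(ages[1, 1, ]), c(0L, 0L, 1L, 2L, 3L, 4L))

  # forest in every history year: never secondary
  h2 <- array(1L, dim = c(1, 1, 6))
  expect_true(all(update_secondary_forest(h2) == 0L))

  # reset semantics: cleared in year 4, re-forested year 6 -> age restarts
  h3 <- array(c(2L, 1L, 1L, 2L, 2L, 1L), dim = c(1, 1, 6))
  expect_identical(as.integer(update_secondary_forest(h3)[1, 1, ]),
                   c(0L, 1L, 2L, 0L, 0L, 1L))
})

test_that("edge zones use an inclusive 120 m Euclidean buffer with ages", {
  # 11x11 forest with one cleared pixel in the centre; 30 m pixels
  forest <- matrix(TRUE, 11, 11)
  src <- matrix(FALSE, 11, 11)
  src[6, 6] <- TRUE
  forest[6, 6] <- FALSE
  ez <- compute_edge_zones(forest, src, matrix(0L, 11, 11),
                           pixel_edge_m = 30, buffer_m = 120)
  expect_true(ez$edge[6, 9])    # 3 pixels (90 m) away: edge
  expect_true(ez$edge[6, 10])   # 4 pixels (120 m, inclusive): edge
  expect_false(ez$edge[6, 11])  # 5 pixels (150 m): beyond the buffer
  # Euclidean metric on pixel centres: diagonal (3,3) offset is ~127 m
  expect_false(ez$edge[3, 9])
  expect_true(ez$edge[4, 9])    # (2,3) offset is ~108 m
  # ages: new edge = 1, persisting edge increments
  expect_identical(max(ez$edge_age), 1L)
  ez2 <- compute_edge_zones(forest, src, ez$edge_age,
                            pixel_edge_m = 30, buffer_m = 120)
  expect_identical(ez2$edge_age[6, 10], 2L)
})

test_that("degradation events respect edge exclusion and the ratchet", {
  forest <- matrix(TRUE, 5, 5)
  edge <- matrix(FALSE, 5, 5); edge[1, 1] <- TRUE
  sec <- matrix(FALSE, 5, 5); sec[5, 5] <- TRUE
  base <- matrix(FALSE, 5, 5); base[3, 3] <- TRUE
  ev <- matrix(FALSE, 5, 5)
  ev[2, 2] <- TRUE   # interior old-growth: counted
  ev[1, 1] <- TRUE   # edge: excluded
  ev[5, 5] <- TRUE   # secondary: excluded
  ev[3, 3] <- TRUE   # already degraded: not double-counted
  out <- extract_degradation_events(ev, forest, edge, sec, base)
  expect_identical(which(out$new_deg), which(matrix(
    seq_len(25) == 7, 5, 5)))  # only (2,2) = linear index 7
  expect_true(out$deg_baseline[3, 3])   # ratchet keeps prior members
  expect_true(out$deg_baseline[2, 2])
  expect_identical(unname(out$ignored[c("edge", "secondary",
                                        "already_degraded")]),
                   c(1L, 1L, 1L))
  # events on non-forest pixels are ignored with a counter
  nf <- matrix(TRUE, 5, 5); nf[4, 4] <- FALSE
  ev2 <- matrix(FALSE, 5, 5); ev2[4, 4] <- TRUE
  out2 <- extract_degradation_events(ev2, nf, edge & FALSE, sec & FALSE,
                                     base & FALSE)
  expect_identical(unname(out2$ignored[["non_forest"]]), 1L)
  expect_false(any(out2$new_deg))
})

test_that("old-growth excludes degraded-ever, secondary and edge forest", {
  forest <- matrix(TRUE, 3, 3)
  deg <- matrix(FALSE, 3, 3); deg[1, 1] <- TRUE
  sec <- matrix(FALSE, 3, 3); sec[2, 2] <- TRUE
  edge <- matrix(FALSE, 3, 3); edge[3, 3] <- TRUE
  og <- derive_old_growth(forest, deg, sec, edge)
  expect_identical(sum(og), 6L)
  expect_false(og[1, 1] || og[2, 2] || og[3, 3])
  expect_true(og[1, 2])
})

test_that("fractional covers partition to one and match a pixel recount", {
  sc <- generate_scene(small_cfg())
  lc <- run_landcover(sc)
  fr <- lc$fractions
  sums <- fr[, f_oldgrowth + f_degraded + f_edge + f_secondary + f_nonforest]
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(fr[, .SD, .SDcols = patterns("^f_")] >= 0))
  # independent recount of the state rasters, cell by cell
  f <- sc$fine_per_coarse
  for (t in c(1L, length(sc$years))) {
    st <- lc$states[, , t]
    for (cell in c(1L, 7L, 16L)) {
      cy <- (cell - 1L) %/% 4L; cx <- (cell - 1L) %% 4L
      blk <- st[cy * f + seq_len(f), cx * f + seq_len(f)]
      expect_identical(
        fr[cell_id == cell & year == sc$years[t], f_oldgrowth],
        sum(blk == 1L) / f^2)
    }
  }
})

test_that("the engine reconstructs the generator's states from rasters alone", {
  sc <- generate_scene(small_cfg())
  lc <- run_landcover(sc)
  expect_identical(lc$states, sc$truth$states)
  expect_identical(lc$sec_age, sc$truth$sec_age)
  expect_identical(lc$edge_age, sc$truth$edge_age)
})
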