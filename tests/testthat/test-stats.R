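brute_force_ts <- function(x, y) {
  n <- length(x)
  s <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- c(s, (y[j] - y[i]) / (x[j] - x[i]))
  }
  median(s)
}

test_that("Theil-Sen slope equals the pairwise-median oracle", {
  # exact line
  expect_equal(theil_sen(2011:2013, c(10, 12, 14))$slope, 2)
  # constant series: zero slope, not significant
  r <- theil_sen(2011:2016, rep(5, 6))
  expect_identical(r$slope, 0)
  expect_false(r$significant)
  # randomized series vs brute force
  set.seed(31)
  for (i in 1:60) {
    y <- rnorm(9)
    expect_identical(theil_sen(2011:2019, y)$slope,
                     brute_force_ts(2011:2019, y))
  }
  expect_error(theil_sen(c(2011, 2011, 2012), 1:3), "duplicate")
})

test_that("Theil-Sen resists symmetric outliers up to its breakdown point", {
  # 7 points on an exact line, 2 gross outliers (29% of 9 points): the
  # robust slope still returns the line's slope
  x <- 2011:2019
  y <- 3 + 0.7 * (x - 2011)
  y[c(3, 7)] <- y[c(3, 7)] + c(50, -50)
  expect_equal(theil_sen(x, y)$slope, 0.7, tolerance = 1e-12)
})

test_that("Mann-Kendall significance agrees with the Kendall-tau oracle", {
  set.seed(32)
  for (i in 1:25) {
    y <- cumsum(rnorm(10)) + seq(0, i %% 4, length.out = 10)
    mine <- theil_sen(2011:2020, y)
    oracle <- suppressWarnings(
      cor.test(2011:2020, y, method = "kendall", exact = FALSE,
               continuity = TRUE))
    expect_equal(mine$p_value, unname(oracle$p.value), tolerance = 1e-10)
  }
})

test_that("trend-field comparison restricts to mixed cells", {
  set.seed(33)
  m <- rnorm(30)
  og <- runif(30, 0, 0.89)
  # identical fields
  cmp <- compare_trend_fields(m, m, og)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$mad, 0)
  expect_equal(cmp$agreement_fraction, 1)
  # antisymmetric fields
  cmp2 <- compare_trend_fields(m, -m, og)
  expect_equal(cmp2$pearson_r, -1)
  expect_equal(cmp2$agreement_fraction, 0)
  # >90% old-growth cells are excluded from the statistics
  og2 <- og; og2[1:10] <- 0.95
  cmp3 <- compare_trend_fields(m, m, og2)
  expect_identical(cmp3$n_cells, 20L)
  expect_error(compare_trend_fields(m[1:2], m[1:2], og[1:2]), "3 eligible")
})

test_that("uncertainty propagation: root sum of squares and plain sum", {
  expect_identical(propagate_uncertainty(c(3, 4)), 5)
  expect_identical(propagate_uncertainty(7), 7)
  expect_identical(propagate_uncertainty(c(3, 4), method = "sum"), 7)
  expect_error(propagate_uncertainty(c(-1, 2)), ">= 0")
})

test_that("regional aggregation is linear and partitions the biome", {
  fx <- data.table::data.table(
    cell_id = rep(1:4, each = 2), year = 2015L,
    process = rep(c("deforestation", "secondary_growth"), 4),
    delta_mgc = rep(c(-10, 2), 4))
  one <- data.table::data.table(cell_id = 1:4, region = "all", weight = 1)
  agg <- aggregate_region(fx, one)
  expect_equal(agg$process_totals[process == "deforestation", delta_mgc],
               -40)
  expect_equal(agg$summary$net_mgc, -32)
  # two half-weighted regions each receive half of every cell's flux
  two <- data.table::rbindlist(list(
    data.table::data.table(cell_id = 1:4, region = "A", weight = 0.5),
    data.table::data.table(cell_id = 1:4, region = "B", weight = 0.5)))
  agg2 <- aggregate_region(fx, two)
  expect_equal(agg2$summary$net_mgc, c(-16, -16))
  expect_error(aggregate_region(fx, data.table::data.table(
    cell_id = 1L, region = "A", weight = 1.2)), "\\[0, 1\\]")

  # degradation share matches a direct recomputation from ground truth
  sc <- generate_scene(small_cfg())
  tru <- sc$truth$flux
  wts <- data.table::data.table(cell_id = 1:16,
                                region = rep(c("west", "east"), each = 8),
                                weight = 1)
  agg3 <- aggregate_region(tru, wts)
  for (rg in c("west", "east")) {
    cells <- wts[region == rg, cell_id]
    loss <- tru[cell_id %in% cells &
                  process %in% c("deforestation", "edge_degradation",
                                 "nonedge_degradation"), sum(delta_mgc)]
    deg <- tru[cell_id %in% cells &
                 process %in% c("edge_degradation", "nonedge_degradation"),
               sum(delta_mgc)]
    expect_equal(agg3$summary[region == rg, degradation_share], deg / loss)
  }
})

test_that("region totals are invariant under partition refinement", {
  sc <- generate_scene(small_cfg())
  tru <- sc$truth$flux
  whole <- aggregate_region(tru, data.table::data.table(
    cell_id = 1:16, region = "biome", weight = 1))
  split <- aggregate_region(tru, data.table::rbindlist(list(
    data.table::data.table(cell_id = 1:16, region = "half1", weight = 0.5),
    data.table::data.table(cell_id = 1:16, region = "half2", weight = 0.5))))
  expect_equal(sum(split$summary$net_mgc), whole$summary$net_mgc)
})
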