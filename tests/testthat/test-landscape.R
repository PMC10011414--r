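test_that("simulated climate satisfies physical invariants on every cell", {
  st <- simulate_climate(grid_spec(100, 100), climate_params(), seed = 42)
  expect_setequal(names(st$layers),
                  c("BIO1", "BIO3", "BIO5", "BIO6", "BIO12", "BIO18"))
  for (l in st$layers) expect_true(all(is.finite(l)))
  expect_true(all(st$layers$BIO6 <= st$layers$BIO1))
  expect_true(all(st$layers$BIO1 <= st$layers$BIO5))
  expect_true(all(st$layers$BIO12 >= 0))
  expect_true(all(st$layers$BIO18 >= 0))
  expect_true(all(st$layers$BIO18 <= st$layers$BIO12))
})

test_that("climate generation is deterministic under the seed", {
  a <- simulate_climate(grid_spec(30, 30), climate_params(), seed = 7)
  b <- simulate_climate(grid_spec(30, 30), climate_params(), seed = 7)
  expect_identical(a, b)
  c <- simulate_climate(grid_spec(30, 30), climate_params(), seed = 8)
  expect_false(identical(a$layers$BIO1, c$layers$BIO1))
})

test_that("long correlation length yields high Moran's I (brute-force oracle)", {
  st <- simulate_climate(grid_spec(20, 20), climate_params(range_km = 8),
                         seed = 3)
  expect_gt(morans_i_brute(st$layers$BIO1), 0.3)
})

test_that("non-positive autocorrelation length is a parameter error", {
  expect_error(simulate_climate(grid_spec(10, 10),
                                climate_params(range_km = 0), seed = 1),
               "positive")
})

test_that("future projection applies additive and multiplicative shifts exactly", {
  st <- toy_stack(15, seed = 2)
  fut <- project_future_climate(st, list(BIO1 = c(add = 2)), noise_sd = 0)
  expect_equal(fut$layers$BIO1, st$layers$BIO1 + 2)
  fut2 <- project_future_climate(st, list(BIO12 = c(mul = 0.8)), noise_sd = 0)
  expect_equal(fut2$layers$BIO12, 0.8 * st$layers$BIO12)
  # invariants survive the shift via repair of unshifted variables
  expect_true(all(fut$layers$BIO6 <= fut$layers$BIO1))
  expect_true(all(fut$layers$BIO1 <= fut$layers$BIO5))
  expect_true(all(fut2$layers$BIO18 <= fut2$layers$BIO12))
})

test_that("unknown variable in shift errors", {
  st <- toy_stack(10)
  expect_error(project_future_climate(st, list(BIO99 = c(add = 1))), "BIO99")
})

test_that("PA damping shrinks climate deltas inside PAs", {
  g <- grid_spec(30, 30)
  st <- simulate_climate(g, climate_params(), seed = 5)
  pa <- simulate_pa_network(g, 0.2, 4, class_mix = c(II = 1), seed = 9)
  fut <- project_future_climate(st, list(BIO1 = c(add = 3)), noise_sd = 0.5,
                                pa_stability = list(pa = pa, damping = 0.5),
                                seed = 11)
  d <- abs(fut$layers$BIO1 - st$layers$BIO1)
  inside <- pa_subset_mask(pa, "all")
  expect_lt(mean(d[inside]), mean(d[!inside]))
})

test_that("true suitability is 1 at the optimum and exp(-1/2) one sd away", {
  g <- grid_spec(1, 3)
  st <- climate_stack(g, "x", list(BIO1 = matrix(c(10, 12, 14), 1)))
  vsp <- virtual_species("v", list(BIO1 = c(opt = 10, sd = 2)))
  s <- true_suitability(vsp, st)
  expect_equal(s[1, 1], 1.0)
  expect_equal(s[1, 2], exp(-1 / 2))
  expect_error(true_suitability(
    virtual_species("v", list(BIO5 = c(opt = 0, sd = 1))), st), "BIO5")
})

test_that("suitability is non-increasing away from the optimum along one axis", {
  g <- grid_spec(1, 50)
  x <- matrix(seq(0, 30, length.out = 50), 1)
  st <- climate_stack(g, "x", list(BIO1 = x, BIO12 = matrix(500, 1, 50)))
  vsp <- virtual_species("v", list(BIO1 = c(opt = 15, sd = 4),
                                   BIO12 = c(opt = 500, sd = 100)))
  s <- as.vector(true_suitability(vsp, st))
  dist_from_opt <- abs(x - 15)
  expect_true(all(diff(s[order(dist_from_opt)]) <= 1e-12))
  # nested true ranges across thresholds
  r_lo <- true_range(vsp, st, threshold = 0.2)
  r_hi <- true_range(vsp, st, threshold = 0.6)
  expect_true(all(r_lo[r_hi]))
})

test_that("occurrence sampling respects the true range and effort bias", {
  g <- grid_spec(10, 10)
  suit <- matrix(0.5, 10, 10)
  truth <- matrix(FALSE, 10, 10); truth[3:8, 2:9] <- TRUE
  occ <- sample_occurrences("sp", suit, truth, 500, g, seed = 1)
  rc <- cells_from_xy(g, occ$x_km, occ$y_km)
  expect_true(all(truth[cbind(rc$row, rc$col)]))

  # two equal blocks, uniform suitability: counts within 3 sigma of 50/50
  truth2 <- matrix(FALSE, 10, 10); truth2[, c(1:2, 9:10)] <- TRUE
  occ2 <- sample_occurrences("sp", matrix(1, 10, 10), truth2, 10000, g,
                             seed = 2)
  left <- mean(occ2$x_km < 5)
  expect_lt(abs(left - 0.5), 3 * sqrt(0.25 / 10000))

  # 9:1 effort on the left half concentrates sampling there
  eff <- matrix(rep(c(9, 1), each = 5), 10, 10, byrow = TRUE)
  occ3 <- sample_occurrences("sp", matrix(1, 10, 10),
                             matrix(TRUE, 10, 10), 1000, g, bias = eff,
                             seed = 3)
  expect_gte(mean(occ3$x_km < 5), 0.8)

  expect_error(sample_occurrences("sp", suit, matrix(FALSE, 10, 10), 5, g,
                                  seed = 1), "unsampleable")
})

test_that("PA network hits the target fraction with contiguous patches", {
  g <- grid_spec(200, 200)
  pa <- simulate_pa_network(g, 0.10, 20, class_mix = c(II = 0.5, V = 0.5),
                            seed = 4)
  frac <- mean(pa$class_raster > 0)
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)

  pa2 <- simulate_pa_network(grid_spec(30, 30), 0.2, 3,
                             class_mix = c(II = 1), seed = 5)
  expect_identical(pa_subset_mask(pa2, "strict"), pa_subset_mask(pa2, "all"))
  expect_error(simulate_pa_network(grid_spec(5, 5), 0.1, 100,
                                   class_mix = c(II = 1), seed = 1),
               "infeasible")
})

test_that("stable-climate placement puts PAs where change is smallest", {
  g <- grid_spec(40, 40)
  cur <- simulate_climate(g, climate_params(), seed = 6)
  fut <- project_future_climate(cur, list(BIO1 = c(add = 2)), noise_sd = 1,
                                seed = 7)
  pa <- simulate_pa_network(g, 0.15, 6, class_mix = c(II = 1),
                            placement = "stable", climate_current = cur,
                            climate_future = fut, seed = 8)
  d <- abs(fut$layers$BIO1 - cur$layers$BIO1)
  inside <- pa_subset_mask(pa, "all")
  expect_lt(mean(d[inside]), mean(d[!inside]))
})

test_that("partitions label every cell with connected regions", {
  g <- grid_spec(25, 25)
  p <- simulate_partition(g, k_regions = 5, k_countries = 1, seed = 10)
  expect_setequal(unique(as.vector(p$region_id)), 1:5)
  expect_true(all(p$country_id == 1))
  # connectivity via flood fill from one seed per region
  for (k in 1:5) {
    cells <- which(p$region_id == k)
    member <- matrix(FALSE, 25, 25); member[cells] <- TRUE
    reached <- matrix(FALSE, 25, 25); reached[cells[1]] <- TRUE
    repeat {
      grow <- (rbind(reached[-1, ], FALSE) | rbind(FALSE, reached[-25, ]) |
                 cbind(reached[, -1], FALSE) | cbind(FALSE, reached[, -25])) &
        member & !reached
      if (!any(grow)) break
      reached[grow] <- TRUE
    }
    expect_true(all(reached[member]))
  }
  expect_identical(p, simulate_partition(g, 5, 1, seed = 10))
  expect_error(simulate_partition(grid_spec(3, 3), 100, 1, seed = 1),
               "exceeds")
})

test_that("ascii raster round-trips values, grid and NA cells", {
  g <- grid_spec(8, 11, cell_size_km = 2, origin = c(3, 40))
  m <- matrix(rnorm(88), 8, 11)
  m[c(4, 17)] <- NA
  path <- tempfile(fileext = ".asc")
  write_ascii_raster(m, g, path)
  back <- read_ascii_raster(path)
  expect_equal(back$mat, m, tolerance = 1e-6)
  expect_equal(back$grid$n_rows, 8L)
  expect_equal(back$grid$cell_size_km, 2)
  expect_equal(back$grid$origin, c(3, 40))
})
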