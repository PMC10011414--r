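test_that("coverage fractions follow the strict/all subset logic", {
  g <- grid_spec(5, 5)
  r <- matrix(FALSE, 5, 5); r[1:10] <- TRUE          # 10-cell range
  rng <- range_from(r)
  # 3 cells class II (strict and all), 2 cells class V (all only)
  cls <- matrix(0L, 5, 5); cls[1:3] <- 3L; cls[4:5] <- 6L
  pa <- pa_mask(g, cls)
  expect_equal(coverage_fraction(rng, pa, "strict"), 0.3)
  expect_equal(coverage_fraction(rng, pa, "all"), 0.5)

  pa_all <- pa_with_cells(g, which(r), "Ia")
  expect_equal(coverage_fraction(rng, pa_all, "strict"), 1.0)

  # inside + outside = 1 (here via the complement of the subset mask)
  inside <- coverage_fraction(rng, pa, "all")
  outside <- sum(r & !pa_subset_mask(pa, "all")) / sum(r)
  expect_equal(inside + outside, 1, tolerance = 1e-12)

  empty <- range_from(matrix(FALSE, 5, 5))
  expect_error(coverage_fraction(empty, pa), "extinct")
})

test_that("percent of species protected excludes extinct species", {
  g <- grid_spec(4, 4)
  pa <- pa_with_cells(g, 1:4, "II")
  mk <- function(cells, extinct = FALSE) {
    m <- matrix(FALSE, 4, 4); m[cells] <- TRUE
    br <- range_from(m); br$extinct <- extinct; br
  }
  # 4 species, 1 with zero PA overlap -> 75%
  ranges <- list(mk(1:2), mk(3:6), mk(c(2, 9)), mk(13:16))
  expect_equal(pct_species_protected(ranges, pa, "all"), 75.0)
  expect_equal(pct_species_protected(ranges[1:3], pa, "all"), 100.0)
  # 5 species: 1 extinct, 1 of remaining 4 unprotected -> 75%
  ranges5 <- c(ranges, list(mk(integer(0), extinct = TRUE)))
  ranges5[[5]]$extinct <- TRUE
  expect_equal(pct_species_protected(ranges5, pa, "all"), 75.0)
})

test_that("benchmark proportions use a strict inequality", {
  cov <- c(0.20, 0.10, 0.50, 0.00)
  expect_equal(benchmark_proportion(cov, 0.15), 50.0)
  expect_equal(benchmark_proportion(cov, 0.30), 25.0)
  expect_equal(benchmark_proportion(c(0.15, 0.16), 0.15), 50.0) # 0.15 not counted
  expect_true(is.na(benchmark_proportion(numeric(0), 0.15)))
})

test_that("rarity-weighted richness: inverse-range scores and conservation", {
  g <- grid_spec(5, 5)
  m1 <- matrix(FALSE, 5, 5); m1[1:10] <- TRUE       # range 10, overlaps PA
  m2 <- matrix(FALSE, 5, 5); m2[21:24] <- TRUE      # range 4, no overlap
  pa <- pa_with_cells(g, 1:2, "II")
  ranges <- list(range_from(m1, "a"), range_from(m2, "b"))
  expect_equal(rarity_weighted_richness(ranges, pa, "strict"), 0.1)
  # cell_sum over ALL cells = number of species
  cs <- rarity_weighted_richness(ranges, pa, "strict", mode = "cell_sum")
  expect_equal(sum(cs$raster), 2, tolerance = 1e-12)
  expect_equal(cs$pa_total, 2 / 10, tolerance = 1e-12)
})

test_that("range loss inside/outside PAs handles all strata", {
  g <- grid_spec(5, 5)
  pa <- pa_with_cells(g, 1:10, "II")
  cur <- matrix(FALSE, 5, 5); cur[1:20] <- TRUE     # 10 in, 10 out
  fut <- matrix(FALSE, 5, 5); fut[c(1:5, 11:12)] <- TRUE  # 5 in, 2 out
  res <- range_change_inside_outside(range_from(cur), range_from(fut), pa)
  expect_equal(res[["loss_inside"]], 50.0)
  expect_equal(res[["loss_outside"]], 80.0)

  same <- range_change_inside_outside(range_from(cur), range_from(cur), pa)
  expect_equal(unname(same), c(0, 0))

  # species entirely outside PAs: inside loss undefined
  out_only <- matrix(FALSE, 5, 5); out_only[11:14] <- TRUE
  res2 <- range_change_inside_outside(range_from(out_only),
                                      range_from(out_only), pa)
  expect_true(is.na(res2[["loss_inside"]]))
  expect_equal(res2[["loss_outside"]], 0)
})

test_that("species metrics table and group summaries are consistent", {
  g <- grid_spec(6, 6)
  pa <- pa_with_cells(g, 1:6, "II")
  mk <- function(n) { m <- matrix(FALSE, 6, 6); m[seq_len(n)] <- TRUE; m }
  current <- list(s1 = range_from(mk(4), "s1"), s2 = range_from(mk(8), "s2"),
                  s3 = range_from(mk(12), "s3"), s4 = range_from(mk(16), "s4"))
  future <- list(s1 = range_from(mk(2), "s1", "future"),
                 s2 = range_from(mk(4), "s2", "future"),
                 s3 = range_from(mk(6), "s3", "future"),
                 s4 = range_from(mk(8), "s4", "future"))
  met <- species_metrics_table(current, future, pa)
  # small_range: areas 4,8,12,16 -> below median 10
  expect_equal(met$small_range, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(met$coverage_strict >= 0 & met$coverage_strict <= 1))
  expect_true(all(met$loss_inside >= 0 & met$loss_inside <= 100, na.rm = TRUE))

  sum_all <- summarize_group(met, "none")
  expect_equal(sum_all$n, 4)
  one <- summarize_group(met[1, ], "none")
  expect_equal(one$median_coverage_strict, met$coverage_strict[1])
  expect_equal(one$q25_coverage, one$q75_coverage)

  bysize <- summarize_group(met, "small_range")
  expect_equal(bysize$n, c(2L, 2L))
})
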