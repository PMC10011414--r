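test_that("range-buffer filter keeps points within 400 km and drops beyond", {
  rng <- range_polygon("sp", list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
  occ <- occurrence_set("sp", x_km = c(5, 410.5, 409.5), y_km = c(5, 5, 5))
  out <- filter_by_range_buffer(occ, rng, buffer_km = 400)
  expect_true(out$kept[1])                        # inside the polygon
  expect_false(out$kept[2])                       # 400.5 km out
  expect_equal(out$reason[2], "outside_range_buffer")
  expect_true(out$kept[3])                        # 399.5 km out: kept
})

test_that("missing range polygon keeps all records with a warning", {
  occ <- occurrence_set("sp", x_km = rnorm(7, 5), y_km = rnorm(7, 5))
  expect_warning(out <- filter_by_range_buffer(occ, NULL), "no range polygon")
  expect_equal(sum(out$kept), 7)
})

test_that("blacklist cleaning and deduplication flag the right records", {
  occ <- occurrence_set("sp", x_km = c(0, 0, 5, 7), y_km = c(0, 0, 5, 5))
  out <- clean_coordinates(occ, blacklist = cbind(0, 0), radius_km = 1)
  expect_false(out$kept[1])
  expect_equal(out$reason[1], "blacklisted")
  expect_false(out$kept[2])                       # same point: blacklisted too
  expect_true(all(out$kept[3:4]))

  occ2 <- occurrence_set("sp", x_km = c(5, 5, 6), y_km = c(2, 2, 2))
  out2 <- clean_coordinates(occ2, dedup = TRUE)
  expect_equal(sum(out2$kept), 2)
  expect_equal(out2$reason[2], "duplicate")

  # 2 km away with radius 1: kept
  occ3 <- occurrence_set("sp", x_km = 2, y_km = 0)
  out3 <- clean_coordinates(occ3, blacklist = cbind(0, 0), radius_km = 1)
  expect_true(out3$kept[1])
})

test_that("thinning keeps exactly the first record per occupied cell", {
  g <- grid_spec(10, 10)
  # three records in one cell, two in another
  occ <- occurrence_set("sp", x_km = c(2.1, 2.5, 2.9, 7.2, 7.8),
                        y_km = c(3.1, 3.5, 3.9, 5.5, 5.5))
  out <- thin_occurrences(occ, g)
  expect_equal(sum(out$kept), 2)
  expect_true(out$kept[1])                        # first in input order
  expect_equal(out$reason[c(2, 3, 5)], rep("thinned", 3))

  # kept count equals the brute-force occupied-cell set size
  set.seed(1)
  occ2 <- occurrence_set("sp", x_km = runif(300, 0, 10),
                         y_km = runif(300, 0, 10))
  out2 <- thin_occurrences(occ2, g)
  cells <- unique(paste(floor(occ2$x_km), floor(10 - occ2$y_km)))
  expect_equal(sum(out2$kept), length(cells))

  # idempotence
  out3 <- thin_occurrences(out2, g)
  expect_identical(out3$kept, out2$kept)
})

test_that("records outside the grid are flagged with a warning", {
  g <- grid_spec(5, 5)
  occ <- occurrence_set("sp", x_km = c(1, 99), y_km = c(1, 1))
  expect_warning(out <- thin_occurrences(occ, g), "outside the grid")
  expect_false(out$kept[2])
})

test_that("record conservation: kept + removed = input, one reason each", {
  g <- grid_spec(10, 10)
  set.seed(2)
  occ <- occurrence_set("sp", x_km = runif(100, -2, 12),
                        y_km = runif(100, -2, 12))
  rng <- range_polygon("sp", list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))))
  out <- filter_by_range_buffer(occ, rng, buffer_km = 1)
  out <- clean_coordinates(out, blacklist = cbind(5, 5), radius_km = 1)
  out <- suppressWarnings(thin_occurrences(out, g))
  expect_equal(sum(out$kept) + sum(!out$kept), 100)
  expect_true(all(is.na(out$reason[out$kept])))
  expect_true(all(!is.na(out$reason[!out$kept])))
})

test_that("species with >= 5 thinned records are modelable, fewer are not", {
  g <- grid_spec(10, 10)
  mk <- function(id, n) {
    thin_occurrences(occurrence_set(id, x_km = seq_len(n) - 0.5,
                                    y_km = rep(0.5, n)), g)
  }
  sel <- select_modelable_species(list(mk("a", 5), mk("b", 4), mk("c", 9)))
  expect_equal(sel$modelable, c(TRUE, FALSE, TRUE))
  expect_equal(sel$n_kept, c(5L, 4L, 9L))
  empty <- select_modelable_species(list())
  expect_equal(nrow(empty), 0)
})

test_that("cleaning report tracks counts through the pinned filter order", {
  g <- grid_spec(10, 10)
  occ <- occurrence_set("sp", x_km = c(1.2, 1.4, 3.5, 3.5, 5.5),
                        y_km = c(1.2, 1.4, 2.5, 2.5, 3.5))
  occ <- clean_coordinates(occ, dedup = TRUE)      # drops one exact duplicate
  occ <- thin_occurrences(occ, g)                  # merges the 1-km pair
  rep <- cleaning_report(list(occ))
  expect_equal(rep$n_input, 5)
  expect_equal(rep$n_after_clean, 4)
  expect_equal(rep$n_after_thin, 3)
  expect_false(rep$modelable)
})
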