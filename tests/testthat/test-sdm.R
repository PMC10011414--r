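test_that("calibration area is the discrete buffer disk (brute-force oracle)", {
  g <- grid_spec(40, 40)
  presence <- matrix(FALSE, 40, 40)
  presence[20, 20] <- TRUE
  ca <- build_calibration_area(presence, g, buffer_km = 10)
  # oracle: scan all cell centres against the presence centre
  ctr <- cell_centres(g, 20, 20)
  want <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (cc in 1:40) {
    xy <- cell_centres(g, r, cc)
    want[r, cc] <- sum((xy - ctr)^2) <= 100
  }
  expect_identical(ca$mask, want)
  expect_true(ca$mask[20, 20])
  expect_error(build_calibration_area(matrix(FALSE, 40, 40), g), "empty")
})

test_that("unoccupied regions are excluded even within the buffer", {
  g <- grid_spec(10, 20)
  part <- structure(list(
    grid = g,
    region_id = matrix(rep(c(1L, 2L), each = 100), 10, 20),
    country_id = matrix(1L, 10, 20)), class = "partition_rasters")
  presence <- matrix(FALSE, 10, 20)
  presence[5, 9] <- TRUE                    # region 1, near the border
  ca <- build_calibration_area(presence, g, part, buffer_km = 500)
  expect_true(all(!ca$mask[part$region_id == 2]))
  expect_true(all(ca$mask[part$region_id == 1]))
})

test_that("pseudo-absences are uniform draws from calibration minus presences", {
  g <- grid_spec(5, 5)
  ca <- structure(list(grid = g, mask = matrix(TRUE, 5, 5)),
                  class = "calibration_area")
  presence <- matrix(FALSE, 5, 5); presence[1:21] <- TRUE
  pa <- sample_pseudo_absences(ca, presence, 3, seed = 1)
  expect_true(all(!presence[pa]))
  # n_pa = available count gives exactly the complement
  expect_warning(all4 <- sample_pseudo_absences(ca, presence, 10, seed = 1),
                 "available")
  expect_setequal(all4, which(!presence))
  # frequency: 1 draw from 4 candidates, each share ~ 0.25
  draws <- vapply(1:10000, function(s)
    sample_pseudo_absences(ca, presence, 1, seed = s), 0L)
  shares <- table(draws) / 10000
  expect_true(all(abs(shares - 0.25) <= 0.02))
})

test_that("train/test replicates are stratified 70/30 partitions", {
  y <- c(rep(1, 4), rep(0, 6))
  reps <- partition_train_test(y, 0.7, 5, seed = 3)
  for (r in reps) {
    expect_length(r$train, 7)
    expect_length(r$test, 3)
    expect_setequal(c(r$train, r$test), 1:10)
    expect_length(intersect(r$train, r$test), 0)
    expect_true(all(c(0, 1) %in% y[r$train]))
    expect_true(all(c(0, 1) %in% y[r$test]))
  }
  # replicates differ from each other (n = 100)
  y2 <- rep(c(0, 1), 50)
  reps2 <- partition_train_test(y2, 0.7, 5, seed = 4)
  keys <- vapply(reps2, function(r) paste(r$train, collapse = ","), "")
  expect_equal(length(unique(keys)), 5)
  expect_error(partition_train_test(c(1, 1, 1, 0), 0.7, 2, seed = 1),
               "at least 2")
})

test_that("all base learners separate two Gaussian clouds (AUC >= 0.95)", {
  toy <- separable_toy(n = 200, d = 2, seed = 42)
  fits <- fit_base_learners(toy$x, toy$y, seed = 7)
  for (alg in names(fits)) {
    sc <- predict(fits[[alg]], toy$x)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gte(evaluate_auc(sc, toy$y), 0.95)
  }
})

test_that("learner fitting is deterministic and tolerates constant columns", {
  toy <- separable_toy(n = 120, d = 3, seed = 5)
  probe <- toy$x[c(1, 60, 120), , drop = FALSE]
  f1 <- fit_base_learners(toy$x, toy$y, seed = 99)
  f2 <- fit_base_learners(toy$x, toy$y, seed = 99)
  for (alg in names(f1)) {
    expect_identical(predict(f1[[alg]], probe), predict(f2[[alg]], probe))
  }
  xconst <- cbind(toy$x, flat = 1)
  expect_message(f3 <- fit_base_learners(xconst, toy$y, seed = 1), "constant")
  for (alg in names(f3)) {
    expect_true(all(is.finite(predict(f3[[alg]], xconst))))
  }
  expect_error(fit_base_learners(toy$x, rep(1, 120)), "single-class")
})

test_that("TSS-weighted ensemble retains, weights and averages correctly", {
  preds <- list(rep(0.2, 4), rep(0.8, 4))
  # 0.6 run excluded at retention 0.7
  out <- ensemble_predict(preds, tss = c(0.6, 0.8), retention_min = 0.7)
  expect_equal(out, rep(0.8, 4))
  # weighted average: (0.9*0.2 + 0.7*0.8)/1.6
  out2 <- ensemble_predict(preds, tss = c(0.9, 0.7), retention_min = 0.7)
  expect_equal(out2, rep((0.9 * 0.2 + 0.7 * 0.8) / 1.6, 4))
  # convexity: agreement passes through
  out3 <- ensemble_predict(list(rep(0.4, 4), rep(0.4, 4)), c(0.8, 0.9), 0.7)
  expect_equal(out3, rep(0.4, 4))
  expect_warning(none <- ensemble_predict(preds, c(0.1, 0.2), 0.7),
                 "unmodelable")
  expect_null(none)
  # monotonicity: lowering retention_min never removes retained runs
  lo <- ensemble_predict(preds, c(0.75, 0.9), retention_min = 0.5)
  expect_false(is.null(lo))
})

test_that("binarization uses >= and matches a raster-scan count", {
  s <- matrix(runif(100, 0, 1), 10, 10)
  s[1, 1] <- 0.5
  br <- binarize(s, 0.5)
  expect_true(br$raster[1, 1])                    # boundary cell is presence
  expect_equal(sum(br$raster), sum(!is.na(s) & s >= 0.5))
  s2 <- matrix(0.1, 3, 3)
  expect_equal(sum(binarize(s2, 0.9)$raster), 0)
})

test_that("no-dispersal projection never gains cells and flags extinction", {
  cur <- binary_range("sp", "current", matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  fut_suit <- matrix(c(0.9, 0.1, 0.9, 0.1), 2)    # cell 3 newly suitable
  fut <- project_future(cur, fut_suit, 0.5)
  expect_true(fut$raster[1, 1])                   # suitable in both
  expect_false(fut$raster[1, 2])                  # newly suitable: not gained
  expect_false(fut$extinct)
  gone <- project_future(cur, matrix(0, 2, 2), 0.5)
  expect_true(gone$extinct)
  expect_error(project_future(cur, matrix(0, 3, 3), 0.5), "mismatch")
})

test_that("ensemble_sdm recovers a clear Gaussian niche end to end", {
  g <- grid_spec(60, 60)
  climate <- simulate_climate(g, climate_params(), seed = 21)
  vsp <- virtual_species("vtest", list(
    BIO1 = c(opt = median(climate$layers$BIO1), sd = 0.35 * sd(climate$layers$BIO1)),
    BIO12 = c(opt = median(climate$layers$BIO12), sd = 0.35 * sd(climate$layers$BIO12))))
  suit <- true_suitability(vsp, climate)
  truth <- true_range(vsp, climate)
  occ <- sample_occurrences("vtest", suit, truth, 400, g, seed = 22)
  occ <- thin_occurrences(occ, g)
  fit <- ensemble_sdm(occ, climate, n_vif_cells = 2000, n_pa = 500,
                      seed = 23)
  expect_s3_class(fit, "esdm")
  expect_equal(fit$status, "ok")
  expect_true(all(fit$runs$tss >= -1 & fit$runs$tss <= 1))
  expect_true(all(fit$runs$auc >= 0 & fit$runs$auc <= 1))
  expect_gte(jaccard(fit$range$raster, truth), 0.5)
  # future ranges are contained in current
  fut_clim <- project_future_climate(climate, list(BIO1 = c(add = 2)))
  fr <- project_range(fit, fut_clim)
  expect_true(all(fit$range$raster[fr$raster]))
  # methods run
  expect_output(print(fit), "Ensemble SDM")
  expect_output(print(summary(fit)), "threshold")
})
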