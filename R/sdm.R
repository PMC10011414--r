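#' @title Per-species ensemble species distribution modelling
#' @description Fits an ensemble SDM for one species: calibration area
#'   (occupied regions + 500 km buffer), random pseudo-absences, stratified
#'   70/30 train/test splits repeated five times, five base learners (GLM,
#'   boosted trees, MaxEnt-style regularized logistic regression, random
#'   forest, SVM), TSS/AUC evaluation per run, retention of runs with
#'   TSS >= 0.7, TSS-weighted model averaging, maxTSS binarization, and
#'   no-dispersal projection to future climates.
#' @name ensemble_sdm_module
NULL

derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1048573
  as.integer((as.numeric(master) %% 1048573 * 1048583 + h) %% 2147483647L)
}

env_at <- function(climate, idx, vars = names(climate$layers)) {
  out <- matrix(NA_real_, length(idx), length(vars),
                dimnames = list(NULL, vars))
  for (v in vars) out[, v] <- climate$layers[[v]][idx]
  out
}

#' Build a species' calibration area
#'
#' The calibration area is the set of cells lying in a zoogeographic region
#' occupied by at least one presence AND whose centre is within `buffer_km`
#' of some presence-cell centre. With `partition = NULL` the whole grid is a
#' single region.
#'
#' @param presence Logical matrix of presence cells on `grid`.
#' @param grid A [grid_spec()].
#' @param partition Optional `partition_rasters` providing region ids.
#' @param buffer_km Buffer radius in km (default 500).
#' @return A `calibration_area`: list with `grid` and logical `mask`.
#' @export
build_calibration_area <- function(presence, grid, partition = NULL,
                                   buffer_km = 500) {
  pidx <- which(presence)
  if (!length(pidx)) stop("empty presence set")
  in_region <- matrix(TRUE, grid$n_rows, grid$n_cols)
  if (!is.null(partition)) {
    stopifnot_same_grid(grid, partition$grid)
    occ_regions <- unique(partition$region_id[pidx])
    in_region <- matrix(partition$region_id %in% occ_regions,
                        grid$n_rows, grid$n_cols)
  }
  prc <- arrayInd(pidx, dim(presence))
  pxy <- cell_centres(grid, prc[, 1], prc[, 2])
  cand <- which(in_region)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  chunk <- 20000L
  b2 <- buffer_km^2
  for (start in seq(1L, length(cand), by = chunk)) {
    ii <- cand[start:min(start + chunk - 1L, length(cand))]
    rc <- arrayInd(ii, dim(presence))
    xy <- cell_centres(grid, rc[, 1], rc[, 2])
    d2 <- outer(xy[, 1], pxy[, 1], "-")^2 + outer(xy[, 2], pxy[, 2], "-")^2
    mask[ii] <- apply(d2 <= b2, 1, any)
  }
  mask[pidx] <- TRUE
  structure(list(grid = grid, mask = mask), class = "calibration_area")
}

#' Sample random pseudo-absences
#'
#' Draws `n_pa` cells uniformly without replacement from the calibration
#' area excluding presence cells (the "gRandom" background strategy).
#'
#' @param calib A `calibration_area`.
#' @param presence Logical presence matrix.
#' @param n_pa Number of pseudo-absence cells.
#' @param seed Integer seed.
#' @return Integer vector of cell indices (column-major).
#' @export
sample_pseudo_absences <- function(calib, presence, n_pa, seed) {
  avail <- which(calib$mask & !presence)
  if (!length(avail)) stop("no cells available for pseudo-absences")
  if (n_pa > length(avail)) {
    warning("n_pa exceeds available cells; drawing all ", length(avail))
    n_pa <- length(avail)
  }
  set.seed(as.integer(seed))
  sort(avail[sample.int(length(avail), n_pa)])
}

#' Stratified train/test replicates
#'
#' Each replicate draws a label-stratified random `train_frac` of the records
#' as training data (overall training size = `round(train_frac * n)`); the
#' remainder is the test set. Both labels are guaranteed present on each side
#' (each class keeps at least one record in train and in test).
#'
#' @param labels 0/1 vector.
#' @param train_frac Training fraction (default 0.7).
#' @param n_rep Number of replicates (default 5).
#' @param seed Integer seed.
#' @return A list of `n_rep` lists with integer index vectors `train`,
#'   `test`.
#' @export
partition_train_test <- function(labels, train_frac = 0.7, n_rep = 5, seed) {
  labels <- as.integer(labels)
  n <- length(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2 || any(tabulate(labels + 1L, 2L) < 2L)) {
    stop("need at least 2 records of each label")
  }
  target <- round(train_frac * n)
  n_by <- vapply(cls, function(k) sum(labels == k), 0L)
  base <- floor(train_frac * n_by)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(train_frac * n_by - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    cut <- order(train_frac * n_by - base)[seq_len(-rem)]
    base[cut] <- base[cut] - 1L
  }
  base <- pmin(pmax(base, 1L), n_by - 1L)   # both labels on both sides
  set.seed(as.integer(seed))
  lapply(seq_len(n_rep), function(r) {
    train <- integer()
    for (j in seq_along(cls)) {
      idx <- which(labels == cls[j])
      train <- c(train, idx[sample.int(length(idx), base[j])])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Default hyperparameters of the five base learners
#'
#' Fixed, versioned defaults: GLM (binomial, all linear terms); boosted trees
#' (xgboost, 60 rounds, depth 3, eta 0.1); MaxEnt-style lasso logistic
#' regression on linear + quadratic features (glmnet, lambda 1e-3); random
#' forest (ranger, 200 trees, probability forest); SVM (radial kernel,
#' scores via the logistic of the decision value).
#'
#' @return A named list of per-algorithm settings.
#' @export
default_learner_specs <- function() {
  list(
    glm    = list(),
    gbm    = list(nrounds = 60, max_depth = 3, eta = 0.1),
    maxent = list(lambda = 1e-3),
    rf     = list(num.trees = 200),
    svm    = list(kernel = "radial", cost = 1)
  )
}

#' Fit the base learners on one training set
#'
#' Constant predictor columns are dropped (with a message) before fitting;
#' every learner is deterministic under `seed` and returns scores in
#' `[0, 1]` via [predict.sdm_scorer()].
#'
#' @param x Numeric predictor matrix (rows = records).
#' @param y 0/1 labels.
#' @param algorithms Subset of `c("glm","gbm","maxent","rf","svm")`.
#' @param specs Hyperparameters, see [default_learner_specs()].
#' @param seed Integer seed.
#' @return A named list of `sdm_scorer` objects.
#' @export
fit_base_learners <- function(x, y,
                              algorithms = c("glm", "gbm", "maxent", "rf", "svm"),
                              specs = default_learner_specs(), seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("single-class training data")
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    message("dropping constant predictor column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (!ncol(x)) stop("no informative predictors left")
  out <- lapply(algorithms, function(alg) {
    fit_one_learner(alg, x, y, specs[[alg]], derive_seed(seed, alg))
  })
  names(out) <- algorithms
  out
}

fit_one_learner <- function(alg, x, y, spec, seed) {
  set.seed(seed)
  model <- switch(
    alg,
    glm = {
      d <- data.frame(x, .y = y)
      suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = d))
    },
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$max_depth %||% 3,
                    eta = spec$eta %||% 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = spec$nrounds %||% 60, verbose = 0),
    maxent = {
      f <- cbind(x, x^2)
      colnames(f) <- c(colnames(x), paste0(colnames(x), "_sq"))
      glmnet::glmnet(f, y, family = "binomial", alpha = 1,
                     lambda = sort(c(spec$lambda %||% 1e-3,
                                     10^seq(0, -4, length.out = 15)),
                                   decreasing = TRUE))
    },
    rf = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        probability = TRUE,
                        num.trees = spec$num.trees %||% 200,
                        seed = seed, num.threads = 1),
    svm = e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                     kernel = spec$kernel %||% "radial",
                     cost = spec$cost %||% 1, scale = TRUE),
    stop("unknown algorithm: ", alg)
  )
  structure(list(algorithm = alg, model = model, spec = spec,
                 columns = colnames(x)), class = "sdm_scorer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score new environments with a fitted base learner
#'
#' @param object An `sdm_scorer` from [fit_base_learners()].
#' @param newdata Numeric matrix with (at least) the fitted columns.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict.sdm_scorer <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$columns, drop = FALSE]
  switch(
    object$algorithm,
    glm = as.numeric(stats::predict(object$model, newdata = data.frame(x),
                                    type = "response")),
    gbm = as.numeric(stats::predict(object$model,
                                    xgboost::xgb.DMatrix(x, nthread = 1))),
    maxent = {
      f <- cbind(x, x^2)
      colnames(f) <- c(object$columns, paste0(object$columns, "_sq"))
      as.numeric(stats::predict(object$model, f,
                                s = object$spec$lambda %||% 1e-3,
                                type = "response"))
    },
    rf = {
      p <- stats::predict(object$model, data = x,
                          num.threads = 1)$predictions
      as.numeric(p[, "1"])
    },
    svm = {
      pr <- stats::predict(object$model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is positive for the class named first in the colname
      pos_first <- startsWith(colnames(dv)[1], "1")
      as.numeric(stats::plogis(if (pos_first) dv[, 1] else -dv[, 1]))
    }
  )
}

#' TSS-weighted ensemble of model-run predictions
#'
#' Runs with TSS below `retention_min` are discarded; retained runs are
#' averaged with weights proportional to their TSS.
#'
#' @param preds List of numeric prediction vectors/matrices (one per run,
#'   identical shape).
#' @param tss Numeric vector of run TSS values, parallel to `preds`.
#' @param retention_min Minimum TSS for retention (default 0.7).
#' @return The weighted-average prediction, or NULL (with a warning) when no
#'   run is retained.
#' @export
ensemble_predict <- function(preds, tss, retention_min = 0.7) {
  stopifnot(length(preds) == length(tss))
  keep <- which(tss >= retention_min)
  if (!length(keep)) {
    warning("no model run reaches TSS >= ", retention_min,
            "; species is unmodelable")
    return(NULL)
  }
  w <- tss[keep] / sum(tss[keep])
  out <- preds[[keep[1]]] * w[1]
  for (j in seq_along(keep)[-1]) out <- out + preds[[keep[j]]] * w[j]
  out
}

#' Construct a binary range object
#'
#' @param species_id Identifier.
#' @param scenario_label Scenario name.
#' @param raster Logical matrix (TRUE = suitable/occupied).
#' @param threshold The maxTSS threshold used for binarization.
#' @param extinct Extinction flag (meaningful for future scenarios).
#' @return A `binary_range` object.
#' @export
binary_range <- function(species_id, scenario_label, raster, threshold = NA,
                         extinct = FALSE) {
  structure(list(species_id = species_id, scenario_label = scenario_label,
                 raster = raster, threshold = threshold, extinct = extinct),
            class = "binary_range")
}

#' Binarize a suitability raster at a threshold
#'
#' Cells with suitability at or above the threshold become presences; masked
#' (NA) cells are absences.
#'
#' @param suitability Numeric matrix in `[0, 1]` (NA = masked).
#' @param threshold Threshold in `[0, 1]`.
#' @param species_id,scenario_label Metadata for the result.
#' @return A [binary_range()].
#' @export
binarize <- function(suitability, threshold, species_id = "sp",
                     scenario_label = "current") {
  stopifnot(threshold >= 0, threshold <= 1)
  r <- !is.na(suitability) & suitability >= threshold
  binary_range(species_id, scenario_label, r, threshold)
}

#' No-dispersal projection of a range to future climate
#'
#' A cell is suitable in the future only if it is suitable under the future
#' climate AND already occupied currently (no colonization of newly emerged
#' habitat). The extinction flag is set when no cell remains.
#'
#' @param current A [binary_range()] for the current scenario.
#' @param future_suitability Future suitability matrix on the same grid.
#' @param threshold The species' maxTSS threshold.
#' @param scenario_label Label for the projected range.
#' @return A [binary_range()] with `extinct` set appropriately.
#' @export
project_future <- function(current, future_suitability, threshold,
                           scenario_label = "future") {
  if (!all(dim(future_suitability) == dim(current$raster))) {
    stop("grid mismatch between current range and future suitability")
  }
  r <- !is.na(future_suitability) & future_suitability >= threshold &
    current$raster
  binary_range(current$species_id, scenario_label, r, threshold,
               extinct = !any(r))
}

#' Fit an ensemble species distribution model
#'
#' The package's central fitting function. From thinned presence records and
#' a current climate stack it: (1) builds the calibration area (occupied
#' regions + `buffer_km`), (2) screens predictors by stepwise VIF,
#' (3) samples random pseudo-absences (default `max(n_presence, 1000)`,
#' capped at availability), (4) makes `n_rep` stratified `train_frac` splits,
#' (5) fits every algorithm on every split and scores test TSS (maximized
#' over thresholds) and AUC, (6) retains runs with TSS >= `retention_min`
#' and averages their predictions with TSS weights, (7) thresholds the
#' ensemble at the maxTSS cut computed on the pooled presence/pseudo-absence
#' set. Cells outside the calibration area are unsuitable by definition.
#'
#' @param occ An [occurrence_set()] (kept records are used) or a logical
#'   presence matrix on the grid.
#' @param climate Current-scenario `climate_stack`.
#' @param partition Optional `partition_rasters` (regions constrain the
#'   calibration area).
#' @param buffer_km Calibration buffer in km (default 500).
#' @param vif_threshold Stepwise-VIF retention threshold (default 10).
#' @param n_vif_cells Cells sampled for VIF estimation (default 10000).
#' @param n_pa Pseudo-absence count; default `max(n_presence, 1000)`.
#' @param train_frac,n_rep Split fraction and replicate count (0.7, 5).
#' @param algorithms Base learners to use.
#' @param retention_min TSS retention minimum (default 0.7).
#' @param specs Learner hyperparameters ([default_learner_specs()]).
#' @param species_id Identifier stored on the fit.
#' @param seed Integer master seed for this fit.
#' @return An object of class `esdm`. Key fields: `runs` (per-run TSS/AUC
#'   and retention), `suitability` (current ensemble raster), `range`
#'   (current [binary_range()]), `threshold` (maxTSS cut), `status`
#'   (`"ok"` or `"unmodelable"`).
#' @seealso [predict.esdm()], [project_range()], [summary.esdm()]
#' @export
ensemble_sdm <- function(occ, climate, partition = NULL, buffer_km = 500,
                         vif_threshold = 10, n_vif_cells = 10000,
                         n_pa = NULL, train_frac = 0.7, n_rep = 5,
                         algorithms = c("glm", "gbm", "maxent", "rf", "svm"),
                         retention_min = 0.7,
                         specs = default_learner_specs(),
                         species_id = NULL, seed = 1) {
  grid <- climate$grid
  if (inherits(occ, "occurrence_set") ||
      (is.data.frame(occ) && all(c("x_km", "y_km") %in% names(occ)))) {
    occ <- as_occurrence_set(occ)
    if (is.null(species_id)) species_id <- as.character(occ$species_id[1])
    rc <- cells_from_xy(grid, occ$x_km[occ$kept], occ$y_km[occ$kept])
    rc <- rc[!is.na(rc$row), , drop = FALSE]
    presence <- matrix(FALSE, grid$n_rows, grid$n_cols)
    presence[cell_index(grid, rc$row, rc$col)] <- TRUE
  } else {
    presence <- occ
    if (is.null(species_id)) species_id <- "sp"
  }
  pidx <- which(presence)
  if (!length(pidx)) stop("species ", species_id, " has no presence cells")

  calib <- build_calibration_area(presence, grid, partition, buffer_km)
  vf <- vif_filter(climate, threshold = vif_threshold,
                   n_sample_cells = n_vif_cells,
                   seed = derive_seed(seed, "vif"), cells = calib$mask)
  vars <- vf$kept

  n_pres <- length(pidx)
  if (is.null(n_pa)) n_pa <- max(n_pres, 1000L)
  pa_idx <- sample_pseudo_absences(calib, presence, n_pa,
                                   derive_seed(seed, "pa"))
  cells <- c(pidx, pa_idx)
  y <- c(rep(1L, n_pres), rep(0L, length(pa_idx)))
  x <- env_at(climate, cells, vars)

  splits <- partition_train_test(y, train_frac, n_rep,
                                 derive_seed(seed, "split"))
  runs <- list(); scorers <- list(); k <- 0L
  for (r in seq_len(n_rep)) {
    sp <- splits[[r]]
    fits <- fit_base_learners(x[sp$train, , drop = FALSE], y[sp$train],
                              algorithms, specs,
                              seed = derive_seed(seed, paste0("fit", r)))
    for (alg in algorithms) {
      k <- k + 1L
      sc <- predict(fits[[alg]], x[sp$test, , drop = FALSE])
      mt <- max_tss_threshold(sc, y[sp$test])
      runs[[k]] <- data.frame(algorithm = alg, replicate = r,
                              tss = mt$tss,
                              auc = evaluate_auc(sc, y[sp$test]),
                              threshold = mt$threshold,
                              retained = mt$tss >= retention_min)
      scorers[[k]] <- fits[[alg]]
    }
  }
  runs <- do.call(rbind, runs)

  fit <- structure(
    list(species_id = species_id, grid = grid, runs = runs,
         scorers = scorers[runs$retained], variables = vars,
         vif = vf, calibration = calib, presence = presence,
         cells = cells, labels = y,
         retention_min = retention_min, n_pa = length(pa_idx),
         weights = NULL, threshold = NA_real_, suitability = NULL,
         range = NULL, status = "ok", seed = seed),
    class = "esdm")

  if (!any(runs$retained)) {
    warning("species ", species_id, ": no run reaches TSS >= ",
            retention_min, "; flagged unmodelable")
    fit$status <- "unmodelable"
    return(fit)
  }
  fit$weights <- runs$tss[runs$retained] / sum(runs$tss[runs$retained])
  fit$suitability <- predict(fit, climate)
  pooled <- fit$suitability[cells]
  mt <- max_tss_threshold(pooled, y)
  fit$threshold <- mt$threshold
  fit$range <- binarize(fit$suitability, fit$threshold, species_id, "current")
  fit
}

#' Ensemble suitability under a climate stack
#'
#' Scores every calibration-area cell with each retained run and returns the
#' TSS-weighted average as a raster; cells outside the calibration area get
#' suitability 0.
#'
#' @param object An `esdm` fit.
#' @param climate A `climate_stack` (current or future) on the fit's grid.
#' @param ... Unused.
#' @return A numeric suitability matrix in `[0, 1]`.
#' @export
predict.esdm <- function(object, climate, ...) {
  if (object$status != "ok") stop("species ", object$species_id,
                                  " is unmodelable")
  stopifnot_same_grid(object$grid, climate$grid)
  idx <- which(object$calibration$mask)
  newx <- env_at(climate, idx, object$variables)
  acc <- numeric(length(idx))
  for (j in seq_along(object$scorers)) {
    acc <- acc + object$weights[j] * predict(object$scorers[[j]], newx)
  }
  out <- matrix(0, object$grid$n_rows, object$grid$n_cols)
  out[idx] <- acc
  out
}

#' Project a fitted species range to a future climate (no dispersal)
#'
#' @param object An `esdm` fit with a current range.
#' @param future_climate A future-scenario `climate_stack`.
#' @param scenario_label Label for the projected range.
#' @return A [binary_range()]; `extinct` is TRUE when no suitable cell of
#'   the current range remains.
#' @export
project_range <- function(object, future_climate,
                          scenario_label = future_climate$scenario_label) {
  fut <- predict(object, future_climate)
  project_future(object$range, fut, object$threshold, scenario_label)
}

#' @export
print.esdm <- function(x, ...) {
  cat(sprintf("Ensemble SDM for '%s' [%s]\n", x$species_id, x$status))
  cat(sprintf("  runs: %d (%d retained at TSS >= %.2f)\n", nrow(x$runs),
              sum(x$runs$retained), x$retention_min))
  if (x$status == "ok") {
    cat(sprintf("  maxTSS threshold: %.3f; current range: %d cells\n",
                x$threshold, sum(x$range$raster)))
  }
  invisible(x)
}

#' Summarize an ensemble SDM fit
#'
#' @param object An `esdm` fit.
#' @param ... Unused.
#' @return A list with per-algorithm mean TSS/AUC, retention counts, the
#'   ensemble threshold and range size; printed compactly.
#' @export
summary.esdm <- function(object, ...) {
  agg <- stats::aggregate(cbind(tss, auc) ~ algorithm, data = object$runs,
                          FUN = mean)
  ret <- stats::aggregate(retained ~ algorithm, data = object$runs, FUN = sum)
  out <- list(species_id = object$species_id, status = object$status,
              by_algorithm = merge(agg, ret), threshold = object$threshold,
              range_cells = if (object$status == "ok")
                sum(object$range$raster) else NA_integer_,
              variables = object$variables)
  class(out) <- "summary.esdm"
  out
}

#' @export
print.summary.esdm <- function(x, ...) {
  cat(sprintf("Ensemble SDM summary for '%s' [%s]\n", x$species_id, x$status))
  print(x$by_algorithm, row.names = FALSE)
  cat(sprintf("  predictors: %s\n", paste(x$variables, collapse = ", ")))
  if (!is.na(x$threshold)) {
    cat(sprintf("  maxTSS threshold %.3f; range %d cells\n", x$threshold,
                x$range_cells))
  }
  invisible(x)
}

#' Plot an ensemble suitability map
#'
#' @param x An `esdm` fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.esdm <- function(x, ...) {
  if (x$status != "ok") stop("nothing to plot: species is unmodelable")
  m <- x$suitability
  graphics::image(t(m[nrow(m):1, ]), zlim = c(0, 1), axes = FALSE,
                  main = paste("Ensemble suitability:", x$species_id),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
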