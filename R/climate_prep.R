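#' @title Predictor preparation: GCM averaging and collinearity screening
#' @description Future climate layers are averaged across global circulation
#'   models cell-by-cell, and predictors are screened for multicollinearity
#'   with the stepwise variance-inflation-factor (VIF) procedure: repeatedly
#'   drop the variable with the largest VIF until all remaining VIFs fall
#'   below the threshold (default 10).
#' @name climate_prep
NULL

#' Average climate stacks across GCMs
#'
#' Per-cell, per-variable arithmetic mean of co-registered stacks. A cell
#' masked in any input is masked in the output.
#'
#' @param stacks A list of `climate_stack` objects sharing grid and variable
#'   set.
#' @param scenario_label Label for the averaged stack (default taken from the
#'   first input).
#' @return A `climate_stack`.
#' @export
average_gcms <- function(stacks, scenario_label = stacks[[1]]$scenario_label) {
  stopifnot(length(stacks) >= 1)
  g <- stacks[[1]]$grid
  vars <- names(stacks[[1]]$layers)
  for (s in stacks) {
    stopifnot_same_grid(g, s$grid)
    if (!setequal(names(s$layers), vars)) stop("variable sets differ")
  }
  mask <- Reduce(`&`, lapply(stacks, `[[`, "mask"))
  layers <- lapply(vars, function(v) {
    m <- Reduce(`+`, lapply(stacks, function(s) s$layers[[v]])) / length(stacks)
    m[!mask] <- NA
    m
  })
  names(layers) <- vars
  climate_stack(g, scenario_label, layers, mask)
}

#' Variance inflation factor of one variable
#'
#' VIF = 1 / (1 - R^2), with R^2 from the least-squares regression (with
#' intercept) of the variable on all others in the sample. Perfect
#' collinearity yields `Inf`, never an error.
#'
#' @param sample Numeric matrix (cells x variables) with column names and no
#'   missing values.
#' @param variable Name of the column to diagnose.
#' @return The VIF (>= 1, possibly `Inf`).
#' @export
compute_vif <- function(sample, variable) {
  stopifnot(is.matrix(sample), variable %in% colnames(sample),
            !anyNA(sample), nrow(sample) > ncol(sample) + 1)
  y <- sample[, variable]
  x <- sample[, setdiff(colnames(sample), variable), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(Inf)             # constant column: undefined, flag high
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

#' Sample predictor values from a climate stack
#'
#' @param stack A `climate_stack`.
#' @param n_sample_cells Number of valid cells to sample (capped at the
#'   available count).
#' @param seed Integer seed.
#' @param cells Optional logical matrix restricting the sampling domain
#'   (e.g. a calibration area).
#' @return A numeric matrix (cells x variables).
#' @export
sample_predictors <- function(stack, n_sample_cells = 10000, seed = 1,
                              cells = NULL) {
  dom <- stack$mask
  if (!is.null(cells)) dom <- dom & cells
  idx <- which(dom)
  if (!length(idx)) stop("no valid cells to sample")
  set.seed(as.integer(seed))
  take <- idx[sample.int(length(idx), min(n_sample_cells, length(idx)))]
  out <- vapply(stack$layers, function(m) m[take], numeric(length(take)))
  colnames(out) <- names(stack$layers)
  out
}

#' Stepwise VIF filtering of predictor variables
#'
#' Iteratively removes the variable with the largest VIF (ties broken by the
#' stack's variable order) until all remaining VIFs are below `threshold`.
#' Stops with a warning rather than dropping below two variables.
#'
#' @param stack A `climate_stack` (or a plain predictor matrix).
#' @param threshold VIF threshold; variables are retained when VIF <
#'   threshold (default 10).
#' @param n_sample_cells Cells sampled to estimate VIFs (default 10000,
#'   capped at availability).
#' @param seed Integer seed for the cell sample.
#' @param cells Optional logical matrix restricting sampling (per-species
#'   calibration areas).
#' @return A list with `kept` (variable names), `removed` (in removal
#'   order) and `vifs` (final VIFs of the kept variables).
#' @export
vif_filter <- function(stack, threshold = 10, n_sample_cells = 10000,
                       seed = 1, cells = NULL) {
  stopifnot(threshold > 1)
  sample <- if (is.matrix(stack)) stack else
    sample_predictors(stack, n_sample_cells, seed, cells)
  vars <- colnames(sample)
  removed <- character()
  repeat {
    if (length(vars) < 2) {
      warning("fewer than 2 variables remain; stopping VIF filtering")
      break
    }
    v <- vapply(vars, function(nm)
      compute_vif(sample[, vars, drop = FALSE], nm), 0)
    if (max(v) < threshold) break
    worst <- vars[which.max(v)]         # which.max takes the first tie
    removed <- c(removed, worst)
    vars <- setdiff(vars, worst)
  }
  final <- if (length(vars) >= 2) {
    vapply(vars, function(nm) compute_vif(sample[, vars, drop = FALSE], nm), 0)
  } else stats::setNames(rep(NA_real_, length(vars)), vars)
  list(kept = vars, removed = removed, vifs = final)
}
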