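#' @title Synthetic landscape generators
#' @description Generators for the synthetic world every downstream stage is
#'   tested against: spatially autocorrelated bioclimatic layers under current
#'   and shifted future scenarios, virtual species with known Gaussian niches,
#'   biased presence-only sampling, a protected-area (PA) network with
#'   IUCN-style classes, and zoogeographic-region / country partitions.
#'   Every generator is a pure function of its parameters and a seed.
#' @name landscape
NULL

BIO_VARS <- c("BIO1", "BIO3", "BIO5", "BIO6", "BIO12", "BIO18")
PA_CLASSES <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")
PA_STRICT <- c("Ia", "Ib", "II", "III", "IV")

# Stationary Gaussian-like random field: white noise convolved (on the torus,
# via FFT) with a Gaussian kernel of the requested correlation length, then
# standardized to mean 0, sd 1.
gaussian_field <- function(n_rows, n_cols, range_cells) {
  if (!is.finite(range_cells) || range_cells <= 0) {
    stop("autocorrelation length must be positive")
  }
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  dr <- pmin(0:(n_rows - 1), n_rows - (0:(n_rows - 1)))
  dc <- pmin(0:(n_cols - 1), n_cols - (0:(n_cols - 1)))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * range_cells^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  (f - mean(f)) / stats::sd(f)
}

#' Default climate-field parameters
#'
#' Means and spreads emulate a temperate-to-subtropical region: annual mean
#' temperature (BIO1) 15 +/- 5 deg C, isothermality (BIO3) 45 +/- 8, warm/cold
#' extremes (BIO5/BIO6) offset from BIO1 by spatially varying positive margins
#' (~+8 / -12 deg C), annual precipitation (BIO12) log-normal around 800 mm,
#' warm-quarter precipitation (BIO18) a (0,1) fraction of BIO12 around 0.4.
#' The construction guarantees BIO6 <= BIO1 <= BIO5, BIO12 >= 0 and
#' 0 <= BIO18 <= BIO12 at every cell without rejection sampling.
#'
#' @param range_km Autocorrelation length of the underlying fields, in km.
#' @param bio1_mean,bio1_sd Mean/spread of BIO1 (deg C).
#' @param bio3_mean,bio3_sd Mean/spread of BIO3 (unitless index).
#' @param bio5_offset,bio6_offset Median positive margins of BIO5 above and
#'   BIO6 below BIO1 (deg C).
#' @param bio12_median Median annual precipitation (mm).
#' @param bio12_logsd Log-scale spread of BIO12.
#' @param bio18_frac Median BIO18/BIO12 fraction.
#' @return A named list of parameters for [simulate_climate()].
#' @export
climate_params <- function(range_km = 15, bio1_mean = 15, bio1_sd = 5,
                           bio3_mean = 45, bio3_sd = 8,
                           bio5_offset = 8, bio6_offset = 12,
                           bio12_median = 800, bio12_logsd = 0.5,
                           bio18_frac = 0.4) {
  as.list(environment())
}

#' Simulate a stack of six bioclimatic layers
#'
#' Generates spatially autocorrelated layers for BIO1, BIO3, BIO5, BIO6,
#' BIO12 and BIO18 on a shared grid. Temperature ordering and precipitation
#' positivity hold by construction (BIO5/BIO6 are BIO1 plus/minus positive
#' log-normal margins; BIO12 is log-normal; BIO18 is a logistic fraction of
#' BIO12).
#'
#' @param grid A [grid_spec()].
#' @param params A [climate_params()] list.
#' @param seed Integer seed; identical inputs reproduce identical stacks.
#' @param scenario_label Label stored on the stack (default "current").
#' @return A `climate_stack`: list with `grid`, `scenario_label`, `layers`
#'   (named list of matrices) and `mask` (logical matrix of valid cells).
#' @export
simulate_climate <- function(grid, params = climate_params(), seed,
                             scenario_label = "current") {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(params$range_km) || params$range_km <= 0) {
    stop("autocorrelation length (range_km) must be positive")
  }
  set.seed(as.integer(seed))
  rc <- params$range_km / grid$cell_size_km
  nr <- grid$n_rows; nc <- grid$n_cols
  f <- replicate(5, gaussian_field(nr, nc, rc), simplify = FALSE)
  bio1 <- params$bio1_mean + params$bio1_sd * f[[1]]
  bio3 <- params$bio3_mean + params$bio3_sd * f[[2]]
  bio5 <- bio1 + exp(log(params$bio5_offset) + 0.2 * f[[3]])
  bio6 <- bio1 - exp(log(params$bio6_offset) - 0.2 * f[[3]])
  bio12 <- exp(log(params$bio12_median) + params$bio12_logsd * f[[4]])
  bio18 <- bio12 * stats::plogis(stats::qlogis(params$bio18_frac) + 0.8 * f[[5]])
  climate_stack(grid, scenario_label,
                list(BIO1 = bio1, BIO3 = bio3, BIO5 = bio5, BIO6 = bio6,
                     BIO12 = bio12, BIO18 = bio18),
                mask = matrix(TRUE, nr, nc))
}

#' Construct a climate stack
#'
#' @param grid A [grid_spec()].
#' @param scenario_label Scenario name, e.g. "current" or "future_rcp45".
#' @param layers Named list of numeric matrices on `grid`.
#' @param mask Logical matrix; TRUE where cells carry data.
#' @return A `climate_stack` object.
#' @export
climate_stack <- function(grid, scenario_label, layers, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == c(grid$n_rows, grid$n_cols))) {
      stop("layer ", nm, " does not match the grid")
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  structure(list(grid = grid, scenario_label = scenario_label,
                 layers = layers, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack '%s': %d x %d, layers: %s\n", x$scenario_label,
              x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Project a climate stack to a future scenario
#'
#' Applies per-variable additive and/or multiplicative shifts plus optional
#' spatially uncorrelated noise. With `pa_stability`, the per-cell climate
#' delta is scaled by a damping factor inside protected cells, emulating the
#' milder climate change observed within PAs. After shifting, temperature
#' ordering and precipitation bounds are restored minimally on the variables
#' the caller did not shift (shifted variables are never altered).
#'
#' @param current A `climate_stack`.
#' @param shift Named list, one entry per shifted variable, each a list/vector
#'   with elements `add` and/or `mul` (e.g.
#'   `list(BIO1 = c(add = 2), BIO12 = c(mul = 0.9))`).
#' @param noise_sd Standard deviation of per-cell Gaussian noise added to each
#'   shifted variable's delta (default 0).
#' @param pa_stability Optional list `(pa = <pa_mask>, damping = f)` with
#'   `f` in `[0, 1]`; deltas inside PA cells (classes Ia-VI) are multiplied by
#'   `f`.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param scenario_label Label for the output stack.
#' @return A `climate_stack` on the same grid and mask.
#' @export
project_future_climate <- function(current, shift, noise_sd = 0,
                                   pa_stability = NULL, seed = 1,
                                   scenario_label = "future") {
  stopifnot(inherits(current, "climate_stack"))
  unknown <- setdiff(names(shift), names(current$layers))
  if (length(unknown)) {
    stop("shift names variables not in the stack: ",
         paste(unknown, collapse = ", "))
  }
  damp <- NULL
  if (!is.null(pa_stability)) {
    f <- pa_stability$damping
    if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1) {
      stop("damping factor must be in [0, 1]")
    }
    stopifnot_same_grid(current$grid, pa_stability$pa$grid)
    damp <- matrix(1, current$grid$n_rows, current$grid$n_cols)
    damp[pa_subset_mask(pa_stability$pa, "all")] <- f
  }
  set.seed(as.integer(seed))
  layers <- current$layers
  shifted <- names(shift)
  for (v in shifted) {
    sh <- as.list(shift[[v]])
    cur <- current$layers[[v]]
    target <- cur
    if (!is.null(sh$mul)) target <- target * sh$mul
    if (!is.null(sh$add)) target <- target + sh$add
    delta <- target - cur
    if (noise_sd > 0) {
      delta <- delta + matrix(stats::rnorm(length(cur), 0, noise_sd),
                              nrow(cur), ncol(cur))
    }
    if (!is.null(damp)) delta <- delta * damp
    layers[[v]] <- cur + delta
  }
  # minimal invariant repair on unshifted variables only
  fix <- function(v, val) if (!(v %in% shifted)) val else layers[[v]]
  if (all(c("BIO1", "BIO5") %in% names(layers))) {
    layers$BIO5 <- fix("BIO5", pmax(layers$BIO5, layers$BIO1))
  }
  if (all(c("BIO1", "BIO6") %in% names(layers))) {
    layers$BIO6 <- fix("BIO6", pmin(layers$BIO6, layers$BIO1))
  }
  if ("BIO12" %in% names(layers)) {
    layers$BIO12 <- fix("BIO12", pmax(layers$BIO12, 0))
  }
  if (all(c("BIO12", "BIO18") %in% names(layers))) {
    layers$BIO18 <- fix("BIO18", pmin(pmax(layers$BIO18, 0), layers$BIO12))
  }
  climate_stack(current$grid, scenario_label, layers, current$mask)
}

#' Define a virtual species
#'
#' A virtual species has a known Gaussian response to each niche variable;
#' joint suitability is the product of the per-variable responses, so it
#' equals 1 exactly at the joint optimum. Cells with suitability at or above
#' `presence_threshold` form the species' true range.
#'
#' @param species_id Identifier string.
#' @param niche Named list; each element `c(opt = , sd = )` for one climate
#'   variable, with `sd > 0`.
#' @param presence_threshold Suitability cut in (0, 1) (default 0.3).
#' @return A `virtual_species` object.
#' @export
virtual_species <- function(species_id, niche, presence_threshold = 0.3) {
  stopifnot(is.list(niche), length(niche) >= 1)
  for (v in names(niche)) {
    p <- as.list(niche[[v]])
    if (is.null(p$sd) || !is.finite(p$sd) || p$sd <= 0) {
      stop("niche breadth (sd) for ", v, " must be positive")
    }
    if (is.null(p$opt) || !is.finite(p$opt)) stop("niche optimum for ", v,
                                                  " must be finite")
  }
  if (presence_threshold <= 0 || presence_threshold >= 1) {
    stop("presence_threshold must be in (0, 1)")
  }
  structure(list(species_id = species_id, niche = niche,
                 presence_threshold = presence_threshold),
            class = "virtual_species")
}

#' Ground-truth suitability of a virtual species
#'
#' @param vsp A [virtual_species()].
#' @param climate A `climate_stack` containing every niche variable.
#' @return A suitability matrix in `[0, 1]` (NA where the stack is masked).
#' @export
true_suitability <- function(vsp, climate) {
  missing_v <- setdiff(names(vsp$niche), names(climate$layers))
  if (length(missing_v)) {
    stop("niche variables missing from the stack: ",
         paste(missing_v, collapse = ", "))
  }
  s <- matrix(1, climate$grid$n_rows, climate$grid$n_cols)
  for (v in names(vsp$niche)) {
    p <- as.list(vsp$niche[[v]])
    s <- s * exp(-(climate$layers[[v]] - p$opt)^2 / (2 * p$sd^2))
  }
  s[!climate$mask] <- NA
  s
}

#' True range of a virtual species
#'
#' @param vsp A [virtual_species()].
#' @param climate A `climate_stack`.
#' @param threshold Optional override of the species' presence threshold.
#' @return Logical matrix: TRUE where suitability >= threshold.
#' @export
true_range <- function(vsp, climate, threshold = vsp$presence_threshold) {
  s <- true_suitability(vsp, climate)
  r <- !is.na(s) & s >= threshold
  r
}

#' Sample presence-only occurrence records
#'
#' Draws `n` records (cells, with replacement — duplicates are expected and
#' removed downstream by thinning) from the species' true range, with
#' per-cell probability proportional to suitability times optional sampling
#' effort. Points are placed at cell centres.
#'
#' @param species_id Identifier attached to the records.
#' @param suitability Suitability matrix from [true_suitability()].
#' @param truth Logical matrix, the species' true range.
#' @param n Number of records to draw (>= 1).
#' @param grid The [grid_spec()] the rasters lie on.
#' @param bias Optional non-negative effort matrix on the same grid.
#' @param seed Integer seed.
#' @return An occurrence data.frame (see [occurrence_set()]).
#' @export
sample_occurrences <- function(species_id, suitability, truth, n, grid,
                               bias = NULL, seed) {
  stopifnot(n >= 1)
  w <- suitability
  w[!truth | is.na(w)] <- 0
  if (!is.null(bias)) {
    stopifnot(all(dim(bias) == dim(w)))
    if (any(bias < 0, na.rm = TRUE)) stop("effort raster must be non-negative")
    w <- w * bias
  }
  if (!any(w > 0)) stop("unsampleable species: ", species_id,
                        " has an empty (or zero-effort) true range")
  set.seed(as.integer(seed))
  idx <- sample.int(length(w), size = n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  xy <- cell_centres(grid, rc[, 1], rc[, 2])
  year <- sample(1970:2022, n, replace = TRUE)
  occurrence_set(species_id, xy[, 1], xy[, 2], year = year,
                 source = "synthetic")
}

#' Simulate a protected-area network
#'
#' Grows `n_patches` contiguous patches by seeded random flood-fill until the
#' protected fraction reaches `target_fraction`. Each patch receives one IUCN
#' class drawn from `class_mix`. With `placement = "stable"`, patch seeds and
#' growth prefer cells with the smallest projected climate change (|delta
#' BIO1| between the supplied current and future stacks), emulating PAs
#' sitting in climatically stable locations.
#'
#' @param grid A [grid_spec()].
#' @param target_fraction Protected fraction of cells, in (0, 1).
#' @param n_patches Number of contiguous patches.
#' @param class_mix Named proportions over `c("Ia","Ib","II","III","IV","V","VI")`
#'   summing to 1.
#' @param placement `"uniform"` or `"stable"`.
#' @param climate_current,climate_future Climate stacks, required for
#'   `placement = "stable"`.
#' @param seed Integer seed.
#' @return A `pa_mask`: list with `grid` and `class_raster` (integer matrix,
#'   0 = unprotected, 1..7 = Ia..VI).
#' @export
simulate_pa_network <- function(grid, target_fraction, n_patches,
                                class_mix = c(II = 0.3, IV = 0.3, V = 0.2, VI = 0.2),
                                placement = c("uniform", "stable"),
                                climate_current = NULL, climate_future = NULL,
                                seed) {
  placement <- match.arg(placement)
  stopifnot(target_fraction > 0, target_fraction < 1)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% PA_CLASSES)) {
    stop("class_mix names must be IUCN classes Ia..VI")
  }
  nr <- grid$n_rows; nc <- grid$n_cols
  total <- nr * nc
  target_cells <- max(1L, round(target_fraction * total))
  if (n_patches > target_cells) {
    stop("target_fraction infeasible: fewer target cells than patches")
  }
  set.seed(as.integer(seed))
  pref <- NULL
  if (placement == "stable") {
    if (is.null(climate_current) || is.null(climate_future)) {
      stop("stable placement needs climate_current and climate_future")
    }
    pref <- abs(climate_future$layers$BIO1 - climate_current$layers$BIO1)
  }
  class_lab <- matrix(0L, nr, nc)
  patch_id <- matrix(0L, nr, nc)
  # patch seeds: uniform, or among the most climate-stable 20% of cells
  if (is.null(pref)) {
    seeds <- sample.int(total, n_patches)
  } else {
    pool <- order(as.vector(pref))[seq_len(max(n_patches, ceiling(0.2 * total)))]
    seeds <- sample(pool, n_patches)
  }
  sizes <- as.vector(stats::rmultinom(1, target_cells - n_patches,
                                      rep(1 / n_patches, n_patches))) + 1L
  nbr_offsets <- function(i) {
    r <- (i - 1L) %% nr + 1L; cl <- (i - 1L) %/% nr + 1L
    c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
      if (cl > 1L) i - nr, if (cl < nc) i + nr)
  }
  classes <- sample(names(class_mix), n_patches, replace = TRUE,
                    prob = class_mix)
  for (p in seq_len(n_patches)) {
    code <- match(classes[p], PA_CLASSES)
    s <- seeds[p]
    if (patch_id[s] != 0L) {           # collided with an earlier patch: move
      free <- which(patch_id == 0L)
      if (!length(free)) break
      s <- if (is.null(pref)) sample(free, 1) else
        free[which.min(pref[free])]
    }
    frontier <- s
    grown <- 0L
    while (grown < sizes[p] && length(frontier)) {
      pick <- if (is.null(pref) || length(frontier) == 1L) {
        frontier[sample.int(length(frontier), 1L)]
      } else {
        frontier[which.min(pref[frontier])]
      }
      frontier <- frontier[frontier != pick]
      if (patch_id[pick] != 0L) next
      patch_id[pick] <- p
      class_lab[pick] <- code
      grown <- grown + 1L
      nb <- nbr_offsets(pick)
      frontier <- c(frontier, nb[patch_id[nb] == 0L])
    }
  }
  structure(list(grid = grid, class_raster = class_lab), class = "pa_mask")
}

#' Construct a PA mask from a class raster
#'
#' @param grid A [grid_spec()].
#' @param class_raster Integer matrix of codes (0 = unprotected, 1..7 =
#'   Ia, Ib, II, III, IV, V, VI) or a character matrix of class labels
#'   ("none" or an IUCN class).
#' @return A `pa_mask` object.
#' @export
pa_mask <- function(grid, class_raster) {
  if (is.character(class_raster)) {
    m <- matrix(match(class_raster, PA_CLASSES, nomatch = 0L),
                nrow(class_raster))
  } else {
    m <- class_raster
    storage.mode(m) <- "integer"
  }
  stopifnot(all(dim(m) == c(grid$n_rows, grid$n_cols)),
            all(m %in% 0:7))
  structure(list(grid = grid, class_raster = m), class = "pa_mask")
}

#' Logical mask of protected cells
#'
#' @param pa A `pa_mask`.
#' @param subset `"strict"` (IUCN classes Ia-IV) or `"all"` (Ia-VI).
#' @return Logical matrix; TRUE where the cell's class is in the subset.
#' @export
pa_subset_mask <- function(pa, subset = c("strict", "all")) {
  subset <- match.arg(subset)
  codes <- if (subset == "strict") match(PA_STRICT, PA_CLASSES) else
    seq_along(PA_CLASSES)
  matrix(pa$class_raster %in% codes, nrow(pa$class_raster))
}

#' Partition the grid into connected regions and countries
#'
#' Multi-source random breadth-first growth from `k` seed cells produces `k`
#' connected, space-filling labels — stand-ins for zoogeographic regions and
#' country borders.
#'
#' @param grid A [grid_spec()].
#' @param k_regions,k_countries Number of regions / countries (>= 1 each).
#' @param seed Integer seed.
#' @return A `partition_rasters`: list with `grid`, `region_id` and
#'   `country_id` integer matrices.
#' @export
simulate_partition <- function(grid, k_regions, k_countries, seed) {
  tot <- n_cells(grid)
  if (k_regions < 1 || k_countries < 1) stop("k must be >= 1")
  if (k_regions > tot || k_countries > tot) {
    stop("k exceeds the number of grid cells")
  }
  set.seed(as.integer(seed))
  structure(list(grid = grid,
                 region_id = grow_labels(grid, k_regions),
                 country_id = grow_labels(grid, k_countries)),
            class = "partition_rasters")
}

# k-source BFS: each sweep dilates every label (in random order) into
# unassigned 4-neighbours; connectivity holds by construction.
grow_labels <- function(grid, k) {
  nr <- grid$n_rows; nc <- grid$n_cols
  lab <- matrix(0L, nr, nc)
  lab[sample.int(nr * nc, k)] <- seq_len(k)
  shift_up <- function(m) rbind(m[-1, , drop = FALSE], rep(0L, nc))
  shift_dn <- function(m) rbind(rep(0L, nc), m[-nr, , drop = FALSE])
  shift_lf <- function(m) cbind(m[, -1, drop = FALSE], rep(0L, nr))
  shift_rt <- function(m) cbind(rep(0L, nr), m[, -nc, drop = FALSE])
  while (any(lab == 0L)) {
    progressed <- FALSE
    for (lb in sample.int(k)) {
      cur <- lab == lb
      grow <- (shift_up(cur) | shift_dn(cur) | shift_lf(cur) | shift_rt(cur)) &
        lab == 0L
      if (any(grow)) {
        lab[grow] <- lb
        progressed <- TRUE
      }
    }
    if (!progressed) break   # cannot happen on a connected grid; safety valve
  }
  lab
}
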