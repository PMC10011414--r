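#' @title Protected-area effectiveness metrics
#' @description Species-level coverage of ranges by the PA network (strict
#'   IUCN classes Ia-IV versus all classes Ia-VI), percentage of species with
#'   suitable habitat in PAs, coverage benchmarks (>15% / >30% of range
#'   protected), rarity-weighted richness, and range loss inside versus
#'   outside PAs under the no-dispersal assumption.
#' @name pa_effectiveness
NULL

#' Fraction of a species' range inside PAs
#'
#' @param range A [binary_range()] with at least one presence cell.
#' @param pa A `pa_mask`.
#' @param subset `"strict"` (Ia-IV) or `"all"` (Ia-VI).
#' @return Fraction in `[0, 1]`; inside + outside fractions sum to 1.
#' @export
coverage_fraction <- function(range, pa, subset = c("strict", "all")) {
  subset <- match.arg(subset)
  n <- sum(range$raster)
  if (n == 0) {
    stop("empty range for ", range$species_id,
         "; extinct species take the extinction path, not coverage")
  }
  sum(range$raster & pa_subset_mask(pa, subset)) / n
}

#' Percentage of species with suitable habitat in PAs
#'
#' A species counts as protected when at least one of its range cells lies
#' in a PA of the chosen subset. Extinct species are excluded from the
#' denominator (future scenarios count surviving species only).
#'
#' @param ranges List of [binary_range()] objects for one scenario.
#' @param pa A `pa_mask`.
#' @param subset `"strict"` or `"all"`.
#' @return Percentage in `[0, 100]`, or NA when no species survives.
#' @export
pct_species_protected <- function(ranges, pa, subset = c("strict", "all")) {
  subset <- match.arg(subset)
  alive <- Filter(function(r) !r$extinct && any(r$raster), ranges)
  if (!length(alive)) return(NA_real_)
  pam <- pa_subset_mask(pa, subset)
  hit <- vapply(alive, function(r) any(r$raster & pam), TRUE)
  100 * mean(hit)
}

#' Share of species exceeding a coverage benchmark
#'
#' Counts species whose protected range fraction strictly exceeds the
#' benchmark (the 15% / 30% conservation targets).
#'
#' @param coverages Numeric vector of per-species coverage fractions in
#'   `[0, 1]`.
#' @param benchmark Benchmark fraction (0.15 or 0.30 in practice).
#' @return Percentage in `[0, 100]`, or NA for empty input.
#' @export
benchmark_proportion <- function(coverages, benchmark = 0.15) {
  stopifnot(all(coverages >= 0 & coverages <= 1))
  if (!length(coverages)) return(NA_real_)
  100 * mean(coverages > benchmark)
}

#' Rarity-weighted richness
#'
#' Each species scores the inverse of its range size (in cells). In
#' `species_sum` mode the PA aggregate is the sum of scores over species
#' occurring (>= 1 cell) in PAs of the subset. In `cell_sum` mode the
#' per-cell RWR is the sum of scores of species present in the cell and the
#' PA aggregate is the sum over PA cells; summed over *all* cells this mode
#' conserves the species count exactly.
#'
#' @param ranges List of non-empty [binary_range()] objects.
#' @param pa A `pa_mask`.
#' @param subset `"strict"` or `"all"`.
#' @param mode `"species_sum"` or `"cell_sum"`.
#' @return For `species_sum`: a single RWR value. For `cell_sum`: a list
#'   with `raster` (per-cell RWR) and `pa_total`.
#' @export
rarity_weighted_richness <- function(ranges, pa,
                                     subset = c("strict", "all"),
                                     mode = c("species_sum", "cell_sum")) {
  subset <- match.arg(subset)
  mode <- match.arg(mode)
  alive <- Filter(function(r) any(r$raster), ranges)
  pam <- pa_subset_mask(pa, subset)
  if (mode == "species_sum") {
    if (!length(alive)) return(0)
    scores <- vapply(alive, function(r) {
      if (any(r$raster & pam)) 1 / sum(r$raster) else 0
    }, 0)
    return(sum(scores))
  }
  rwr <- matrix(0, nrow(pa$class_raster), ncol(pa$class_raster))
  for (r in alive) rwr <- rwr + r$raster / sum(r$raster)
  list(raster = rwr, pa_total = sum(rwr[pam]))
}

#' Range loss inside and outside PAs
#'
#' Percent of current range cells lost by the future scenario, separately
#' for the protected and unprotected strata. A stratum with zero current
#' cells yields NA for that side (the species is excluded from that
#' stratum's sample downstream).
#'
#' @param current,future [binary_range()] objects for one species
#'   (`future` must be contained in `current`; guaranteed by the
#'   no-dispersal projection).
#' @param pa A `pa_mask`.
#' @param subset `"strict"` or `"all"`.
#' @return Named numeric: `loss_inside`, `loss_outside` (percent, 0-100 or
#'   NA).
#' @export
range_change_inside_outside <- function(current, future, pa,
                                        subset = c("strict", "all")) {
  subset <- match.arg(subset)
  pam <- pa_subset_mask(pa, subset)
  loss_in <- stratum_loss(current$raster, future$raster, pam)
  loss_out <- stratum_loss(current$raster, future$raster, !pam)
  c(loss_inside = loss_in, loss_outside = loss_out)
}

stratum_loss <- function(cur, fut, stratum) {
  n_cur <- sum(cur & stratum)
  if (n_cur == 0) return(NA_real_)
  100 * (n_cur - sum(fut & stratum)) / n_cur
}

#' Build the per-species metrics table
#'
#' One row per species per scenario with range area, protected areas and
#' coverage fractions under both PA subsets, loss percentages (future rows),
#' the extinction flag, and attribute columns consumed by
#' [summarize_group()].
#'
#' @param current,future Named lists of [binary_range()] objects (same
#'   species ids; `future` may be NULL for a current-only table).
#' @param pa A `pa_mask`.
#' @param cell_area_km2 Area of one cell (default 1).
#' @param attributes Optional data.frame with `species_id` plus attribute
#'   columns (e.g. `threatened`).
#' @return A data.frame of class `species_metrics`.
#' @export
species_metrics_table <- function(current, future = NULL, pa,
                                  cell_area_km2 = 1, attributes = NULL) {
  rows <- lapply(names(current), function(id) {
    cur <- current[[id]]
    fut <- if (!is.null(future)) future[[id]] else NULL
    n_cur <- sum(cur$raster)
    strict <- if (n_cur) coverage_fraction(cur, pa, "strict") else NA_real_
    all_f <- if (n_cur) coverage_fraction(cur, pa, "all") else NA_real_
    loss <- if (!is.null(fut))
      range_change_inside_outside(cur, fut, pa, "strict") else
        c(loss_inside = NA_real_, loss_outside = NA_real_)
    data.frame(
      species_id = id,
      range_cells_current = n_cur,
      range_km2_current = n_cur * cell_area_km2,
      range_cells_future = if (!is.null(fut)) sum(fut$raster) else NA_integer_,
      coverage_strict = strict, coverage_all = all_f,
      coverage_strict_future = if (!is.null(fut) && any(fut$raster))
        coverage_fraction(fut, pa, "strict") else NA_real_,
      coverage_all_future = if (!is.null(fut) && any(fut$raster))
        coverage_fraction(fut, pa, "all") else NA_real_,
      loss_inside = loss[["loss_inside"]],
      loss_outside = loss[["loss_outside"]],
      extinct_future = if (!is.null(fut)) fut$extinct else NA)
  })
  out <- do.call(rbind, rows)
  med <- stats::median(out$range_km2_current[out$range_cells_current > 0])
  out$small_range <- out$range_km2_current < med
  if (!is.null(attributes)) out <- merge(out, attributes, by = "species_id",
                                         all.x = TRUE, sort = FALSE)
  class(out) <- c("species_metrics", "data.frame")
  out
}

#' Group-wise summaries of the species metrics table
#'
#' Computes, per group, the medians and quartiles of coverage and loss, the
#' protected percentage and the benchmark proportions — the same formulas as
#' the global summaries. `small_range` groups species below the median range
#' area; `region` assigns a species to every region its range overlaps.
#'
#' @param metrics A [species_metrics_table()].
#' @param group_by `"none"`, `"small_range"`, or the name of a logical
#'   attribute column (e.g. `"threatened"`).
#' @param benchmarks Coverage benchmarks (default `c(0.15, 0.30)`).
#' @return A data.frame, one row per group level.
#' @export
summarize_group <- function(metrics, group_by = "none",
                            benchmarks = c(0.15, 0.30)) {
  groups <- if (group_by == "none") {
    list(all = rep(TRUE, nrow(metrics)))
  } else {
    g <- metrics[[group_by]]
    if (is.null(g)) stop("no attribute column '", group_by, "'")
    stats::setNames(lapply(c(TRUE, FALSE), function(v) !is.na(g) & g == v),
                    paste0(group_by, "=", c("TRUE", "FALSE")))
  }
  rows <- lapply(names(groups), function(nm) {
    m <- metrics[groups[[nm]], , drop = FALSE]
    if (!nrow(m)) {
      return(data.frame(group = nm, n = 0L, median_coverage_strict = NA_real_,
                        q25_coverage = NA_real_, q75_coverage = NA_real_,
                        median_loss_inside = NA_real_,
                        median_loss_outside = NA_real_,
                        pct_over_15 = NA_real_, pct_over_30 = NA_real_))
    }
    cov <- m$coverage_strict[!is.na(m$coverage_strict)]
    q <- if (length(cov)) stats::quantile(cov, c(0.25, 0.5, 0.75), names = FALSE)
      else rep(NA_real_, 3)
    data.frame(group = nm, n = nrow(m),
               median_coverage_strict = q[2],
               q25_coverage = q[1], q75_coverage = q[3],
               median_loss_inside = stats::median(m$loss_inside, na.rm = TRUE),
               median_loss_outside = stats::median(m$loss_outside, na.rm = TRUE),
               pct_over_15 = benchmark_proportion(cov, benchmarks[1]),
               pct_over_30 = benchmark_proportion(cov, benchmarks[2]))
  })
  do.call(rbind, rows)
}
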