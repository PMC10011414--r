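#' @title Conservation-priority and gap mapping
#' @description Cell-level species richness and projected species-loss maps,
#'   decile (quantile) classification for bivariate mapping, identification
#'   of conservation-priority cells (top richness, low projected loss) and
#'   conservation gaps (priority cells outside the PA network), and
#'   country-level gap accounting.
#' @name gap_analysis
NULL

#' Species richness raster
#'
#' @param ranges List of [binary_range()] objects on one grid.
#' @param grid The shared [grid_spec()] (needed when `ranges` may be empty).
#' @return Integer matrix: per-cell count of species present.
#' @export
richness_map <- function(ranges, grid = NULL) {
  if (!length(ranges)) {
    stopifnot(!is.null(grid))
    return(matrix(0L, grid$n_rows, grid$n_cols))
  }
  out <- matrix(0L, nrow(ranges[[1]]$raster), ncol(ranges[[1]]$raster))
  for (r in ranges) out <- out + r$raster
  out
}

#' Projected percent species loss per cell
#'
#' `100 * (richness_current - richness_future) / richness_current`; cells
#' with zero current richness are NA (masked) and never enter quantiles.
#'
#' @param current,future Lists of [binary_range()] objects (future ranges
#'   contained in current ones).
#' @param grid Shared [grid_spec()] fallback for empty lists.
#' @return Numeric matrix of losses in `[0, 100]`, NA where undefined.
#' @export
species_loss_map <- function(current, future, grid = NULL) {
  rc <- richness_map(current, grid)
  rf <- richness_map(future, grid)
  out <- 100 * (rc - rf) / rc
  out[rc == 0] <- NA
  out
}

#' Decile (quantile) classification of a raster
#'
#' Bin `k` holds values in `(q_{(k-1)/n}, q_{k/n}]` with type-1
#' (inverse-empirical-CDF) quantiles, so boundaries are bit-exact across
#' platforms; tied values fall into the lowest admissible bin and the
#' classification is monotone in the value.
#'
#' @param values Numeric matrix (NA = masked).
#' @param n_bins Number of quantile bins (default 10).
#' @return Integer matrix of bin indices 1..n_bins (NA preserved).
#' @export
quantile_classify <- function(values, n_bins = 10) {
  v <- values[!is.na(values)]
  if (length(v) < n_bins) stop("fewer valid cells than bins")
  if (length(unique(v)) == 1) {
    warning("all values identical; single bin")
    out <- values
    out[!is.na(out)] <- 1
    storage.mode(out) <- "integer"
    return(out)
  }
  q <- stats::quantile(v, seq_len(n_bins - 1) / n_bins, type = 1,
                       names = FALSE)
  out <- matrix(NA_integer_, nrow(values), ncol(values))
  ok <- !is.na(values)
  bins <- rep(1L, sum(ok))
  for (k in seq_len(n_bins - 1)) bins <- bins + (values[ok] > q[k])
  out[ok] <- bins
  out
}

#' Identify conservation-priority cells and gaps
#'
#' Priority cells have richness at or above the `(1 - top_frac)` richness
#' quantile AND loss at or below the `bottom_frac` loss quantile, both
#' type-1 quantiles over valid (non-masked) cells. Gaps are priority cells
#' outside the PA network.
#'
#' @param richness Integer richness matrix.
#' @param loss Percent-loss matrix (NA = masked; masked cells never qualify).
#' @param pa A `pa_mask`.
#' @param subset `"strict"` or `"all"`.
#' @param top_frac Top richness fraction (default 0.2).
#' @param bottom_frac Bottom loss fraction (default 0.2).
#' @return A `priority_map`: list with `priority` and `gap` logical
#'   matrices, `richness_bin` and `loss_bin` decile matrices and the two
#'   quantile thresholds.
#' @export
identify_priority_and_gaps <- function(richness, loss, pa,
                                       subset = c("strict", "all"),
                                       top_frac = 0.2, bottom_frac = 0.2) {
  subset <- match.arg(subset)
  valid <- !is.na(loss)
  if (!any(valid)) stop("no valid cells")
  rq <- stats::quantile(richness[valid], 1 - top_frac, type = 1, names = FALSE)
  lq <- stats::quantile(loss[valid], bottom_frac, type = 1, names = FALSE)
  priority <- valid & richness >= rq & loss <= lq
  priority[is.na(priority)] <- FALSE
  gap <- priority & !pa_subset_mask(pa, subset)
  structure(list(priority = priority, gap = gap,
                 richness_bin = quantile_classify_masked(richness, valid),
                 loss_bin = quantile_classify(loss),
                 richness_threshold = rq, loss_threshold = lq),
            class = "priority_map")
}

quantile_classify_masked <- function(values, valid, n_bins = 10) {
  v <- values
  v[!valid] <- NA
  quantile_classify(v, n_bins)
}

#' Country-level conservation-gap accounting
#'
#' @param gap Logical gap matrix (e.g. from
#'   [identify_priority_and_gaps()]).
#' @param countries A `partition_rasters` with `country_id`.
#' @param cell_area_km2 Area of one cell (default 1).
#' @return A data.frame with `country_id`, `gap_area_km2`,
#'   `country_area_km2`, `gap_percent`; gap areas sum to the total gap area.
#' @export
country_gap_summary <- function(gap, countries, cell_area_km2 = 1) {
  cid <- countries$country_id
  stopifnot(all(dim(gap) == dim(cid)))
  ids <- sort(unique(cid[cid > 0]))
  rows <- lapply(ids, function(k) {
    in_c <- cid == k
    n_c <- sum(in_c)
    n_g <- sum(gap & in_c)
    data.frame(country_id = k,
               gap_area_km2 = n_g * cell_area_km2,
               country_area_km2 = n_c * cell_area_km2,
               gap_percent = 100 * n_g / n_c)
  })
  do.call(rbind, rows)
}
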