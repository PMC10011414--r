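#' @title Occurrence cleaning, filtering and thinning
#' @description Record-level quality control for presence-only data: removal
#'   of records far outside the species' known range polygon, blacklist-based
#'   coordinate cleaning, deduplication, spatial thinning to one record per
#'   grid cell, and the minimum-record rule deciding which species can be
#'   modelled. Every removed record keeps a provenance flag with exactly one
#'   removal reason, so kept + removed always equals the input count.
#' @name occurrence_prep
NULL

REMOVAL_REASONS <- c("outside_range_buffer", "blacklisted", "duplicate",
                     "thinned", "outside_grid")

#' Create an occurrence set
#'
#' @param species_id Identifier (recycled).
#' @param x_km,y_km Planar coordinates in km.
#' @param year Observation year (optional).
#' @param source Record source label.
#' @return A data.frame of class `occurrence_set` with provenance columns
#'   `kept` (logical) and `reason` (NA or one removal reason).
#' @export
occurrence_set <- function(species_id, x_km, y_km, year = NA_integer_,
                           source = "unknown") {
  stopifnot(length(x_km) == length(y_km), all(is.finite(x_km)),
            all(is.finite(y_km)))
  df <- data.frame(species_id = rep_len(species_id, length(x_km)),
                   x_km = as.numeric(x_km), y_km = as.numeric(y_km),
                   year = rep_len(year, length(x_km)),
                   source = rep_len(source, length(x_km)),
                   kept = rep(TRUE, length(x_km)),
                   reason = rep(NA_character_, length(x_km)),
                   stringsAsFactors = FALSE)
  class(df) <- c("occurrence_set", "data.frame")
  df
}

as_occurrence_set <- function(df) {
  if (is.null(df$kept)) df$kept <- TRUE
  if (is.null(df$reason)) df$reason <- NA_character_
  class(df) <- c("occurrence_set", "data.frame")
  df
}

mark_removed <- function(occ, idx, reason) {
  stopifnot(reason %in% REMOVAL_REASONS)
  occ$kept[idx] <- FALSE
  occ$reason[idx] <- reason
  occ
}

#' Define a range polygon set for one species
#'
#' @param species_id Identifier.
#' @param polygons A list of two-column matrices (x_km, y_km vertex rings;
#'   closure is implicit).
#' @return A `range_polygon` object.
#' @export
range_polygon <- function(species_id, polygons) {
  stopifnot(is.list(polygons), length(polygons) >= 1)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3, all(is.finite(p)))
    p
  })
  structure(list(species_id = species_id, polygons = polygons),
            class = "range_polygon")
}

# even-odd ray casting
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# min distance from points to a polygon boundary (segments)
dist_to_poly_edges <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

#' Distance from points to a polygon set
#'
#' Euclidean point-to-polygon distance in km; 0 for points inside any
#' polygon.
#'
#' @param x,y Point coordinates (km).
#' @param range A [range_polygon()].
#' @return Numeric vector of distances.
#' @export
dist_to_range <- function(x, y, range) {
  d <- rep(Inf, length(x))
  inside <- rep(FALSE, length(x))
  for (poly in range$polygons) {
    inside <- inside | point_in_poly(x, y, poly)
    d <- pmin(d, dist_to_poly_edges(x, y, poly))
  }
  d[inside] <- 0
  d
}

#' Drop records far outside the species' known range
#'
#' Records farther than `buffer_km` (Euclidean, point-to-polygon) from the
#' nearest range polygon are flagged removed with reason
#' `"outside_range_buffer"`; records at distance exactly `buffer_km` are kept.
#' With no polygon available all records are kept and a warning is emitted.
#'
#' @param occ An [occurrence_set()].
#' @param range A [range_polygon()] or NULL.
#' @param buffer_km Buffer distance in km (default 400).
#' @return The occurrence set with updated provenance flags.
#' @export
filter_by_range_buffer <- function(occ, range = NULL, buffer_km = 400) {
  stopifnot(buffer_km >= 0)
  occ <- as_occurrence_set(occ)
  if (is.null(range)) {
    warning("no range polygon for species ", occ$species_id[1],
            "; all records kept")
    return(occ)
  }
  live <- which(occ$kept)
  if (!length(live)) return(occ)
  d <- dist_to_range(occ$x_km[live], occ$y_km[live], range)
  mark_removed(occ, live[d > buffer_km], "outside_range_buffer")
}

#' Blacklist-based coordinate cleaning and deduplication
#'
#' Removes records within `radius_km` of any blacklisted point (capitals,
#' museums, institution coordinates in real data) and, with `dedup = TRUE`,
#' collapses exact coordinate duplicates to the first record.
#'
#' @param occ An [occurrence_set()].
#' @param blacklist Two-column matrix of blacklisted points (km), or NULL.
#' @param radius_km Removal radius around blacklist points (default 1).
#' @param dedup Collapse exact coordinate duplicates (default TRUE).
#' @return The occurrence set with updated provenance flags.
#' @export
clean_coordinates <- function(occ, blacklist = NULL, radius_km = 1,
                              dedup = TRUE) {
  stopifnot(radius_km >= 0)
  occ <- as_occurrence_set(occ)
  live <- which(occ$kept)
  if (length(live) && !is.null(blacklist) && nrow(blacklist)) {
    bl <- as.matrix(blacklist)
    d2min <- rep(Inf, length(live))
    for (i in seq_len(nrow(bl))) {
      d2 <- (occ$x_km[live] - bl[i, 1])^2 + (occ$y_km[live] - bl[i, 2])^2
      d2min <- pmin(d2min, d2)
    }
    occ <- mark_removed(occ, live[d2min <= radius_km^2], "blacklisted")
    live <- which(occ$kept)
  }
  if (dedup && length(live) > 1) {
    key <- paste(occ$x_km[live], occ$y_km[live])
    occ <- mark_removed(occ, live[duplicated(key)], "duplicate")
  }
  occ
}

#' Thin occurrences to one record per grid cell
#'
#' Retains the first (in input order) kept record in each occupied cell and
#' flags the rest `"thinned"`. Records outside the grid extent are flagged
#' `"outside_grid"` with a warning. Thinning is idempotent.
#'
#' @param occ An [occurrence_set()].
#' @param grid A [grid_spec()] defining the thinning resolution (1 km cells
#'   by default throughout the package).
#' @return The occurrence set with updated provenance flags.
#' @export
thin_occurrences <- function(occ, grid) {
  occ <- as_occurrence_set(occ)
  live <- which(occ$kept)
  if (!length(live)) return(occ)
  rc <- cells_from_xy(grid, occ$x_km[live], occ$y_km[live])
  outside <- is.na(rc$row)
  if (any(outside)) {
    warning(sum(outside), " record(s) outside the grid extent removed")
    occ <- mark_removed(occ, live[outside], "outside_grid")
  }
  inside <- !outside
  cell <- cell_index(grid, rc$row[inside], rc$col[inside])
  occ <- mark_removed(occ, live[inside][duplicated(cell)], "thinned")
  occ
}

#' Select species with enough records to model
#'
#' @param occ_sets A list of occurrence sets (one per species, already
#'   thinned).
#' @param min_records Minimum kept records for inclusion (default 5,
#'   inclusive).
#' @return A data.frame with `species_id`, `n_kept`, `modelable`; the vector
#'   of modelable ids is in attribute-free column form
#'   (`subset(x, modelable)$species_id`).
#' @export
select_modelable_species <- function(occ_sets, min_records = 5) {
  if (!length(occ_sets)) {
    return(data.frame(species_id = character(), n_kept = integer(),
                      modelable = logical()))
  }
  counts <- vapply(occ_sets, function(o) sum(as_occurrence_set(o)$kept), 0L)
  ids <- vapply(occ_sets, function(o) as.character(o$species_id[1]), "")
  data.frame(species_id = ids, n_kept = counts,
             modelable = counts >= min_records, row.names = NULL)
}

#' Per-species cleaning report
#'
#' One row per species with record counts after each cleaning stage, in the
#' pinned filter order: range buffer, blacklist/dedup, thinning,
#' minimum-record rule.
#'
#' @param occ_sets List of fully processed occurrence sets.
#' @param min_records Minimum kept records for the modelable flag.
#' @return A data.frame suitable for writing as the cleaning-report CSV.
#' @export
cleaning_report <- function(occ_sets, min_records = 5) {
  rows <- lapply(occ_sets, function(o) {
    o <- as_occurrence_set(o)
    n_in <- nrow(o)
    n_buf <- n_in - sum(o$reason %in% "outside_range_buffer")
    n_cln <- n_buf - sum(o$reason %in% c("blacklisted", "duplicate"))
    n_thin <- sum(o$kept)
    data.frame(species_id = as.character(o$species_id[1]), n_input = n_in,
               n_after_buffer = n_buf, n_after_clean = n_cln,
               n_after_thin = n_thin, modelable = n_thin >= min_records)
  })
  do.call(rbind, rows)
}

#' Optional year-window filter
#'
#' Real occurrence archives span fixed periods (e.g. 1970-2022); synthetic
#' records carry arbitrary years, so this filter is off by default in the
#' pipeline.
#'
#' @param occ An [occurrence_set()].
#' @param min_year,max_year Inclusive bounds; NA disables a bound.
#' @return The occurrence set with out-of-window kept records dropped
#'   (removed records are retained for provenance).
#' @keywords internal
filter_years <- function(occ, min_year = NA, max_year = NA) {
  occ <- as_occurrence_set(occ)
  keep <- rep(TRUE, nrow(occ))
  if (!is.na(min_year)) keep <- keep & (!is.na(occ$year) & occ$year >= min_year)
  if (!is.na(max_year)) keep <- keep & (!is.na(occ$year) & occ$year <= max_year)
  occ[keep | !occ$kept, , drop = FALSE]
}
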