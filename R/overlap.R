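# The computational core: species-map x site overlap areas on the shared
# equal-area frame. A suitable cell contributes its full area to a polygon
# iff its centre lies inside (cell-centre zonal rule — the unbiased
# estimator standard in zonal statistics; no sub-cell apportionment).

geom_rings <- function(geom) {
  if (inherits(geom, "kba_union")) return(geom$rings)
  if (is.matrix(geom)) return(list(geom))
  if (is.list(geom) && !is.null(geom$rings)) return(geom$rings)
  if (is.list(geom)) return(lapply(geom, as_ring))
  stop("unsupported geometry", call. = FALSE)
}

#' Suitable-habitat area of a species map inside a polygon
#'
#' Counts the suitable cells whose centres fall inside the polygon and
#' multiplies by the cell area. Map and polygon must share the analysis
#' frame.
#'
#' @param map An `aoh_map`.
#' @param geom A ring matrix, list of rings, site geometry or `kba_union`.
#' @return Overlap area in km^2.
#' @export
mask_area <- function(map, geom) {
  stopifnot(inherits(map, "aoh_map"))
  gframe <- attr(geom, "frame")
  if (!is.null(gframe)) stop_if_frame_mismatch(map, geom)
  frame <- attr(map, "frame")
  if (!length(map$cells)) return(0)
  pts <- cell_centers(frame, map$cells)
  sum(points_in_polygon(pts, geom_rings(geom))) * cell_area(frame)
}

#' Combination count of the full species-map x site matrix
#'
#' Closed-form size of the cross-product data matrix after dropping
#' unrepairable site geometries: `n_maps * (n_sites_raw - n_dropped)`.
#' Zero-overlap pairs count; they are simply stored implicitly.
#'
#' @param n_maps Number of species maps.
#' @param n_sites_raw Number of site polygons before repair.
#' @param n_dropped Number of sites dropped by [repair_geometries()].
#' @export
count_combinations <- function(n_maps, n_sites_raw, n_dropped = 0) {
  stopifnot(n_maps >= 0, n_sites_raw >= n_dropped, n_dropped >= 0)
  as.numeric(n_maps) * (as.numeric(n_sites_raw) - as.numeric(n_dropped))
}

# Logical membership over all grid cells for each retained site geometry;
# cached per site so the matrix build touches each cell-centre once per site.
site_cell_masks <- function(site_set, frame) {
  pts <- cell_centers(frame)
  lapply(site_set$geoms, function(g) {
    bb <- bbox_of(g)
    cand <- which(pts[, 1] >= bb["xmin"] & pts[, 1] <= bb["xmax"] &
                    pts[, 2] >= bb["ymin"] & pts[, 2] <= bb["ymax"])
    inside <- logical(nrow(pts))
    if (length(cand)) {
      inside[cand] <- points_in_polygon(pts[cand, , drop = FALSE], g)
    }
    inside
  })
}

#' Build the species-map x site overlap matrix
#'
#' Computes, for every (map, retained site) pair, the suitable-habitat area
#' of the map inside the site and the percentage of the map's habitat that
#' area represents. The full cross-product is accounted for (the
#' `n_combinations` attribute); zero-overlap records are stored implicitly
#' and only pairs with positive overlap materialise as rows, which is what
#' the downstream analyses consume.
#'
#' @param maps List of `aoh_map` objects (or a `species_set`).
#' @param site_set A repaired `site_set`.
#' @return A data frame of class `overlap_matrix` with columns `map_id`,
#'   `site_id`, `area_km2`, `pct_of_map`, `site_extent_km2`, `region`,
#'   `iba`; attributes `n_maps`, `n_sites`, `n_combinations`.
#' @export
build_overlap_matrix <- function(maps, site_set) {
  if (inherits(maps, "species_set")) maps <- maps$maps
  stopifnot(inherits(site_set, "site_set"))
  ids <- vapply(maps, `[[`, character(1), "map_id")
  if (anyDuplicated(ids)) stop("duplicate map ids", call. = FALSE)
  frame <- attr(site_set, "frame")
  if (is.null(frame) && length(maps)) frame <- attr(maps[[1]], "frame")
  for (m in maps) stop_if_frame_mismatch(m, frame)

  masks <- site_cell_masks(site_set, frame)
  ca <- cell_area(frame)
  rec <- site_set$records
  rows <- vector("list", length(maps))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    if (!length(m$cells)) next
    ov <- vapply(masks, function(msk) sum(msk[m$cells]), numeric(1))
    hit <- which(ov > 0)
    if (!length(hit)) next
    sid <- names(masks)[hit]
    ri <- match(sid, rec$site_id)
    rows[[k]] <- data.frame(
      map_id = m$map_id, site_id = sid,
      area_km2 = ov[hit] * ca,
      pct_of_map = 100 * ov[hit] * ca / m$area_km2,
      site_extent_km2 = rec$extent_km2[ri],
      region = rec$region[ri], iba = rec$iba[ri],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(map_id = character(), site_id = character(),
                      area_km2 = numeric(), pct_of_map = numeric(),
                      site_extent_km2 = numeric(), region = character(),
                      iba = logical())
  }
  structure(out, class = c("overlap_matrix", "data.frame"),
            n_maps = length(maps), n_sites = nrow(rec),
            n_combinations = count_combinations(length(maps), nrow(rec) +
                                                  nrow(site_set$dropped),
                                                nrow(site_set$dropped)))
}

#' Per-map representation summary against the dissolved site union
#'
#' The headline per-map statistic: percent of the map's suitable habitat
#' inside the dissolved union of all retained sites. Because the union is
#' dissolved first, the percentage is guaranteed to lie in [0, 100] — summed
#' per-site percentages can exceed 100 wherever sites overlap, which is
#' exactly why the dissolve step exists. Maps with zero suitable area are
#' flagged unusable and get `NA` percentages.
#'
#' @param maps List of `aoh_map` objects (or a `species_set`).
#' @param union A `kba_union` from [dissolve_sites()].
#' @param pa_union Optional second `kba_union` of protected-area polygons;
#'   adds a `pct_protected` column computed with the same rule.
#' @return A data frame of class `map_summary`: `map_id`, `species_id`,
#'   `season`, `area_km2`, `area_in_sites_km2`, `pct_in_sites`, `usable`,
#'   and optionally `pct_protected`.
#' @export
summarize_maps <- function(maps, union, pa_union = NULL) {
  if (inherits(maps, "species_set")) maps <- maps$maps
  stopifnot(inherits(union, "kba_union"))
  frame <- attr(union, "frame")
  union_mask <- rings_cell_mask(union$rings, frame)
  pa_mask <- if (!is.null(pa_union)) rings_cell_mask(pa_union$rings, frame)
  ca <- cell_area(frame)
  rows <- lapply(maps, function(m) {
    stop_if_frame_mismatch(m, frame)
    usable <- length(m$cells) > 0
    a_in <- if (usable) sum(union_mask[m$cells]) * ca else NA_real_
    out <- data.frame(
      map_id = m$map_id, species_id = m$species_id, season = m$season,
      area_km2 = m$area_km2, area_in_sites_km2 = a_in,
      pct_in_sites = if (usable) 100 * a_in / m$area_km2 else NA_real_,
      usable = usable, stringsAsFactors = FALSE)
    if (!is.null(pa_mask)) {
      out$pct_protected <- if (usable) {
        100 * sum(pa_mask[m$cells]) / length(m$cells)
      } else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  n_un <- sum(!out$usable)
  if (n_un > 0) {
    warning(sprintf("%d zero-area map(s) flagged unusable and excluded from percentages",
                    n_un), call. = FALSE)
  }
  structure(out, class = c("map_summary", "data.frame"), frame = frame)
}

rings_cell_mask <- function(rings, frame) {
  pts <- cell_centers(frame)
  inside <- logical(nrow(pts))
  for (r in rings) {
    bb <- bbox_of(r)
    cand <- which(!inside & pts[, 1] >= bb["xmin"] & pts[, 1] <= bb["xmax"] &
                    pts[, 2] >= bb["ymin"] & pts[, 2] <= bb["ymax"])
    if (length(cand)) {
      inside[cand] <- points_in_ring(pts[cand, 1], pts[cand, 2], r)
    }
  }
  inside
}
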