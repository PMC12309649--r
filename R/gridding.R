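# Coarse equal-area gridding of richness and gap metrics (the map-figure
# machinery) plus the overlap histogram. A species is present in a coarse
# cell when any suitable fine-cell centre of any of its seasonal maps falls
# in it — the same cell-centre rule as the overlap engine.

coarse_index <- function(frame, cells, grid_km) {
  xy <- cell_centers(frame, cells)
  gx <- floor((xy[, 1] - frame$origin[1]) / grid_km) + 1L
  gy <- floor((xy[, 2] - frame$origin[2]) / grid_km) + 1L
  ngx <- ceiling(frame$cols * frame$cell_km / grid_km)
  unique((gy - 1L) * ngx + gx)
}

#' Species richness on a coarse equal-area grid
#'
#' @param maps List of `aoh_map` objects (or a `species_set`); seasonal maps
#'   of one species are pooled, so each species counts once per cell.
#' @param grid_km Coarse cell size in km (e.g. 100).
#' @return Data frame of class `grid_summary` with `gx`, `gy` (coarse cell
#'   indices, x east, y north), `x_km`, `y_km` (cell centres) and
#'   `richness`; attribute `grid_km`.
#' @export
stack_to_grid <- function(maps, grid_km) {
  if (inherits(maps, "species_set")) maps <- maps$maps
  stopifnot(length(maps) > 0)
  frame <- attr(maps[[1]], "frame")
  for (m in maps) stop_if_frame_mismatch(m, frame)
  cover <- species_coarse_cells(maps, frame, grid_km)
  tab <- table(unlist(cover, use.names = FALSE))
  grid_df(as.integer(names(tab)), as.integer(tab), frame, grid_km, "richness")
}

species_coarse_cells <- function(maps, frame, grid_km) {
  sp <- vapply(maps, `[[`, character(1), "species_id")
  out <- list()
  for (k in seq_along(maps)) {
    if (!length(maps[[k]]$cells)) next
    idx <- coarse_index(frame, maps[[k]]$cells, grid_km)
    out[[sp[k]]] <- unique(c(out[[sp[k]]], idx))
  }
  out
}

grid_df <- function(cell_id, value, frame, grid_km, name) {
  ngx <- ceiling(frame$cols * frame$cell_km / grid_km)
  gx <- ((cell_id - 1L) %% ngx) + 1L
  gy <- ((cell_id - 1L) %/% ngx) + 1L
  out <- data.frame(gx = gx, gy = gy,
                    x_km = frame$origin[1] + (gx - 0.5) * grid_km,
                    y_km = frame$origin[2] + (gy - 0.5) * grid_km)
  out[[name]] <- value
  structure(out, class = c("grid_summary", "data.frame"),
            grid_km = grid_km, frame = frame)
}

#' Gap grids: richness, under-represented counts, proportions, triggers
#'
#' Combines the richness grid with species-level flags into the per-cell
#' gap metrics: number of flagged (under-represented) species, their
#' proportion of richness, and the number of trigger species. Species in
#' `maps` but absent from `rollup` are excluded with a warning.
#'
#' @param maps List of `aoh_map` objects or a `species_set`.
#' @param rollup Species rollup from [rollup_species()] (`species_id`,
#'   `flagged`).
#' @param species Attribute table with `species_id` and `trigger`.
#' @param grid_km Coarse cell size in km.
#' @return `grid_summary` data frame with `richness`, `n_under`,
#'   `prop_under`, `n_trigger` per occupied cell.
#' @export
gap_grids <- function(maps, rollup, species, grid_km) {
  if (inherits(maps, "species_set")) {
    if (missing(species)) species <- maps$species
    maps <- maps$maps
  }
  frame <- attr(maps[[1]], "frame")
  cover <- species_coarse_cells(maps, frame, grid_km)
  known <- names(cover) %in% rollup$species_id
  if (any(!known)) {
    warning(sprintf("%d species missing from the rollup were excluded",
                    sum(!known)), call. = FALSE)
    cover <- cover[known]
  }
  flag <- rollup$flagged[match(names(cover), rollup$species_id)]
  trig <- species$trigger[match(names(cover), species$species_id)]

  rich_tab <- table(unlist(cover, use.names = FALSE))
  ids <- as.integer(names(rich_tab))
  count_in <- function(sel) {
    t2 <- table(factor(unlist(cover[sel], use.names = FALSE), levels = ids))
    as.integer(t2)
  }
  out <- grid_df(ids, as.integer(rich_tab), frame, grid_km, "richness")
  out$n_under <- count_in(flag %in% TRUE)
  out$prop_under <- out$n_under / out$richness
  out$n_trigger <- count_in(trig %in% TRUE)
  out
}

#' Area-weighted centroids of the worst-covered maps
#'
#' One point per qualifying map — no site overlap at all, or an
#' endangered/critically endangered species below the very-under threshold
#' — at the mean coordinate of its suitable cells. Empty maps are skipped
#' with a warning.
#'
#' @param maps List of `aoh_map` objects or a `species_set`.
#' @param summary A `map_summary`.
#' @param species Attribute table with `species_id`, `redlist`.
#' @param very_under Strict threshold (default 5).
#' @return Data frame `map_id`, `species_id`, `season`, `x_km`, `y_km`,
#'   `class`, `redlist`.
#' @export
centroid_points <- function(maps, summary, species, very_under = 5) {
  if (inherits(maps, "species_set")) {
    if (missing(species)) species <- maps$species
    maps <- maps$maps
  }
  rl <- species$redlist[match(summary$species_id, species$species_id)]
  qual <- summary$usable &
    (summary$pct_in_sites == 0 |
       (rl %in% c("EN", "CR") & summary$pct_in_sites < very_under))
  ids <- summary$map_id[qual]
  rows <- list()
  skipped <- 0L
  for (m in maps) {
    if (!m$map_id %in% ids) next
    if (!length(m$cells)) { skipped <- skipped + 1L; next }
    xy <- cell_centers(attr(m, "frame"), m$cells)
    i <- match(m$map_id, summary$map_id)
    rows[[length(rows) + 1L]] <- data.frame(
      map_id = m$map_id, species_id = m$species_id, season = m$season,
      x_km = mean(xy[, 1]), y_km = mean(xy[, 2]),
      class = as.character(classify_overlap(summary$pct_in_sites[i])),
      redlist = species$redlist[match(m$species_id, species$species_id)],
      stringsAsFactors = FALSE)
  }
  if (skipped) warning(sprintf("%d empty map(s) skipped", skipped), call. = FALSE)
  if (!length(rows)) {
    return(data.frame(map_id = character(), species_id = character(),
                      season = character(), x_km = numeric(), y_km = numeric(),
                      class = character(), redlist = character()))
  }
  do.call(rbind, rows)
}

#' Histogram of per-map overlap percentages
#'
#' Fixed-width bins over [0, 100], left-closed right-open, with the final
#' bin closed at 100 so counts conserve the number of maps.
#'
#' @param pct Percentages in [0, 100] (`NA` dropped).
#' @param width Bin width in percentage points (default 5; must divide 100).
#' @return Data frame `bin_lo`, `bin_hi`, `count`.
#' @export
overlap_histogram <- function(pct, width = 5) {
  stopifnot(width > 0, isTRUE(all.equal(100 %% width, 0)))
  pct <- pct[!is.na(pct)]
  if (any(pct < 0 | pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  breaks <- seq(0, 100, by = width)
  bin <- findInterval(pct, breaks, rightmost.closed = TRUE)
  data.frame(bin_lo = breaks[-length(breaks)],
             bin_hi = breaks[-1],
             count = tabulate(bin, nbins = length(breaks) - 1L))
}
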