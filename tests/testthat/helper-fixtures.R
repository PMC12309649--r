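# Shared fixtures and independent oracles for the suite.

# a small scenario that keeps generator runs fast
small_config <- function(...) {
  scenario_config(n_species = 40, rows = 60, cols = 60, n_sites = 25,
                  range_meanlog = log(60), seed = 42, ...)
}

# build an aoh_map directly from cell indices
make_map <- function(cells, frame, map_id = "m1", species_id = "sp1",
                     season = "resident") {
  kbagap:::new_aoh_map(map_id, species_id, season, cells, frame)
}

# raw site record around a list of rings
make_site <- function(rings, id = "s1", region = "northwest") {
  kbagap:::new_raw_site(id, id, region, rings)
}

raw_collection <- function(sites, frame = NULL) {
  structure(sites, class = "raw_sites", frame = frame)
}

bowtie_ring <- function() cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))

# unrepairable by the single-crossing policy: pentagram has five crossings
star_ring <- function(cx = 0, cy = 0, r = 1) kbagap:::pentagram_ring(cx, cy, r)

# independent point-in-polygon oracle (different algorithm, different code)
oracle_inside <- function(pts, ring) {
  ring <- rbind(ring, ring[1, , drop = FALSE])
  mgcv::in.out(ring, pts)
}

# exhaustive mask-area oracle: per-cell point-in-polygon via mgcv
oracle_mask_area <- function(map, rings, frame) {
  if (is.matrix(rings)) rings <- list(rings)
  pts <- cell_centers(frame, map$cells)
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) inside <- inside | oracle_inside(pts, r)
  sum(inside) * cell_area(frame)
}

# fine-grid rasterisation oracle for union areas
oracle_union_area <- function(rings, step, bbox = NULL) {
  if (is.matrix(rings)) rings <- list(rings)
  if (is.null(bbox)) bbox <- kbagap:::bbox_of(rings)
  xs <- seq(bbox["xmin"] + step / 2, bbox["xmax"], by = step)
  ys <- seq(bbox["ymin"] + step / 2, bbox["ymax"], by = step)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) inside <- inside | oracle_inside(pts, r)
  sum(inside) * step^2
}

random_rects <- function(n, extent = 100) {
  lapply(seq_len(n), function(i) {
    x <- sort(runif(2, 0, extent)); y <- sort(runif(2, 0, extent))
    rect_ring(x[1], y[1], x[2], y[2])
  })
}
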