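# Plain-text interchange: species rasters as ESRI ASCII grids, site
# polygons as WKT-in-CSV, attribute tables as CSV, and a JSON scenario
# manifest recording config + seed for reproducibility.

#' Write a species map as an ESRI ASCII grid
#'
#' Single-band text raster: 1 = suitable habitat, 0 = unsuitable. The
#' header records the frame (cell size in km, lower-left corner), so the
#' raster and the vector layers share one coordinate system.
#'
#' @param map An `aoh_map`.
#' @param path Output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(map, path) {
  frame <- attr(map, "frame")
  m <- matrix(0L, frame$rows, frame$cols)
  m[map$cells] <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", frame$cols),
    sprintf("nrows %d", frame$rows),
    sprintf("xllcorner %.10g", frame$origin[1]),
    sprintf("yllcorner %.10g", frame$origin[2]),
    sprintf("cellsize %.10g", frame$cell_km),
    "NODATA_value -9999"), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid back into an `aoh_map`
#'
#' @param path File written by [write_ascii_grid()].
#' @param map_id,species_id,season Identity of the map (defaults derive
#'   from the file name).
#' @export
read_ascii_grid <- function(path, map_id = basename(path),
                            species_id = map_id, season = "resident") {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  val <- function(k) as.numeric(kv[match(k, tolower(kv[, 1])), 2])
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  frame <- grid_frame(nr, nc, val("cellsize"),
                      origin = c(val("xllcorner"), val("yllcorner")))
  m <- as.matrix(utils::read.table(path, skip = 6L))
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  new_aoh_map(map_id, species_id, season, which(m == 1L), frame)
}

ring_to_wkt <- function(rings) {
  one <- function(r) {
    r <- rbind(r, r[1, , drop = FALSE])
    sprintf("((%s))", paste(sprintf("%.10g %.10g", r[, 1], r[, 2]),
                            collapse = ", "))
  }
  if (length(rings) == 1L) {
    sprintf("POLYGON %s", one(rings[[1]]))
  } else {
    sprintf("MULTIPOLYGON (%s)",
            paste(vapply(rings, one, character(1)), collapse = ", "))
  }
}

wkt_to_rings <- function(wkt) {
  body <- regmatches(wkt, gregexpr("\\(\\([^()]*\\)\\)", wkt))[[1]]
  lapply(body, function(b) {
    b <- gsub("[()]", "", b)
    xy <- do.call(rbind, lapply(strsplit(strsplit(b, ",")[[1]], "\\s+"),
                                function(p) as.numeric(p[p != ""])))
    as_ring(xy)
  })
}

#' Write site polygons as WKT-in-CSV
#'
#' One row per site: `site_id`, `name`, `region`, `iba`, `wkt`. Round-trips
#' through [read_sites_wkt()].
#'
#' @param sites A `raw_sites` collection or `site_set`.
#' @param path Output CSV path.
#' @export
write_sites_wkt <- function(sites, path) {
  if (inherits(sites, "site_set")) {
    df <- sites$records
    df$wkt <- vapply(sites$geoms[df$site_id], ring_to_wkt, character(1))
    df$extent_km2 <- NULL
  } else {
    df <- do.call(rbind, lapply(sites, function(s) data.frame(
      site_id = s$site_id, name = s$name, region = s$region,
      iba = s$iba, wkt = ring_to_wkt(s$rings), stringsAsFactors = FALSE)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read site polygons from WKT-in-CSV
#'
#' @param path CSV written by [write_sites_wkt()].
#' @param frame Optional [grid_frame()] to attach.
#' @return A `raw_sites` collection.
#' @export
read_sites_wkt <- function(path, frame = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sites <- lapply(seq_len(nrow(df)), function(i) {
    new_raw_site(df$site_id[i], df$name[i], df$region[i],
                 wkt_to_rings(df$wkt[i]), iba = df$iba[i])
  })
  structure(sites, class = "raw_sites", frame = frame)
}

#' Write the scenario manifest (config + seed) as JSON
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @param extra Optional named list of extra fields (e.g. achieved
#'   coverage).
#' @export
write_manifest <- function(config, path, extra = list()) {
  payload <- c(unclass(config), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write the standard gap-analysis output tables
#'
#' Emits the per-map summary, species rollup, overlap matrix, null-model
#' results, gap grids, centroids, histogram and dropped-site ledger as CSV
#' files under `dir`.
#'
#' @param results A [run_gap_analysis()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_gap_outputs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    files <<- c(files, p)
  }
  emit(results$summary, "map_summary.csv")
  emit(results$rollup, "species_rollup.csv")
  emit(results$matrix, "overlap_matrix.csv")
  emit(results$site_set$dropped, "dropped_sites.csv")
  for (nm in names(results$bias)) {
    emit(results$bias[[nm]], sprintf("bias_%s.csv", nm))
  }
  emit(results$grids, "gap_grids.csv")
  emit(results$centroids, "gap_centroids.csv")
  emit(results$histogram, "overlap_histogram.csv")
  invisible(files)
}
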