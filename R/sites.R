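# Synthetic site polygons (the KBA-network stand-in): rectangles of
# log-normal size whose dissolved union is calibrated to cover a target
# fraction of the terrestrial cells, with optional injection of invalid
# self-intersecting geometries and targeted placement on threatened-species
# richness.

new_raw_site <- function(site_id, name, region, rings, iba = TRUE) {
  list(site_id = site_id, name = name, region = region,
       rings = rings, iba = iba)
}

# five-pointed star traced in pentagram order: five proper self-crossings,
# unrepairable under the single-crossing split policy
pentagram_ring <- function(cx, cy, radius) {
  ang <- pi / 2 + 2 * pi * (0:4) / 5
  pent <- cbind(cx + radius * cos(ang), cy + radius * sin(ang))
  pent[c(1, 3, 5, 2, 4), ]
}

#' Generate synthetic site polygons
#'
#' Produces `n_sites` raw site polygons in the landscape's frame:
#' `n_sites - n_invalid_sites` valid axis-aligned rectangles whose
#' *dissolved union* covers `coverage` of the terrestrial cells to within
#' 0.5 percentage points, plus exactly `n_invalid_sites` self-intersecting
#' (pentagram) polygons that fail the validity check and — having several
#' crossings — resist the one-shot repair, mirroring networks in which a
#' handful of digitised boundaries are irreparably broken.
#'
#' Coverage is calibrated by bisection on a single global size factor
#' (site centres fixed), measured as the fraction of terrestrial cell
#' centres inside the union — the same cell-centre rule the overlap engine
#' uses, so the achieved coverage and downstream percent-in-union agree by
#' construction. At least one pair of valid sites is guaranteed to overlap.
#'
#' Under `site_mode = "targeted"` site centres are sampled from terrestrial
#' cells with probability proportional to local threatened-species richness
#' (plus a small floor so all land is possible), emulating a network built
#' around threatened species; `species` must then be supplied.
#'
#' @param landscape A [generate_landscape()] result.
#' @param config The matching [scenario_config()].
#' @param species A [generate_species_maps()] result; required for
#'   targeted placement.
#' @return A list of class `raw_sites` of per-site records
#'   (`site_id`, `name`, `region`, `rings`, `iba`), with the landscape's
#'   frame attached as the `frame` attribute and the achieved coverage as
#'   attribute `coverage`.
#' @export
generate_sites <- function(landscape, config = landscape$config, species = NULL) {
  stopifnot(inherits(landscape, "kba_landscape"))
  if (config$site_mode == "targeted" && is.null(species)) {
    stop("targeted placement needs the species maps and attributes",
         call. = FALSE)
  }
  n_valid <- config$n_sites - config$n_invalid_sites
  if (n_valid < 1L) stop("no valid sites requested", call. = FALSE)

  with_seed(config$seed + 2L, {
    frame <- landscape$frame
    land <- which(landscape$mask)
    if (!length(land)) stop("landscape has no terrestrial cells", call. = FALSE)
    land_xy <- cell_centers(frame, land)
    ext_x <- c(frame$origin[1], frame$origin[1] + frame$cols * frame$cell_km)
    ext_y <- c(frame$origin[2], frame$origin[2] + frame$rows * frame$cell_km)

    # site centres: targeted mode emulates sites being identified *for*
    # trigger species — each site draws a trigger species (threatened
    # species up-weighted, as sites qualify most easily under threatened-
    # species criteria) and lands uniformly within that species' range.
    # One site inside a vast range contributes a negligible share of it,
    # so wide-ranging species gain little per site, exactly as in real
    # networks; small-range threatened species gain a lot.
    if (config$site_mode == "targeted") {
      att <- species$species
      trig_sp <- att$species_id[att$trigger]
      if (length(trig_sp)) {
        gamma <- if (!is.null(config$threatened_site_weight)) {
          config$threatened_site_weight
        } else 5
        w_sp <- 1 + gamma * att$threatened[match(trig_sp, att$species_id)]
        sp_cells <- lapply(trig_sp, function(id) {
          unique(unlist(lapply(species$maps[vapply(species$maps, `[[`, "",
                                                   "species_id") == id],
                               `[[`, "cells")))
        })
        pick <- sample.int(length(trig_sp), config$n_sites, replace = TRUE,
                           prob = w_sp)
        ctr_cells <- vapply(pick, function(k) {
          cs <- sp_cells[[k]]
          cs[sample.int(length(cs), 1L)]
        }, integer(1))
      } else {
        ctr_cells <- land[sample.int(length(land), config$n_sites,
                                     replace = TRUE)]
      }
    } else {
      ctr_cells <- land[sample.int(length(land), config$n_sites,
                                   replace = TRUE)]
    }
    ctr <- cell_centers(frame, ctr_cells)

    # base half-sizes (km), log-normal with mild aspect variation
    base <- stats::rlnorm(config$n_sites, log(3 * frame$cell_km), 0.6)
    aspect <- stats::runif(config$n_sites, 0.6, 1.6)
    # guarantee at least one overlapping pair of valid sites: co-centred
    # rectangles of different size always intersect
    if (n_valid >= 2L) ctr[2, ] <- ctr[1, ]

    valid_idx <- seq_len(n_valid)
    make_rects <- function(scale) {
      lapply(valid_idx, function(i) {
        w2 <- scale * base[i] * aspect[i]
        h2 <- scale * base[i] / aspect[i]
        rect_ring(max(ext_x[1], ctr[i, 1] - w2), max(ext_y[1], ctr[i, 2] - h2),
                  min(ext_x[2], ctr[i, 1] + w2), min(ext_y[2], ctr[i, 2] + h2))
      })
    }
    cov_of <- function(rects) {
      inside <- logical(length(land))
      for (r in rects) {
        todo <- !inside
        inside[todo] <- land_xy[todo, 1] >= r[1, 1] & land_xy[todo, 1] <= r[2, 1] &
          land_xy[todo, 2] >= r[1, 2] & land_xy[todo, 2] <= r[3, 2]
      }
      mean(inside)
    }

    lo <- 1e-3; hi <- max(diff(ext_x), diff(ext_y)) / min(base)
    if (cov_of(make_rects(hi)) < config$coverage - 0.005) {
      stop("target coverage unreachable with the requested sites", call. = FALSE)
    }
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      cv <- cov_of(make_rects(mid))
      if (abs(cv - config$coverage) <= 0.004) break
      if (cv < config$coverage) lo <- mid else hi <- mid
    }
    rects <- make_rects(mid)
    achieved <- cov_of(rects)
    if (abs(achieved - config$coverage) > 0.005) {
      stop(sprintf("coverage calibration failed: achieved %.4f vs target %.4f",
                   achieved, config$coverage), call. = FALSE)
    }

    region_of <- function(x, y) {
      paste0(ifelse(y > mean(ext_y), "north", "south"),
             ifelse(x > mean(ext_x), "east", "west"))
    }

    sites <- vector("list", config$n_sites)
    for (i in valid_idx) {
      sites[[i]] <- new_raw_site(
        sprintf("site%04d", i), sprintf("Site %d", i),
        region_of(ctr[i, 1], ctr[i, 2]), list(rects[[i]]),
        iba = stats::runif(1) < 0.7)
    }
    if (config$n_invalid_sites > 0L) {
      for (k in seq_len(config$n_invalid_sites)) {
        i <- n_valid + k
        ring <- pentagram_ring(ctr[i, 1], ctr[i, 2], mid * base[i])
        sites[[i]] <- new_raw_site(
          sprintf("site%04d", i), sprintf("Site %d", i),
          region_of(ctr[i, 1], ctr[i, 2]), list(ring),
          iba = stats::runif(1) < 0.7)
      }
    }
    sites <- sites[sample.int(length(sites))]  # invalid ones sit "among" the rest

    structure(sites, class = "raw_sites", frame = frame, coverage = achieved)
  })
}

#' @export
print.raw_sites <- function(x, ...) {
  cat(sprintf("<raw_sites> %d site polygons, achieved land coverage %.2f%%\n",
              length(x), 100 * attr(x, "coverage")))
  invisible(x)
}
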