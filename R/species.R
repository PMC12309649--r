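# Synthetic species maps: compact binary habitat patches grown by random
# accretion, plus the species attribute table (taxonomy, Red List category,
# habitat importance, trigger status, recognition year).

new_aoh_map <- function(map_id, species_id, season, cells, frame) {
  structure(list(map_id = map_id, species_id = species_id, season = season,
                 cells = as.integer(cells),
                 area_km2 = length(cells) * cell_area(frame)),
            class = "aoh_map", frame = frame)
}

#' @export
print.aoh_map <- function(x, ...) {
  cat(sprintf("<aoh_map> %s (%s, %s): %d cells, %g km^2\n",
              x$map_id, x$species_id, x$season, length(x$cells), x$area_km2))
  invisible(x)
}

#' Generate synthetic species maps and their attribute table
#'
#' Each species receives one binary suitable-habitat map (residents) or two
#' (migratory species: breeding and nonbreeding), grown as a compact patch
#' of terrestrial cells by seeded random accretion from a start cell —
#' mimicking the contiguity of real Area-of-Habitat maps. Range sizes (in
#' cells) are log-normal; threatened species' ranges are shifted smaller by
#' `threatened_range_shift`; island species are confined to one reserved
#' island component. Ranges larger than the reachable terrestrial area are
#' clipped with a warning.
#'
#' The attribute table links geography to the grouping variables of the
#' bias analyses: each species' "major" habitat is the modal habitat code
#' of its patch, a configurable fraction of species have exactly one major
#' habitat (the single-important-habitat construct), threatened species
#' avoid the `widespread_habitat` region, and trigger status (a site has
#' been identified for the species) is more likely for threatened species.
#'
#' @param landscape A [generate_landscape()] result.
#' @param config The same [scenario_config()] used for the landscape.
#' @return A list of class `species_set` with
#'   * `maps`: list of `aoh_map` objects (one per species-season);
#'   * `species`: data frame with one row per species (`species_id`,
#'     `order_name`, `family`, `redlist`, `threatened`, `trigger`,
#'     `migratory`, `island`, `year_recognized`, `major_habitat`,
#'     `n_major_habitats`, `single_major_habitat`);
#'   * `habitats`: long data frame (`species_id`, `code`, `importance`).
#' @export
generate_species_maps <- function(landscape, config = landscape$config) {
  stopifnot(inherits(landscape, "kba_landscape"))
  with_seed(config$seed + 1L, {
    frame <- landscape$frame
    nr <- frame$rows; nc <- frame$cols
    mask_cells <- which(landscape$mask)
    n_sp <- config$n_species
    ids <- sprintf("sp%04d", seq_len(n_sp))

    # taxonomy: families nested in orders, uneven sizes
    ord_names <- sprintf("order%02d", seq_len(config$n_orders))
    fam_names <- sprintf("family%03d", seq_len(config$n_families))
    fam_order <- sample(ord_names, config$n_families, replace = TRUE,
                        prob = 1 / seq_len(config$n_orders))
    sp_family <- sample(fam_names, n_sp, replace = TRUE,
                        prob = 1 / sqrt(seq_len(config$n_families)))
    sp_order <- fam_order[match(sp_family, fam_names)]

    redlist <- sample(names(config$redlist_probs), n_sp, replace = TRUE,
                      prob = config$redlist_probs)
    threatened <- redlist %in% c("VU", "EN", "CR")
    n_mig <- round(config$migratory_frac * n_sp)
    migratory <- seq_len(n_sp) %in% sample.int(n_sp, n_mig)
    n_island_sp <- round(config$island_frac * n_sp)
    island_sp <- seq_len(n_sp) %in% sample.int(n_sp, n_island_sp)

    island_ids <- setdiff(unique(landscape$island_id[!is.na(landscape$island_id)]), 0L)
    if (!length(island_ids)) island_sp[] <- FALSE

    # start-cell weights: richness clusters on the landscape's core
    # gradient; threatened species additionally avoid the widespread
    # habitat (its specialists are the common, wide-ranging ones)
    # threatened species never specialise on the widespread habitat (as
    # with boreal forest, whose habitat specialists are all non-threatened)
    hab_at <- landscape$habitat[mask_cells]
    clus <- if (!is.null(config$clustering)) config$clustering else 0
    w_base <- exp(clus * landscape$core[mask_cells])
    w_threat <- w_base * !(hab_at %in% config$widespread_habitat)
    on_main <- landscape$island_id[mask_cells] == 0L
    mainland <- mask_cells[on_main]
    w_base_main <- w_base[on_main]
    w_threat_main <- w_threat[on_main]

    maps <- list()
    sp_rows <- vector("list", n_sp)
    hab_rows <- list()
    clipped <- 0L

    for (i in seq_len(n_sp)) {
      meanlog <- config$range_meanlog +
        if (threatened[i]) config$threatened_range_shift else 0
      seasons <- if (migratory[i]) c("breeding", "nonbreeding") else "resident"
      sp_cells <- integer(0)
      for (season in seasons) {
        if (island_sp[i]) {
          isl <- island_ids[(i %% length(island_ids)) + 1L]
          allowed <- which(!is.na(landscape$island_id) & landscape$island_id == isl)
          start <- allowed[sample.int(length(allowed), 1L)]
        } else {
          allowed <- mask_cells
          pool <- if (length(mainland)) mainland else mask_cells
          wts <- if (!length(mainland)) NULL
            else if (threatened[i]) w_threat_main else w_base_main
          start <- pool[sample.int(length(pool), 1L, prob = wts)]
        }
        # widespread-habitat species are wide-ranging (think boreal birds):
        # their log range size is shifted up by one unit
        ml <- meanlog +
          (landscape$habitat[start] %in% config$widespread_habitat)
        size <- max(1L, round(stats::rlnorm(1, ml, config$range_sdlog)))
        if (size > length(allowed)) {
          # island confinement is by design, not worth a warning
          if (!island_sp[i]) clipped <- clipped + 1L
          size <- length(allowed)
        }
        cells <- grow_patch(nr, nc, allowed, start, size)
        map_id <- sprintf("%s_%s", ids[i], substr(season, 1, 1))
        maps[[length(maps) + 1L]] <-
          new_aoh_map(map_id, ids[i], season, cells, frame)
        sp_cells <- union(sp_cells, cells)
      }

      # habitat composition of the pooled range
      tab <- sort(table(landscape$habitat[sp_cells]), decreasing = TRUE)
      major <- names(tab)[1]
      n_major <- 1L
      if (stats::runif(1) > config$single_major_frac) {
        second <- if (length(tab) >= 2) names(tab)[2] else
          sample(setdiff(habitat_codes()$code, major), 1L)
        hab_rows[[length(hab_rows) + 1L]] <-
          data.frame(species_id = ids[i], code = second, importance = "major")
        n_major <- 2L
      }
      hab_rows[[length(hab_rows) + 1L]] <-
        data.frame(species_id = ids[i], code = major, importance = "major")
      if (length(tab) > n_major) {
        extra <- utils::head(setdiff(names(tab), major), 2L)
        for (e in extra) {
          hab_rows[[length(hab_rows) + 1L]] <-
            data.frame(species_id = ids[i], code = e, importance = "suitable")
        }
      }

      trig_p <- if (threatened[i]) config$trigger_p_threatened else
        config$trigger_p_other
      sp_rows[[i]] <- data.frame(
        species_id = ids[i], order_name = sp_order[i], family = sp_family[i],
        redlist = redlist[i], threatened = threatened[i],
        trigger = stats::runif(1) < trig_p,
        migratory = migratory[i], island = island_sp[i],
        year_recognized = sample(1965:2024, 1L),
        major_habitat = major, n_major_habitats = n_major,
        stringsAsFactors = FALSE)
    }
    if (clipped > 0L) {
      warning(sprintf("%d requested ranges exceeded the reachable area and were clipped",
                      clipped), call. = FALSE)
    }

    species <- do.call(rbind, sp_rows)
    species$single_major_habitat <- species$n_major_habitats == 1L
    habitats <- do.call(rbind, hab_rows)
    structure(list(maps = maps, species = species, habitats = habitats),
              class = "species_set", frame = frame)
  })
}

#' @export
print.species_set <- function(x, ...) {
  cat(sprintf("<species_set> %d species, %d maps (%d migratory species)\n",
              nrow(x$species), length(x$maps), sum(x$species$migratory)))
  invisible(x)
}

# Random-accretion patch growth restricted to `allowed` cells. Keeps the
# patch connected and compact-ish; frontier managed as an integer vector
# with a logical membership mask for O(1) dedup.
grow_patch <- function(nr, nc, allowed, start, size) {
  ncell <- nr * nc
  ok <- logical(ncell); ok[allowed] <- TRUE
  stopifnot(ok[start])
  in_patch <- logical(ncell)
  in_patch[start] <- TRUE
  cells <- integer(size); cells[1L] <- start; got <- 1L
  frontier <- setdiff(cell_neighbors(nr, nc, start), start)
  frontier <- frontier[ok[frontier]]
  in_front <- logical(ncell); in_front[frontier] <- TRUE
  while (got < size && length(frontier)) {
    j <- sample.int(length(frontier), 1L)
    cell <- frontier[j]
    frontier[j] <- frontier[length(frontier)]
    frontier <- frontier[-length(frontier)]
    in_front[cell] <- FALSE
    if (in_patch[cell]) next
    got <- got + 1L
    cells[got] <- cell
    in_patch[cell] <- TRUE
    nb <- cell_neighbors(nr, nc, cell)
    nb <- nb[ok[nb] & !in_patch[nb] & !in_front[nb]]
    if (length(nb)) {
      frontier <- c(frontier, nb)
      in_front[nb] <- TRUE
    }
  }
  sort(cells[seq_len(got)])
}
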