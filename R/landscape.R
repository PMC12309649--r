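# Synthetic landscape generation: terrestrial mask + habitat mosaic on an
# abstract equal-area grid. Stands in for the Behrmann-projected rasters the
# real analysis runs on; the downstream method only needs equal cell areas.

# k-pass moving-average smoothing of a matrix (reflecting edges), used to
# turn white noise into a spatially autocorrelated field.
smooth2d <- function(m, window = 5L, passes = 3L) {
  half <- window %/% 2L
  pad_idx <- function(n) c(rev(seq_len(half)), seq_len(n), n - seq_len(half) + 1L)
  for (p in seq_len(passes)) {
    mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m)), drop = FALSE]
    cs <- apply(mp, 2, function(v) {
      c0 <- cumsum(v)
      (c0[window:length(v)] - c(0, c0)[seq_len(length(v) - window + 1L)]) / window
    })
    cs <- t(apply(cs, 1, function(v) {
      c0 <- cumsum(v)
      (c0[window:length(v)] - c(0, c0)[seq_len(length(v) - window + 1L)]) / window
    }))
    m <- cs
  }
  m
}

#' Generate a synthetic equal-area landscape
#'
#' Builds the world every other generator draws on: a binary terrestrial
#' mask whose land fraction hits `terr_frac` exactly (to the nearest cell),
#' a set of small disconnected "island" components reserved for
#' island-endemic species, and a habitat mosaic of spatially autocorrelated
#' patches labelled with two-level habitat codes.
#'
#' The mainland is carved from a smoothed Gaussian random field by taking
#' the top cells, which yields blocky connected land masses rather than
#' i.i.d. salt-and-pepper; islands are placed in open water with a one-cell
#' sea buffer so they stay disconnected.
#'
#' @param config A [scenario_config()].
#' @return An object of class `kba_landscape`: list with `frame`
#'   ([grid_frame()]), `mask` (logical rows x cols matrix, TRUE = land),
#'   `habitat` (character matrix of level-2 codes, NA over water),
#'   `island_id` (integer matrix, 0 = mainland, k = island k, NA = water),
#'   `core` (standardised smooth gradient over land on which species
#'   richness clusters), and the generating `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    nr <- config$rows; nc <- config$cols
    ncell <- nr * nc
    n_land <- max(1L, round(config$terr_frac * ncell))
    frame <- grid_frame(nr, nc, config$cell_km)

    island_id <- matrix(NA_integer_, nr, nc)
    reserved <- matrix(FALSE, nr, nc)  # islands + their sea buffer
    n_isl <- if (config$terr_frac < 1) config$n_islands else 0L
    isl_cells <- integer(0)
    k <- 0L
    attempts <- 0L
    while (k < n_isl && attempts < 200L) {
      attempts <- attempts + 1L
      r0 <- sample.int(nr, 1); c0 <- sample.int(nc, 1)
      size <- sample.int(config$island_size, 1)
      # grow a tiny blob; require its buffered footprint free of other land
      blob <- grow_blob(nr, nc, r0, c0, size)
      buf <- dilate_cells(nr, nc, blob)
      if (any(reserved[buf])) next
      if (length(isl_cells) + length(blob) > n_land %/% 4L) break
      k <- k + 1L
      island_id[blob] <- k
      reserved[buf] <- TRUE
      isl_cells <- c(isl_cells, blob)
    }

    n_main <- n_land - length(isl_cells)
    field <- smooth2d(matrix(stats::rnorm(ncell), nr, nc))
    field[reserved] <- -Inf
    ord <- order(field, decreasing = TRUE)
    main_cells <- ord[seq_len(max(0L, n_main))]

    mask <- matrix(FALSE, nr, nc)
    mask[main_cells] <- TRUE
    island_id[main_cells] <- 0L
    mask[isl_cells] <- TRUE

    # "core" gradient: the same smooth field, standardised over land. High
    # values mark continental interiors; species richness clusters there
    # (real richness is strongly spatially structured, not uniform).
    core <- matrix(NA_real_, nr, nc)
    fl <- field[mask]
    fl[!is.finite(fl)] <- min(fl[is.finite(fl)])
    core[mask] <- as.numeric(scale(fl))

    # habitat mosaic: nearest-seed (Voronoi) patches over land
    hc <- habitat_codes()
    n_seed <- min(config$n_habitat_patches, sum(mask))
    seeds <- sample(which(mask), n_seed)
    seed_xy <- cell_centers(frame, seeds)
    # every habitat class occurs somewhere in the world (one patch each),
    # remaining patches drawn at random
    seed_code <- if (n_seed >= nrow(hc)) {
      sample(c(hc$code, sample(hc$code, n_seed - nrow(hc), replace = TRUE)))
    } else {
      sample(hc$code, n_seed)
    }
    # the widespread habitat occupies the species-poor periphery (boreal
    # forest sits at high latitudes, away from richness cores) and is the
    # largest single habitat (at least 3 patches): swap its patches onto
    # the seeds with the lowest core values
    wh <- config$widespread_habitat
    n_wide <- min(max(sum(seed_code == wh), 3L), n_seed)
    if (n_wide > 0) {
      periph <- order(core[seeds])[seq_len(n_wide)]
      have <- which(seed_code == wh)
      give <- setdiff(have, periph)   # wh patches not yet peripheral
      take <- setdiff(periph, have)   # peripheral seeds lacking wh
      seed_code[give] <- seed_code[take][seq_along(give)]
      seed_code[take] <- wh
    }
    land <- which(mask)
    land_xy <- cell_centers(frame, land)
    nearest <- max.col(-outer(rowSums(land_xy^2), rep(1, n_seed)) -
                         outer(rep(1, nrow(land_xy)), rowSums(seed_xy^2)) +
                         2 * land_xy %*% t(seed_xy), ties.method = "first")
    habitat <- matrix(NA_character_, nr, nc)
    habitat[land] <- seed_code[nearest]

    structure(list(frame = frame, mask = mask, habitat = habitat,
                   island_id = island_id, core = core, config = config),
              class = "kba_landscape")
  })
}

#' @export
print.kba_landscape <- function(x, ...) {
  n_isl <- max(c(0L, x$island_id[!is.na(x$island_id)]))
  cat(sprintf("<kba_landscape> %dx%d cells of %g km, %d terrestrial (%.1f%%), %d islands\n",
              x$frame$rows, x$frame$cols, x$frame$cell_km, sum(x$mask),
              100 * mean(x$mask), n_isl))
  invisible(x)
}

# 4-neighbourhood of cell indices within an nr x nc grid
cell_neighbors <- function(nr, nc, cells) {
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  out <- c(ifelse(r > 1L, cells - 1L, NA),
           ifelse(r < nr, cells + 1L, NA),
           ifelse(c > 1L, cells - nr, NA),
           ifelse(c < nc, cells + nr, NA))
  unique(out[!is.na(out)])
}

# cells plus their 8-neighbour ring
dilate_cells <- function(nr, nc, cells) {
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- c(out, (cc[ok] - 1L) * nr + rr[ok])
  }
  unique(out)
}

# grow a connected blob of `size` cells from (r0, c0) by random accretion
grow_blob <- function(nr, nc, r0, c0, size) {
  start <- (c0 - 1L) * nr + r0
  cells <- start
  while (length(cells) < size) {
    cand <- setdiff(cell_neighbors(nr, nc, cells), cells)
    if (!length(cand)) break
    cells <- c(cells, cand[sample.int(length(cand), 1L)])
  }
  cells
}
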