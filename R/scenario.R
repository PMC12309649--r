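#' Two-level habitat code table
#'
#' The fixed habitat taxonomy used by the synthetic generator and the
#' habitat-bias null models: level-2 codes nested in broad level-1 classes
#' (forest, savanna, shrubland, grassland, inland wetlands, desert), in the
#' style of the IUCN habitat classification scheme.
#'
#' @return A data frame with columns `code`, `name`, `level1_code`,
#'   `level1_name`.
#' @export
habitat_codes <- function() {
  path <- system.file("extdata", "habitat_codes.csv", package = "kbagap")
  utils::read.csv(path, colClasses = "character")
}

#' Red List categories used throughout the package
#' @export
redlist_categories <- function() c("LC", "NT", "VU", "EN", "CR", "DD")

#' Configuration of a synthetic study scenario
#'
#' Bundles every knob of the synthetic world: the landscape, the species
#' pool, and the site network. Defaults describe a mid-sized world that the
#' test-suite and examples share: a 120 x 120 grid of 10-km cells with 55%
#' land, 150 species of which 15% are migratory (two seasonal maps each),
#' and 200 sites whose dissolved union covers 8.01% of the land — the
#' published terrestrial coverage of the global KBA network, which anchors
#' the 8% representation threshold.
#'
#' Range sizes are drawn log-normally on the cell-count scale. The real
#' global range-size distribution is not quantitatively described in the
#' source datasets we emulate, so `range_meanlog`/`range_sdlog` are
#' placeholders chosen to give a right-skewed distribution with many small
#' ranges and a long tail; treat them as such.
#'
#' @param n_species Number of species.
#' @param migratory_frac Fraction of species with separate breeding and
#'   nonbreeding maps (each contributes 2 maps; residents contribute 1).
#' @param range_meanlog,range_sdlog Log-scale mean and sd of range size in
#'   cells.
#' @param threatened_range_shift Added to `range_meanlog` for threatened
#'   (VU/EN/CR) species; negative values make threatened ranges smaller,
#'   as in real data.
#' @param island_frac Fraction of species confined to small disconnected
#'   terrestrial patches ("island" species).
#' @param n_islands,island_size Number of reserved island components and the
#'   maximum cells per island.
#' @param rows,cols,cell_km,terr_frac Landscape grid dimensions, cell size
#'   (km) and terrestrial fraction of the grid.
#' @param n_habitat_patches Number of habitat patches (Voronoi seeds) that
#'   tile the land with spatially autocorrelated habitat classes.
#' @param n_sites Number of site polygons (including any injected invalid
#'   ones).
#' @param coverage Target fraction of terrestrial cells covered by the
#'   dissolved union of valid sites (tolerance +/- 0.005).
#' @param site_mode `"random"` (site centres uniform over land, independent
#'   of the species) or `"targeted"` (each site is identified *for* a
#'   trigger species: a trigger species is drawn — threatened species
#'   up-weighted by `threatened_site_weight` — and the site centre lands
#'   uniformly inside that species' range, emulating site networks built
#'   species by species under threatened-species criteria).
#' @param threatened_site_weight Relative weight of a threatened trigger
#'   species when drawing the species a targeted site is identified for
#'   (non-threatened trigger species have weight 1).
#' @param clustering Strength of spatial richness clustering: species start
#'   cells are drawn with weight `exp(clustering * core)` where `core` is
#'   the landscape's standardised interior gradient. 0 = uniform placement.
#' @param n_invalid_sites Number of injected self-intersecting (and, under
#'   the default repair policy, unrepairable) site polygons.
#' @param redlist_probs Named marginal probabilities over
#'   [redlist_categories()]; must sum to 1.
#' @param single_major_frac Fraction of species with exactly one habitat of
#'   "major" importance (the unit of the habitat-bias analysis).
#' @param trigger_p_threatened,trigger_p_other Probability that a threatened
#'   / non-threatened species has at least one site identified for it
#'   (trigger species).
#' @param widespread_habitat Level-2 habitat code whose region threatened
#'   species tend to avoid; under targeted site placement its (mostly
#'   least-concern, wide-ranging) specialists end up under-covered, the
#'   synthetic analogue of an extensive low-endemism biome.
#' @param n_orders,n_families Sizes of the taxonomic group schema.
#' @param seed Integer RNG seed; identical seed + config reproduce the
#'   scenario exactly.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 150,
                            migratory_frac = 0.15,
                            range_meanlog = log(150),
                            range_sdlog = 1.0,
                            threatened_range_shift = -1.5,
                            island_frac = 0.10,
                            n_islands = 8,
                            island_size = 4,
                            rows = 120, cols = 120,
                            cell_km = 10,
                            terr_frac = 0.55,
                            n_habitat_patches = 25,
                            n_sites = 200,
                            coverage = 0.0801,
                            site_mode = c("random", "targeted"),
                            threatened_site_weight = 5,
                            clustering = 1.0,
                            n_invalid_sites = 0,
                            redlist_probs = c(LC = 0.55, NT = 0.10, VU = 0.15,
                                              EN = 0.10, CR = 0.05, DD = 0.05),
                            single_major_frac = 0.8,
                            trigger_p_threatened = 0.9,
                            trigger_p_other = 0.35,
                            widespread_habitat = "1.1",
                            n_orders = 12,
                            n_families = 40,
                            seed = 1L) {
  site_mode <- match.arg(site_mode)
  if (rows < 10 || cols < 10) {
    stop("landscape must be at least 10 x 10 cells", call. = FALSE)
  }
  if (cell_km <= 0) stop("`cell_km` must be positive", call. = FALSE)
  if (!(coverage > 0 && coverage < 1)) {
    stop("`coverage` must lie in (0, 1)", call. = FALSE)
  }
  if (!(terr_frac > 0 && terr_frac <= 1)) {
    stop("`terr_frac` must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(redlist_probs) - 1) > 1e-8 || any(redlist_probs < 0)) {
    stop("`redlist_probs` must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(redlist_probs), redlist_categories())) {
    stop("`redlist_probs` must be named by ",
         paste(redlist_categories(), collapse = ", "), call. = FALSE)
  }
  if (n_invalid_sites < 0 || n_invalid_sites >= n_sites) {
    stop("`n_invalid_sites` must be in [0, n_sites)", call. = FALSE)
  }
  if (migratory_frac < 0 || migratory_frac > 1 ||
      island_frac < 0 || island_frac > 1 ||
      single_major_frac < 0 || single_major_frac > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d species (%.0f%% migratory), %dx%d grid of %g km,\n",
    x$n_species, 100 * x$migratory_frac, x$rows, x$cols, x$cell_km))
  cat(sprintf("  %d sites targeting %.2f%% land coverage (%s placement), seed %d\n",
              x$n_sites, 100 * x$coverage, x$site_mode, x$seed))
  invisible(x)
}
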