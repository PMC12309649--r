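# Synthetic-data generators: determinism, configured marginals, coverage.

test_that("landscape hits the terrestrial fraction and is deterministic", {
  cfg <- scenario_config(n_species = 5, rows = 50, cols = 50, terr_frac = 1.0,
                         seed = 1)
  L <- generate_landscape(cfg)
  expect_equal(sum(L$mask), 2500)

  cfg2 <- scenario_config(n_species = 5, rows = 100, cols = 100,
                          terr_frac = 0.6, seed = 3)
  L2 <- generate_landscape(cfg2)
  expect_lt(abs(sum(L2$mask) - 6000), 60)  # within 1%

  L2b <- generate_landscape(cfg2)
  expect_identical(L2$mask, L2b$mask)
  expect_identical(L2$habitat, L2b$habitat)
})

test_that("landscape invariants hold: habitat over land only, islands disconnected", {
  L <- generate_landscape(small_config())
  expect_true(all(!is.na(L$habitat[L$mask])))
  expect_true(all(is.na(L$habitat[!L$mask])))
  # every island cell's 8-neighbourhood contains no mainland cell
  isl <- which(!is.na(L$island_id) & L$island_id > 0)
  for (cell in isl) {
    nb <- kbagap:::dilate_cells(L$frame$rows, L$frame$cols, cell)
    ids <- L$island_id[nb]
    expect_false(any(ids == 0L, na.rm = TRUE))
  }
})

test_that("landscape rejects degenerate dimensions", {
  expect_error(scenario_config(rows = 5, cols = 50), "10 x 10")
  expect_error(scenario_config(cell_km = 0), "cell_km")
  expect_error(scenario_config(coverage = 1.2), "coverage")
})

test_that("species counts follow the resident/migratory accounting", {
  cfg <- scenario_config(n_species = 15, migratory_frac = 1 / 3,
                         rows = 60, cols = 60, island_frac = 0, seed = 5)
  L <- generate_landscape(cfg)
  sp <- generate_species_maps(L, cfg)
  expect_equal(nrow(sp$species), 15)
  expect_length(sp$maps, 10 + 2 * 5)  # 10 residents + 2 maps x 5 migrants
  expect_equal(sum(sp$species$migratory), 5)
  # (species, season) unique
  key <- paste(vapply(sp$maps, `[[`, "", "species_id"),
               vapply(sp$maps, `[[`, "", "season"))
  expect_false(anyDuplicated(key) > 0)
})

test_that("species maps are terrestrial, connected patches of the drawn size", {
  cfg <- small_config()
  L <- generate_landscape(cfg)
  sp <- generate_species_maps(L, cfg)
  land <- which(L$mask)
  for (m in sp$maps[1:10]) {
    expect_true(all(m$cells %in% land))
    expect_equal(m$area_km2, length(m$cells) * cell_area(L$frame))
    # connectivity: flood fill from the first cell reaches all cells
    reach <- m$cells[1]
    repeat {
      grown <- union(reach, intersect(
        kbagap:::cell_neighbors(L$frame$rows, L$frame$cols, reach), m$cells))
      if (length(grown) == length(reach)) break
      reach <- grown
    }
    expect_setequal(reach, m$cells)
  }
})

test_that("forcing one-cell ranges yields maps of exactly one cell area", {
  cfg <- scenario_config(n_species = 12, rows = 60, cols = 60,
                         range_meanlog = log(1), range_sdlog = 0,
                         threatened_range_shift = 0, island_frac = 0, seed = 8)
  L <- generate_landscape(cfg)
  sp <- generate_species_maps(L, cfg)
  areas <- vapply(sp$maps, `[[`, numeric(1), "area_km2")
  expect_true(all(areas == cell_area(L$frame)))
})

test_that("island species stay confined to a single island component", {
  cfg <- scenario_config(n_species = 50, rows = 80, cols = 80,
                         island_frac = 0.2, seed = 9)
  L <- generate_landscape(cfg)
  sp <- generate_species_maps(L, cfg)
  isl_sp <- sp$species$species_id[sp$species$island]
  expect_equal(length(isl_sp), 10)
  for (m in sp$maps) {
    if (!m$species_id %in% isl_sp) next
    ids <- unique(L$island_id[m$cells])
    expect_length(ids, 1)
    expect_gt(ids, 0)
    expect_lte(length(m$cells), cfg$island_size)
  }
})

test_that("generators reproduce exactly under the same seed", {
  cfg <- small_config()
  L <- generate_landscape(cfg)
  a <- generate_species_maps(L, cfg)
  b <- generate_species_maps(L, cfg)
  expect_identical(a, b)
  sa <- generate_sites(L, cfg)
  sb <- generate_sites(L, cfg)
  expect_identical(sa, sb)
})

test_that("Red List marginals and range-size location are recovered", {
  probs <- c(LC = 0.5, NT = 0.1, VU = 0.2, EN = 0.1, CR = 0.05, DD = 0.05)
  cfg <- scenario_config(n_species = 1200, rows = 110, cols = 110,
                         migratory_frac = 0, island_frac = 0,
                         range_meanlog = log(30), range_sdlog = 0.7,
                         threatened_range_shift = 0,
                         redlist_probs = probs, seed = 12)
  L <- generate_landscape(cfg)
  sp <- generate_species_maps(L, cfg)
  n <- nrow(sp$species)
  for (cat in names(probs)) {
    p_hat <- mean(sp$species$redlist == cat)
    se <- sqrt(probs[[cat]] * (1 - probs[[cat]]) / n)
    expect_lt(abs(p_hat - probs[[cat]]), 3 * se + 1e-9)
  }
  sizes <- vapply(sp$maps, function(m) length(m$cells), numeric(1))
  # clipping and the 1-cell floor perturb the tails only
  lm_hat <- mean(log(sizes))
  expect_lt(abs(lm_hat - log(30)), 3 * 0.7 / sqrt(length(sizes)) + 0.05)
})

test_that("site union coverage lands inside the stated tolerance", {
  cfg <- scenario_config(n_species = 10, rows = 100, cols = 100,
                         n_sites = 40, coverage = 0.0801, seed = 21)
  L <- generate_landscape(cfg)
  st <- generate_sites(L, cfg)
  ss <- repair_geometries(st)
  u <- dissolve_sites(ss)
  land <- which(L$mask)
  pts <- cell_centers(L$frame, land)
  covered <- mean(points_in_polygon(pts, u$rings))
  expect_gte(covered, 0.0801 - 0.005)
  expect_lte(covered, 0.0801 + 0.005)
  expect_equal(attr(st, "coverage"), covered)
})

test_that("invalid-geometry injection count is exact and sites overlap somewhere", {
  cfg <- scenario_config(n_species = 10, rows = 60, cols = 60,
                         n_sites = 30, n_invalid_sites = 9, seed = 23)
  L <- generate_landscape(cfg)
  st <- generate_sites(L, cfg)
  n_bad <- sum(!vapply(st, function(s) {
    all(vapply(s$rings, ring_is_valid, logical(1)))
  }, logical(1)))
  expect_equal(n_bad, 9)
  ss <- repair_geometries(st)
  expect_lt(dissolve_sites(ss)$area_km2,
            sum(ss$records$extent_km2))  # some pair overlaps
})

test_that("unreachable site configurations raise parameter errors", {
  cfg <- small_config()
  L <- generate_landscape(cfg)
  cfg_bad <- cfg
  cfg_bad$n_sites <- 1L
  cfg_bad$n_invalid_sites <- 1L
  expect_error(generate_sites(L, cfg_bad), "valid sites")
  cfg_t <- cfg
  cfg_t$site_mode <- "targeted"
  expect_error(generate_sites(L, cfg_t), "species")
})
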