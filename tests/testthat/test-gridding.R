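# Coarse gap grids, centroids, and the overlap histogram.

frame20 <- grid_frame(20, 20, 1)

test_that("richness grids count each species once per coarse cell", {
  # one species covering one fine cell -> exactly one coarse cell at 1
  m1 <- make_map(1, frame20, "a_r", "a")
  g <- stack_to_grid(list(m1), grid_km = 5)
  expect_equal(nrow(g), 1)
  expect_equal(g$richness, 1)

  # two species with identical footprints -> every covered cell at 2
  cells <- c(1, 25, 380)
  g2 <- stack_to_grid(list(make_map(cells, frame20, "a_r", "a"),
                           make_map(cells, frame20, "b_r", "b")), grid_km = 5)
  expect_true(all(g2$richness == 2))

  # seasonal maps of one species pool into a single presence
  g3 <- stack_to_grid(list(make_map(cells, frame20, "c_b", "c", "breeding"),
                           make_map(cells, frame20, "c_n", "c", "nonbreeding")),
                      grid_km = 5)
  expect_true(all(g3$richness == 1))
})

test_that("richness equals the exhaustive per-species intersection oracle", {
  set.seed(77)
  maps <- lapply(1:30, function(i) {
    make_map(sample.int(400, sample(5:60, 1)), frame20,
             sprintf("m%d", i), sprintf("sp%d", i))
  })
  grid_km <- 4
  g <- stack_to_grid(maps, grid_km)
  # oracle: test every (species, coarse cell) pair by brute force
  ngx <- 5
  for (row in sample.int(nrow(g), 10)) {
    gx <- g$gx[row]; gy <- g$gy[row]
    n <- 0
    for (m in maps) {
      xy <- cell_centers(frame20, m$cells)
      hit <- any(xy[, 1] > (gx - 1) * grid_km & xy[, 1] < gx * grid_km &
                   xy[, 2] > (gy - 1) * grid_km & xy[, 2] < gy * grid_km)
      n <- n + hit
    }
    expect_equal(g$richness[row], n)
  }
  # conservation: richness grid is the sum of per-species indicator grids
  total <- sum(vapply(maps, function(m) {
    length(kbagap:::coarse_index(frame20, m$cells, grid_km))
  }, numeric(1)))
  expect_equal(sum(g$richness), total)
})

test_that("gap grids combine flags into counts and proportions", {
  cells <- 1:40
  maps <- list(make_map(cells, frame20, "a_r", "a"),
               make_map(cells, frame20, "b_r", "b"))
  species <- data.frame(species_id = c("a", "b"), trigger = c(TRUE, FALSE))
  rollup <- data.frame(species_id = c("a", "b"), flagged = c(TRUE, TRUE))
  g <- gap_grids(maps, rollup, species, grid_km = 5)
  expect_true(all(g$prop_under == 1))
  expect_true(all(g$n_trigger == 1))

  rollup$flagged <- FALSE
  g0 <- gap_grids(maps, rollup, species, grid_km = 5)
  expect_true(all(g0$n_under == 0))
  expect_true(all(g0$prop_under == 0))

  rollup$flagged <- c(TRUE, FALSE)
  gh <- gap_grids(maps, rollup, species, grid_km = 5)
  expect_true(all(gh$prop_under == 0.5))
  expect_true(all(gh$n_under <= gh$richness))

  # species missing from the rollup are excluded with a warning
  expect_warning(gap_grids(maps, rollup[1, ], species, grid_km = 5), "excluded")
})

test_that("centroids are suitable-cell means and translate with the frame", {
  # single cell: centroid is that cell's centre
  m <- make_map(20, frame20, "a_r", "a")  # row 20, col 1 -> (0.5, 0.5)
  s <- data.frame(map_id = "a_r", species_id = "a", season = "resident",
                  area_km2 = 1, area_in_sites_km2 = 0, pct_in_sites = 0,
                  usable = TRUE)
  species <- data.frame(species_id = "a", redlist = "LC")
  pts <- centroid_points(list(m), s, species)
  expect_equal(c(pts$x_km, pts$y_km), c(0.5, 0.5))
  expect_equal(pts$class, "no_overlap")

  # L-shaped 3-cell map at unit cells (0,0),(1,0),(0,1): mean of centres
  mL <- make_map(c(20, 40, 19), frame20, "b_r", "b")
  sL <- within(s, {map_id <- "b_r"; species_id <- "b"})
  ptsL <- centroid_points(list(mL), sL, data.frame(species_id = "b", redlist = "EN"))
  expect_equal(c(ptsL$x_km, ptsL$y_km), c(mean(c(0.5, 1.5, 0.5)),
                                          mean(c(0.5, 0.5, 1.5))))

  # symmetric two-cell map centred on the shared corner
  m2 <- make_map(c(20, 39), frame20, "c_r", "c")  # (0.5,0.5) and (1.5,1.5)
  s2 <- within(s, {map_id <- "c_r"; species_id <- "c"})
  pts2 <- centroid_points(list(m2), s2, data.frame(species_id = "c", redlist = "CR"))
  expect_equal(c(pts2$x_km, pts2$y_km), c(1, 1))

  # frame translation moves centroids by exactly the same offset
  frame_t <- grid_frame(20, 20, 1, origin = c(100, -50))
  mt <- make_map(c(20, 39), frame_t, "c_r", "c")
  ptst <- centroid_points(list(mt), s2, data.frame(species_id = "c", redlist = "CR"))
  expect_equal(c(ptst$x_km, ptst$y_km), c(1 + 100, 1 - 50))
})

test_that("centroid layer keeps only qualifying maps and skips empty ones", {
  maps <- list(make_map(1, frame20, "ok_r", "ok"),
               make_map(integer(0), frame20, "void_r", "void"))
  s <- data.frame(map_id = c("ok_r", "void_r"), species_id = c("ok", "void"),
                  season = "resident", area_km2 = c(1, 0),
                  area_in_sites_km2 = 0, pct_in_sites = c(0, NA),
                  usable = c(TRUE, FALSE))
  species <- data.frame(species_id = c("ok", "void"), redlist = "LC")
  pts <- centroid_points(maps, s, species)
  expect_equal(pts$map_id, "ok_r")
  # an EN species at 4.9% qualifies, at 5% it does not
  s$pct_in_sites <- c(4.9, NA)
  species$redlist <- "EN"
  expect_equal(nrow(centroid_points(maps, s, species)), 1)
  s$pct_in_sites <- c(5, NA)
  expect_equal(nrow(centroid_points(maps, s, species)), 0)
})

test_that("overlap histogram bins are left-closed with a closed last bin", {
  h <- overlap_histogram(c(0, 0, 100), width = 10)
  expect_equal(h$count[1], 2)
  expect_equal(h$count[nrow(h)], 1)
  expect_equal(sum(h$count), 3)

  h2 <- overlap_histogram(rep(42, 7), width = 5)
  expect_equal(h2$count[h2$bin_lo == 40], 7)
  expect_equal(sum(h2$count), 7)

  set.seed(5)
  pct <- runif(500, 0, 100)
  h3 <- overlap_histogram(pct, width = 5)
  expect_equal(sum(h3$count), 500)
  # boundary goes to the right bin: 5 lands in [5,10)
  h4 <- overlap_histogram(c(5), width = 5)
  expect_equal(h4$count[h4$bin_lo == 5], 1)
})
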