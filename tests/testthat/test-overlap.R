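# Overlap engine: mask areas, the cross-product matrix, per-map summaries.

frame9 <- grid_frame(3, 3, 1)  # 3x3 grid of 1-km cells, centres at 0.5..2.5

test_that("mask_area counts suitable cell centres inside the polygon", {
  # 4 suitable cells in the bottom-left 2x2 block (rows 2:3, cols 1:2)
  m <- make_map(c(2, 3, 5, 6), frame9)
  # polygon covering the two left-column centres only
  expect_equal(mask_area(m, rect_ring(0, 0, 1, 2)), 2.0)
  # polygon disjoint from the map footprint
  expect_equal(mask_area(m, rect_ring(10, 10, 12, 12)), 0.0)
  # polygon covering everything
  expect_equal(mask_area(m, rect_ring(0, 0, 3, 3)), 4.0)
})

test_that("mask_area refuses mismatched frames", {
  m <- make_map(1, frame9)
  ring <- rect_ring(0, 0, 1, 1)
  geom <- structure(list(rings = list(ring)), frame = grid_frame(5, 5, 2))
  expect_error(mask_area(m, geom), "frame")
})

test_that("mask_area equals the exhaustive oracle on random map/polygon pairs", {
  skip_if_not_installed("mgcv")
  set.seed(33)
  frame <- grid_frame(40, 40, 1)
  for (rep in 1:25) {
    cells <- sample.int(1600, 200)
    m <- make_map(cells, frame)
    n <- sample(3:8, 1)
    ang <- sort(runif(n, 0, 2 * pi))
    rad <- runif(n, 3, 18)
    ring <- cbind(20 + rad * cos(ang), 20 + rad * sin(ang))
    expect_equal(mask_area(m, ring), oracle_mask_area(m, ring, frame))
  }
})

test_that("matrix covers the cross-product and flags duplicate map ids", {
  ss <- repair_geometries(raw_collection(list(
    make_site(list(rect_ring(0, 0, 1, 3)), id = "left"),
    make_site(list(rect_ring(2, 0, 3, 3)), id = "right"))))
  attr(ss, "frame") <- frame9
  maps <- list(make_map(1:3, frame9, "m1"),      # left column
               make_map(7:9, frame9, "m2"),      # right column
               make_map(c(1, 9), frame9, "m3"))  # one cell each side
  mat <- build_overlap_matrix(maps, ss)
  expect_equal(attr(mat, "n_combinations"), 6)
  expect_equal(attr(mat, "n_maps"), 3)
  expect_equal(attr(mat, "n_sites"), 2)
  # m1 wholly in "left": 100% there, absent (0) elsewhere
  expect_equal(mat$pct_of_map[mat$map_id == "m1" & mat$site_id == "left"], 100)
  expect_false(any(mat$map_id == "m1" & mat$site_id == "right"))
  m3 <- mat[mat$map_id == "m3", ]
  expect_setequal(m3$site_id, c("left", "right"))
  expect_equal(m3$pct_of_map, c(50, 50))

  expect_error(build_overlap_matrix(list(make_map(1, frame9, "dup"),
                                         make_map(2, frame9, "dup")), ss),
               "duplicate")
})

test_that("the counting path reproduces the full-study combination count", {
  expect_equal(count_combinations(11985, 16012, 9), 191795955)
  expect_equal(count_combinations(3, 2, 0), 6)
  expect_error(count_combinations(3, 2, 5))
})

test_that("summaries use the dissolved union, not summed per-site percents", {
  # map = bottom row (3 cells); two identical sites cover its left 2 cells
  maps <- list(make_map(c(3, 6, 9), frame9, "m1"))
  ss <- repair_geometries(raw_collection(list(
    make_site(list(rect_ring(0, 0, 2, 1)), id = "a"),
    make_site(list(rect_ring(0, 0, 2, 1)), id = "b"))))
  attr(ss, "frame") <- frame9
  u <- dissolve_sites(ss)
  attr(u, "frame") <- frame9
  s <- summarize_maps(maps, u)
  expect_equal(s$pct_in_sites, 100 * 2 / 3, tolerance = 1e-12)
  # summed per-site percents double count: 2/3 + 2/3
  mat <- build_overlap_matrix(maps, ss)
  expect_equal(sum(mat$pct_of_map), 2 * 100 * 2 / 3, tolerance = 1e-12)
  expect_gt(sum(mat$pct_of_map), s$pct_in_sites)
})

test_that("fully inside and fully outside maps hit 100 and 0 percent", {
  maps <- list(make_map(1:9, frame9, "all"), make_map(5, frame9, "mid"))
  ss <- repair_geometries(raw_collection(list(
    make_site(list(rect_ring(0, 0, 3, 3)), id = "big"))))
  attr(ss, "frame") <- frame9
  u <- dissolve_sites(ss); attr(u, "frame") <- frame9
  s <- summarize_maps(maps, u)
  expect_equal(s$pct_in_sites, c(100, 100))

  ss0 <- repair_geometries(raw_collection(list(
    make_site(list(rect_ring(10, 10, 11, 11)), id = "far"))))
  u0 <- dissolve_sites(ss0); attr(u0, "frame") <- frame9
  expect_equal(summarize_maps(maps, u0)$pct_in_sites, c(0, 0))
})

test_that("zero-area maps are flagged unusable with a warning", {
  maps <- list(make_map(integer(0), frame9, "empty"), make_map(1, frame9, "ok"))
  u <- dissolve_sites(list(rect_ring(0, 0, 3, 3)))
  attr(u, "frame") <- frame9
  expect_warning(s <- summarize_maps(maps, u), "unusable")
  expect_false(s$usable[1])
  expect_true(is.na(s$pct_in_sites[1]))
  expect_true(s$usable[2])
})

test_that("percent-in-union is bounded by summed per-site percents and monotone", {
  set.seed(55)
  frame <- grid_frame(30, 30, 1)
  for (rep in 1:10) {
    maps <- lapply(1:5, function(i) {
      make_map(sample.int(900, 80), frame, sprintf("m%d", i))
    })
    rects <- random_rects(6, extent = 30)
    sites <- lapply(seq_along(rects), function(i) {
      make_site(list(rects[[i]]), id = sprintf("s%d", i))
    })
    ss <- repair_geometries(raw_collection(sites, frame = frame))
    u <- dissolve_sites(ss)
    mat <- build_overlap_matrix(maps, ss)
    s <- summarize_maps(maps, u)
    for (m in maps) {
      in_union <- s$pct_in_sites[s$map_id == m$map_id]
      summed <- sum(mat$pct_of_map[mat$map_id == m$map_id])
      expect_lte(in_union, summed + 1e-9)
    }
    # monotonicity: adding a site never decreases percent-in-union
    extra <- c(u$rings, random_rects(1, extent = 30))
    u2 <- dissolve_sites(extra)
    attr(u2, "frame") <- frame
    s2 <- summarize_maps(maps, u2)
    expect_true(all(s2$pct_in_sites >= s$pct_in_sites - 1e-9))
  }
})

test_that("splitting a site into abutting halves leaves percents unchanged", {
  set.seed(66)
  frame <- grid_frame(20, 20, 1)
  for (rep in 1:10) {
    m <- make_map(sample.int(400, 60), frame, "m")
    x <- sort(runif(2, 0, 20)); y <- sort(runif(2, 0, 20))
    whole <- rect_ring(x[1], y[1], x[2], y[2])
    cut <- runif(1, x[1], x[2])
    halves <- list(rect_ring(x[1], y[1], cut, y[2]),
                   rect_ring(cut, y[1], x[2], y[2]))
    u1 <- dissolve_sites(list(whole)); attr(u1, "frame") <- frame
    u2 <- dissolve_sites(halves); attr(u2, "frame") <- frame
    s1 <- summarize_maps(list(m), u1)$pct_in_sites
    s2 <- summarize_maps(list(m), u2)$pct_in_sites
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})
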