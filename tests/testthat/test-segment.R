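test_that("extract_green_channel selects the second channel verbatim", {
  px <- array(0, c(2, 3, 3))
  px[1, 1, ] <- c(200, 37, 180)
  img <- rgb_raster(px, 1)
  g <- extract_green_channel(img)
  expect_identical(g$pixels[1, 1], 37L)
  expect_identical(dim(g$pixels), c(2L, 3L))
  expect_identical(g$pixel_size_um, 1)

  white <- rgb_raster(array(255, c(4, 4, 3)), 1)
  expect_true(all(extract_green_channel(white)$pixels == 255L))

  expect_error(extract_green_channel(matrix(1, 2, 2)), "3 channels")
})

test_that("unimodal threshold matches the exhaustive corner-rule oracle", {
  # spec example: decaying histogram from a peak at bin 1
  h1 <- c(100, 10, 8, 6, 4, 2, rep(0, 250))
  expect_identical(unimodal_threshold(h1), oracle_unimodal_threshold(h1))

  # random unimodal-ish histograms
  set.seed(42)
  for (i in 1:25) {
    peak_at <- sample(50:250, 1)
    h <- dnorm(0:255, peak_at, sample(5:40, 1)) * 1e4 +
      c(rep(0, 30), runif(196, 0, 20), rep(0, 30))
    h <- round(h)
    if (all(h == 0)) next
    expect_identical(unimodal_threshold(h), oracle_unimodal_threshold(h))
  }

  # scale invariance of the geometric rule
  expect_identical(unimodal_threshold(h1 * 10), unimodal_threshold(h1))

  # degenerate cases
  h_single <- rep(0, 256); h_single[43] <- 7
  expect_identical(unimodal_threshold(h_single), 42L)
  expect_error(unimodal_threshold(rep(0, 256)), "all-zero")
})

test_that("binarize_tissue uses the dark-tissue polarity", {
  g <- gray_raster(matrix(c(40L, 230L, 128L, 129L), 2), 1)
  expect_identical(binarize_tissue(g, 128)$pixels,
                   matrix(c(TRUE, FALSE, TRUE, FALSE), 2))
  expect_true(all(binarize_tissue(g, 255)$pixels))
  expect_false(any(binarize_tissue(g, 10)$pixels))
  # synthetic scene: mask recovers the rendered wall set exactly
  sc <- render_scene(random_scene(5, 1, image_size = c(300, 300), seed = 8))
  m <- binarize_tissue(extract_green_channel(sc$image), 128)
  expect_identical(m$pixels, sc$truth$wall_mask)
})

test_that("label_lumina finds enclosed lumina and drops border background", {
  ring <- matrix(FALSE, 20, 20)
  ring[5:15, c(5, 15)] <- TRUE
  ring[c(5, 15), 5:15] <- TRUE
  map <- label_lumina(tissue_mask(ring, 1))
  expect_identical(nrow(map$regions), 1L)
  expect_identical(map$regions$area_px, 9 * 9) # 9x9 interior
  expect_equal(map$regions$centroid_row, 10)
  expect_equal(map$regions$centroid_col, 10)

  # all-false mask: everything is border-connected background
  empty <- label_lumina(tissue_mask(matrix(FALSE, 10, 10), 1))
  expect_identical(nrow(empty$regions), 0L)

  # synthetic scene: one region per airspace + vessel
  spec <- random_scene(5, 1, image_size = c(400, 400), seed = 3)
  sc <- render_scene(spec)
  m <- binarize_tissue(extract_green_channel(sc$image), 128)
  expect_identical(nrow(label_lumina(m)$regions), 6L)
})

test_that("erosion matches brute force and is monotone", {
  block <- matrix(FALSE, 60, 60)
  block[6:55, 6:55] <- TRUE # 50x50 solid block
  out <- extract_thick_walls(tissue_mask(block, 1), 7)
  expect_identical(sum(out$pixels), 44L * 44L)
  expect_identical(out$pixels, oracle_erode_square(block, 7))

  # thin stripe vanishes
  stripe <- matrix(FALSE, 30, 30)
  stripe[10:12, 2:29] <- TRUE
  expect_false(any(extract_thick_walls(tissue_mask(stripe, 1), 7)$pixels))

  # random masks: subset property, growing SE never adds pixels
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.7, 30, 30)
    e5 <- extract_thick_walls(tissue_mask(m, 1), 5)$pixels
    e7 <- extract_thick_walls(tissue_mask(m, 1), 7)$pixels
    expect_identical(e5, e5 & m)
    expect_identical(e7, e7 & e5)
    expect_identical(e5, oracle_erode_square(m, 5))
  }

  expect_false(any(extract_thick_walls(
    tissue_mask(matrix(FALSE, 9, 9), 1), 7)$pixels))
  expect_error(extract_thick_walls(tissue_mask(block, 1), 6), "odd")
  # disk SE is a subset of the square SE's constraints: erodes no more
  ed <- extract_thick_walls(tissue_mask(block, 1), 7, "disk")$pixels
  expect_identical(out$pixels, out$pixels & ed)
})

test_that("wall hulls close openings and survive OR-pooled downsampling", {
  # C-shaped thick wall: hull must close the opening
  cshape <- matrix(FALSE, 40, 40)
  cshape[5:35, 5:14] <- TRUE
  cshape[5:14, 5:35] <- TRUE
  cshape[26:35, 5:35] <- TRUE
  hs <- wall_convex_hulls(tissue_mask(cshape, 1), downsample_factor = 1)
  expect_length(hs$hulls, 1)
  # point in the C's mouth, outside the wall pixels but inside the hull
  expect_false(cshape[20, 30])
  expect_true(point_in_polygon(c(20, 30), hs$hulls[[1]]))
  # hull is the hull of the listed pixels: every wall pixel lies inside
  pts <- which(cshape, arr.ind = TRUE)
  set.seed(1)
  for (i in sample(nrow(pts), 30))
    expect_true(point_in_polygon(pts[i, ], hs$hulls[[1]]))

  # two disjoint rings give two hulls
  two <- matrix(FALSE, 60, 120)
  two[10:50, 10:50] <- TRUE; two[20:40, 20:40] <- FALSE
  two[10:50, 70:110] <- TRUE; two[20:40, 80:100] <- FALSE
  expect_length(wall_convex_hulls(tissue_mask(two, 1), 1)$hulls, 2)

  # OR-pooling: no wall component vanishes even when 1 px thin
  thin <- matrix(FALSE, 32, 32)
  thin[9, 9] <- TRUE
  hs4 <- wall_convex_hulls(tissue_mask(thin, 1), 4)
  expect_length(hs4$hulls, 1)

  expect_length(wall_convex_hulls(
    tissue_mask(matrix(FALSE, 8, 8), 1), 4)$hulls, 0)
})

test_that("point-in-polygon agrees with a winding-number oracle", {
  set.seed(11)
  for (trial in 1:40) {
    nv <- sample(3:20, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 2, 10)
    poly <- cbind(10 + rad * sin(ang), 10 + rad * cos(ang)) # star-convex
    pts <- cbind(runif(15, -2, 22), runif(15, -2, 22))
    for (i in seq_len(nrow(pts))) {
      expect_identical(point_in_polygon(pts[i, ], poly),
                       oracle_point_in_polygon(pts[i, ], poly),
                       info = sprintf("trial %d point %d", trial, i))
    }
  }
  # boundary counts as inside (conservative vessel exclusion)
  sq <- cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))
  expect_true(point_in_polygon(c(0, 5), sq))
  expect_true(point_in_polygon(c(10, 10), sq))
  expect_true(point_in_polygon(c(5, 5), sq))
  expect_false(point_in_polygon(c(20, 20), sq))
})

test_that("remove_vessels deletes exactly the hull-covered regions", {
  lab <- matrix(0L, 30, 30)
  lab[4:6, 4:6] <- 1L    # centroid (5,5): inside the hull below
  lab[19:21, 19:21] <- 2L # centroid (20,20): outside
  map <- make_map(lab)
  hulls <- structure(list(
    hulls = list(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))),
    downsample_factor = 1L), class = "wall_hull_set")
  out <- remove_vessels(map, hulls)
  expect_identical(nrow(out$regions), 1L)
  expect_equal(out$regions$centroid_row, 20)
  # relabeled contiguously
  expect_identical(out$regions$label, 1L)
  # never increases the region count
  expect_lte(nrow(out$regions), nrow(map$regions))
})

test_that("segment_section composes the full flowchart", {
  spec <- random_scene(5, 1, image_size = c(400, 400), seed = 13)
  sc <- render_scene(spec)
  map <- segment_section(sc$image)
  expect_identical(nrow(map$regions), 5L)
  # the vessel lumen is gone: no accepted pixel on vessel-lumen truth
  vessel_px <- sc$truth$label_map %in% sc$truth$vessel_labels
  expect_true(all(map$label_map[vessel_px] == 0L))
  # areas equal rasterized truth exactly at noise 0
  truth_airspace <- setdiff(seq_along(spec$airspaces), integer(0))
  expect_identical(sort(map$regions$area_px),
                   sort(as.numeric(sc$truth$true_areas_px[truth_airspace])))

  # blank image: zero regions
  blank <- rgb_raster(array(240, c(64, 64, 3)), 1)
  expect_identical(nrow(segment_section(blank, threshold = 128)$regions), 0L)

  # vessel-only scene: everything removed
  vs <- render_scene(random_scene(0, 2, image_size = c(300, 300), seed = 2))
  expect_identical(nrow(segment_section(vs$image)$regions), 0L)

  # min-area filter is off by default but available
  map_f <- segment_section(sc$image, min_area_px = 1e6)
  expect_identical(nrow(map_f$regions), 0L)

  # stage errors carry stage identification
  expect_error(segment_section(blank, threshold = 300), "binarize")
})
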