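test_that("render_scene produces consistent geometry and ground truth", {
  # one circle, radius 50 px at 1 um/px: equivalent diameter ~ 100 um
  spec <- scene_spec(c(140, 140), pixel_size_um = 1,
                     airspaces = list(scene_shape(c(70, 70), c(50, 50))))
  sc <- render_scene(spec)
  expect_length(sc$truth$true_diameters_um, 1)
  expect_equal(sc$truth$true_diameters_um,
               2 * sqrt(sc$truth$true_areas_um2 / pi))
  expect_lt(abs(sc$truth$true_diameters_um - 100), 2) # rasterization slack
  # green channel darkest on walls, bright elsewhere
  g <- sc$image$pixels[, , 2]
  expect_true(all(g[sc$truth$wall_mask] == spec$tissue_level))
  expect_true(all(g[!sc$truth$wall_mask] == spec$background_level))

  # empty scene: uniform background, empty truth
  sc0 <- render_scene(scene_spec(c(30, 30), pixel_size_um = 1))
  expect_identical(max(sc0$truth$label_map), 0L)
  expect_length(sc0$truth$true_areas_px, 0)
  expect_true(all(sc0$image$pixels[, , 2] == 230))

  # 2 circles + 1 thick vessel: 3 labels, one vessel label
  spec3 <- scene_spec(c(200, 200), pixel_size_um = 1,
                      airspaces = list(scene_shape(c(40, 40), c(15, 15)),
                                       scene_shape(c(40, 120), c(18, 12))),
                      vessels = list(scene_shape(c(140, 100), c(25, 25),
                                                 wall_thickness_px = 12)))
  sc3 <- render_scene(spec3)
  expect_identical(sort(unique(as.vector(sc3$truth$label_map))), 0:3)
  expect_identical(sc3$truth$vessel_labels, 3L)
})

test_that("scene validation rejects bad specs", {
  expect_error(
    render_scene(scene_spec(c(100, 100), pixel_size_um = 1,
                            airspaces = list(scene_shape(c(50, 40), c(15, 15)),
                                             scene_shape(c(50, 55), c(15, 15))))),
    "overlapping airspace interiors")
  expect_error( # vessel wall must be strictly thicker than airspace walls
    scene_spec(c(100, 100), airspaces = list(scene_shape(c(30, 30), c(5, 5),
                                                         wall_thickness_px = 5)),
               vessels = list(scene_shape(c(70, 70), c(10, 10),
                                          wall_thickness_px = 5))),
    "strictly thicker")
  expect_error( # shape must fit inside the image
    scene_spec(c(50, 50), airspaces = list(scene_shape(c(5, 25), c(10, 10)))),
    "outside the image")
})

test_that("generators are bit-identical under a fixed seed", {
  s1 <- render_scene(random_scene(6, 1, noise_sd = 8, seed = 11))
  s2 <- render_scene(random_scene(6, 1, noise_sd = 8, seed = 11))
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth, s2$truth)

  v1 <- render_hu_volume(c(10, 14, 14), 0.3, -480, seed = 4)
  v2 <- render_hu_volume(c(10, 14, 14), 0.3, -480, seed = 4)
  expect_identical(v1$volume$voxels, v2$volume$voxels)

  c1 <- simulate_cohort(8, seed = 2)
  c2 <- simulate_cohort(8, seed = 2)
  expect_identical(c1, c2)
})

test_that("render_hu_volume enforces its construction contract", {
  hv <- render_hu_volume(c(12, 16, 16), 0.4, -500, seed = 9)
  vals <- hv$volume$voxels[hv$mask]
  expect_identical(sum(vals < -900), hv$n_below)
  expect_identical(hv$n_below, as.integer(round(0.4 * hv$n_voxels)))
  expect_lt(abs(mean(vals) - (-500)), 1)

  hv0 <- render_hu_volume(c(8, 10, 10), 0, -450, seed = 1)
  expect_identical(sum(hv0$volume$voxels[hv0$mask] < -900), 0L)

  expect_error(render_hu_volume(c(8, 10, 10), 1.2, -500), "\\[0, 1\\]")
  expect_error(render_hu_volume(c(8, 10, 10), 1, -500), "infeasible")
  expect_error(render_hu_volume(c(8, 10, 10), 0, -950), "infeasible")
})

test_that("simulate_cohort honors effect sizes and validation", {
  expect_error(simulate_cohort(1), ">= 2")
  expect_error(simulate_cohort(5, effect_sizes = c(bogus = 1)), "named")
  tab <- simulate_cohort(200, effect_sizes = c(D2 = 50), seed = 3)
  expect_identical(nrow(tab), 400L)
  expect_setequal(unique(tab$group), c("control", "treated"))
  d2_shift <- mean(tab$D2[tab$group == "treated"]) -
    mean(tab$D2[tab$group == "control"])
  expect_lt(abs(d2_shift - 50), 3) # ~sd 8 / sqrt(200) scale
  # all-zero shift gives exchangeable groups
  tab0 <- simulate_cohort(50, effect_sizes = setNames(
    rep(0, 11), c("MLVI", "VBT", "RMBR", "LMBR", "R", "C", "IL6", "IP10",
                  "KC", "MCP1", "D2")), seed = 4)
  expect_lt(abs(mean(tab0$D2[tab0$group == "treated"]) -
                  mean(tab0$D2[tab0$group == "control"])), 5)
})

test_that("scene and feature-table I/O round-trips", {
  tmp <- withr::local_tempdir()
  sc <- render_scene(random_scene(4, 1, image_size = c(300, 300), seed = 5))
  stem <- file.path(tmp, "scene")
  write_scene(sc, stem)
  img <- read_raster(paste0(stem, ".png"), 0.725)
  expect_identical(img$pixels, sc$image$pixels)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(side$true_areas_px, sc$truth$true_areas_px)
  expect_equal(side$vessel_labels, sc$truth$vessel_labels)

  # plain-text NetPBM round-trip
  ppm <- file.path(tmp, "scene.ppm")
  write_raster(sc$image, ppm)
  img2 <- read_raster(ppm, 0.725)
  expect_identical(img2$pixels, sc$image$pixels)

  tab <- simulate_cohort(5, seed = 1)
  csv <- file.path(tmp, "cohort.csv")
  write_feature_table(tab, csv)
  expect_equal(read_feature_table(csv), tab, tolerance = 1e-12)
})
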