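# Synthetic histology scenes, HU volumes and feature cohorts with exact
# ground truth, so every downstream stage is testable without external data.

#' Elliptical shape for a synthetic scene
#'
#' @param center numeric `(row, col)` in pixel units
#' @param semi_axes numeric `(a, b)` semi-axis lengths in pixels (lumen)
#' @param rotation rotation angle in radians
#' @param wall_thickness_px thickness of the tissue wall ring drawn around
#'   the lumen, in pixels
#' @return a `scene_shape` list
#' @export
scene_shape <- function(center, semi_axes, rotation = 0,
                        wall_thickness_px = 3) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes > 0), wall_thickness_px > 0)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation),
                 wall_thickness_px = as.numeric(wall_thickness_px)),
            class = "scene_shape")
}

#' Specification of a synthetic lung-section scene
#'
#' Describes a histology-like image: thin-walled airspaces (alveoli /
#' emphysematous spaces), thick-walled vessels or bronchioles with bright
#' lumina, and a bright empty-slide background. Levels refer to the green
#' channel of the rendered image, where H&E tissue is darkest.
#'
#' @param image_size `(rows, cols)` in pixels
#' @param pixel_size_um calibration, micrometres per pixel (default 0.725,
#'   a typical 10x whole-slide acquisition)
#' @param airspaces list of [scene_shape()] with thin walls
#' @param vessels list of [scene_shape()] with thick walls; every vessel's
#'   wall must be strictly thicker than every airspace wall
#' @param background_level 8-bit green level of empty space (default 230)
#' @param tissue_level 8-bit green level of tissue walls (default 40)
#' @param noise_sd additive Gaussian noise SD, applied per channel after
#'   rasterization and clipped to `[0, 255]`
#' @param seed integer seed for the noise
#' @return a `scene_spec` list
#' @export
scene_spec <- function(image_size, pixel_size_um = 0.725,
                       airspaces = list(), vessels = list(),
                       background_level = 230, tissue_level = 40,
                       noise_sd = 0, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 1))
  check_pixel_size(pixel_size_um)
  stopifnot(noise_sd >= 0, tissue_level < background_level)
  airspaces <- lapply(airspaces, as_shape)
  vessels <- lapply(vessels, as_shape)
  if (length(airspaces) && length(vessels)) {
    wa <- max(vapply(airspaces, `[[`, 0, "wall_thickness_px"))
    wv <- min(vapply(vessels, `[[`, 0, "wall_thickness_px"))
    if (wv <= wa)
      stop("vessel walls must be strictly thicker than airspace walls (",
           wv, " <= ", wa, ")")
  }
  spec <- structure(list(image_size = as.integer(image_size),
                         pixel_size_um = pixel_size_um,
                         airspaces = airspaces, vessels = vessels,
                         background_level = background_level,
                         tissue_level = tissue_level,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "scene_spec")
  for (sh in c(airspaces, vessels)) check_inside(sh, spec$image_size)
  spec
}

as_shape <- function(x) {
  if (inherits(x, "scene_shape")) return(x)
  do.call(scene_shape, x)
}

check_inside <- function(sh, image_size) {
  reach <- max(sh$semi_axes) + sh$wall_thickness_px
  if (sh$center[1] - reach < 0.5 || sh$center[1] + reach > image_size[1] + 0.5 ||
      sh$center[2] - reach < 0.5 || sh$center[2] + reach > image_size[2] + 0.5)
    stop("shape (incl. wall) extends outside the image")
  invisible(TRUE)
}

# Logical matrix: pixel centers inside the (rotated) ellipse boundary.
# grow expands both semi-axes, used to rasterize the wall ring.
rasterize_ellipse <- function(sh, image_size, grow = 0) {
  a <- sh$semi_axes[1] + grow
  b <- sh$semi_axes[2] + grow
  reach <- max(a, b)
  r0 <- max(1L, floor(sh$center[1] - reach))
  r1 <- min(image_size[1], ceiling(sh$center[1] + reach))
  c0 <- max(1L, floor(sh$center[2] - reach))
  c1 <- min(image_size[2], ceiling(sh$center[2] + reach))
  m <- matrix(FALSE, image_size[1], image_size[2])
  if (r1 < r0 || c1 < c0) return(m)
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - sh$center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - sh$center[2])
  ct <- cos(sh$rotation); st <- sin(sh$rotation)
  u <- dr * ct + dc * st
  v <- -dr * st + dc * ct
  m[rr, cc] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

#' Render a synthetic scene and its ground truth
#'
#' Rasterizes the scene (a pixel belongs to a shape iff its center lies
#' inside the analytic boundary), draws walls over background, renders a
#' 24-bit RGB image whose green channel is darkest on tissue, and returns
#' the exact ground-truth label map. Ground-truth areas are computed from
#' the rasterized regions so that segmentation output can be compared
#' exactly. Labels `1..n_airspaces` are airspaces; the following labels are
#' vessel lumina (listed in `vessel_labels`).
#'
#' @param spec a [scene_spec()]
#' @return list with elements `image` (an [rgb_raster()]) and `truth`
#'   (list: `label_map`, `true_areas_px`, `true_areas_um2`,
#'   `true_diameters_um`, `vessel_labels`, `wall_mask`)
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  shapes <- c(spec$airspaces, spec$vessels)
  lab <- matrix(0L, nr, nc)
  wall <- matrix(FALSE, nr, nc)
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    lumen <- rasterize_ellipse(sh, spec$image_size)
    if (i <= length(spec$airspaces) && any(lab[lumen] > 0L))
      stop("validation error: overlapping airspace interiors")
    outer_e <- rasterize_ellipse(sh, spec$image_size,
                                 grow = sh$wall_thickness_px)
    lab[lumen] <- i
    wall <- wall | (outer_e & !lumen)
  }
  lab[wall] <- 0L # walls win over any overlapped lumen pixels
  px_um2 <- spec$pixel_size_um^2
  areas <- if (length(shapes)) tabulate(lab[lab > 0L], length(shapes)) else
    integer(0)
  truth <- list(
    label_map = lab,
    true_areas_px = areas,
    true_areas_um2 = areas * px_um2,
    true_diameters_um = 2 * sqrt(areas * px_um2 / pi),
    vessel_labels = if (length(spec$vessels))
      length(spec$airspaces) + seq_along(spec$vessels) else integer(0),
    wall_mask = wall)

  g <- matrix(spec$background_level, nr, nc)
  g[wall] <- spec$tissue_level
  r <- matrix(min(255, spec$background_level + 15), nr, nc)
  b <- r
  r[wall] <- min(255, spec$tissue_level + 140) # eosin: red-dominant tissue
  b[wall] <- min(255, spec$tissue_level + 80)
  img <- array(0, c(nr, nc, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, {
      img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    })
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = rgb_raster(round(img), spec$pixel_size_um), truth = truth)
}

#' Draw a random non-overlapping scene
#'
#' Places `n_vessels` thick-walled rings and `n_airspaces` thin-walled
#' ellipses by rejection sampling with a separation margin, so that every
#' lumen is enclosed by its own wall and no two shapes touch.
#'
#' @param n_airspaces number of airspaces
#' @param n_vessels number of vessels/bronchioles
#' @param image_size `(rows, cols)`; default `c(600, 600)`
#' @param pixel_size_um calibration (default 0.725)
#' @param noise_sd additive noise SD (default 0)
#' @param seed integer seed (drives both placement and rendering noise)
#' @param airspace_radius_range lumen semi-axis range for airspaces, px
#' @param vessel_radius_range lumen semi-axis range for vessels, px
#' @param airspace_wall_px airspace wall thickness (default 3)
#' @param vessel_wall_px vessel wall thickness (default 12)
#' @return a [scene_spec()]
#' @export
random_scene <- function(n_airspaces, n_vessels = 0, image_size = c(600, 600),
                         pixel_size_um = 0.725, noise_sd = 0, seed = 1L,
                         airspace_radius_range = c(8, 18),
                         vessel_radius_range = c(18, 30),
                         airspace_wall_px = 3, vessel_wall_px = 12) {
  with_seed(seed, {
    placed <- list() # (center_r, center_c, bounding_radius)
    margin <- 4
    place <- function(rad_range, wall, n, rot_max) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(5000)) {
          ax <- stats::runif(2, rad_range[1], rad_range[2])
          reach <- max(ax) + wall
          ctr <- c(stats::runif(1, reach + 1, image_size[1] - reach),
                   stats::runif(1, reach + 1, image_size[2] - reach))
          clear <- TRUE
          for (p in placed) {
            if (sqrt(sum((ctr - p[1:2])^2)) < reach + p[3] + margin) {
              clear <- FALSE; break
            }
          }
          if (clear) {
            placed[[length(placed) + 1L]] <<- c(ctr, reach)
            out[[i]] <- scene_shape(ctr, ax, stats::runif(1, 0, rot_max),
                                    wall)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place shape ", i,
                      ": image too crowded, reduce n or radii")
      }
      out
    }
    vessels <- place(vessel_radius_range, vessel_wall_px, n_vessels, pi)
    airspaces <- place(airspace_radius_range, airspace_wall_px,
                       n_airspaces, pi)
    scene_spec(image_size, pixel_size_um, airspaces = airspaces,
               vessels = vessels, noise_sd = noise_sd, seed = seed)
  })
}

#' Write a rendered scene to disk (image + JSON ground-truth sidecar)
#'
#' @param scene result of [render_scene()]
#' @param stem output path stem; writes `<stem>.png` and `<stem>.json`
#' @return the image path, invisibly
#' @export
write_scene <- function(scene, stem) {
  img_path <- paste0(stem, ".png")
  write_raster(scene$image, img_path)
  truth <- scene$truth
  side <- list(pixel_size_um = scene$image$pixel_size_um,
               true_areas_px = truth$true_areas_px,
               true_areas_um2 = truth$true_areas_um2,
               true_diameters_um = truth$true_diameters_um,
               vessel_labels = truth$vessel_labels)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(img_path)
}

# ---- HU volume fixture -----------------------------------------------------

#' Hounsfield-unit volume container
#'
#' @param voxels 3D numeric array of HU values
#' @param voxel_size_um isotropic voxel edge length in micrometres
#' @return an object of class `hu_volume`
#' @export
hu_volume <- function(voxels, voxel_size_um = 46) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            all(is.finite(voxels)), voxel_size_um > 0)
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um),
            class = "hu_volume")
}

#' Generate a synthetic HU volume with a lung mask and exact density truth
#'
#' Constructs an ellipsoidal "lung" mask inside the volume and fills the
#' in-mask voxels so that exactly `round(fraction * N)` of them lie strictly
#' below -900 HU and the in-mask mean equals `mean_hu` to machine precision
#' (jitter is zero-sum within each stratum). Out-of-mask voxels are set to
#' soft-tissue values around 0 HU.
#'
#' @param shape integer `(z, y, x)` volume dimensions
#' @param lung_fraction_below_thresh target fraction of in-mask voxels
#'   strictly below -900 HU, in `[0, 1]`
#' @param mean_hu target in-mask mean intensity (HU)
#' @param seed integer seed
#' @param voxel_size_um isotropic voxel size (default 46, a typical
#'   murine micro-CT reconstruction)
#' @return list: `volume` (an [hu_volume()]), `mask` (logical 3D array),
#'   `n_voxels`, `n_below`
#' @export
render_hu_volume <- function(shape, lung_fraction_below_thresh, mean_hu,
                             seed = 1L, voxel_size_um = 46) {
  f <- lung_fraction_below_thresh
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("lung_fraction_below_thresh must lie in [0, 1]")
  stopifnot(length(shape) == 3L, all(shape >= 3))
  dz <- shape[1]; dy <- shape[2]; dx <- shape[3]
  ctr <- (c(dz, dy, dx) + 1) / 2
  ax <- 0.42 * c(dz, dy, dx)
  iz <- slice.index(array(0, shape), 1)
  iy <- slice.index(array(0, shape), 2)
  ix <- slice.index(array(0, shape), 3)
  mask <- ((iz - ctr[1]) / ax[1])^2 + ((iy - ctr[2]) / ax[2])^2 +
    ((ix - ctr[3]) / ax[3])^2 <= 1
  n <- sum(mask)
  k <- as.integer(round(f * n))
  vox <- array(0, shape)
  with_seed(seed, {
    vox[!mask] <- stats::rnorm(sum(!mask), 0, 30) # chest-wall soft tissue
    idx <- which(mask)
    below_idx <- if (k > 0) sample(idx, k) else integer(0)
    above_idx <- setdiff(idx, below_idx)
    if (k == n) {
      if (mean_hu >= -900)
        stop("infeasible: all voxels below -900 HU but mean_hu >= -900")
      vox[below_idx] <- jitter_stratum(mean_hu, k, upper = -901)
    } else if (k == 0L) {
      if (mean_hu < -900)
        stop("infeasible: no voxel below -900 HU but mean_hu < -900")
      vox[above_idx] <- jitter_stratum(mean_hu, n, lower = -899)
    } else {
      b0 <- -950
      a0 <- (n * mean_hu - k * b0) / (n - k)
      if (a0 < -899)
        stop("infeasible: mean_hu too low for the requested fraction")
      vox[below_idx] <- jitter_stratum(b0, k, upper = -901)
      vox[above_idx] <- jitter_stratum(a0, n - k, lower = -899)
    }
  })
  list(volume = hu_volume(vox, voxel_size_um), mask = mask,
       n_voxels = n, n_below = k)
}

# Values with exact mean `center`, jittered but kept on one side of the
# -900 HU threshold (zero-sum jitter, shrunk to respect the bound).
jitter_stratum <- function(center, n, lower = -Inf, upper = Inf) {
  if (n == 1L) return(center)
  j <- stats::rnorm(n, 0, 10)
  j <- j - mean(j)
  s <- 1
  if (is.finite(upper) && max(j) > 0) s <- min(s, (upper - center) / max(j))
  if (is.finite(lower) && min(j) < 0) s <- min(s, (lower - center) / min(j))
  center + s * j
}

# ---- feature cohorts -------------------------------------------------------

cohort_features <- c("MLVI", "VBT", "RMBR", "LMBR", "R", "C",
                     "IL6", "IP10", "KC", "MCP1", "D2")

# Stated-world defaults for the murine elastase model (see methods
# vignette): D2 anchored to published control/treated medians, VBT to the
# "< 5% in healthy animals" rule; others are realistic murine values.
default_control_means <- c(MLVI = -350, VBT = 2.5, RMBR = 420, LMBR = 380,
                           R = 0.55, C = 0.045, IL6 = 1, IP10 = 1, KC = 1,
                           MCP1 = 1, D2 = 100)
default_effect_sizes <- c(MLVI = -80, VBT = 12, RMBR = 40, LMBR = 30,
                          R = 0.15, C = -0.008, IL6 = 2, IP10 = 1.5,
                          KC = 2.5, MCP1 = 1.2, D2 = 80)
default_noise_sd <- c(MLVI = 25, VBT = 1.5, RMBR = 25, LMBR = 25,
                      R = 0.06, C = 0.005, IL6 = 0.3, IP10 = 0.3,
                      KC = 0.35, MCP1 = 0.3, D2 = 8)

#' Simulate a two-group per-animal feature cohort
#'
#' Draws control and treated groups from per-feature Gaussians
#' `N(control_mean, noise_sd)` and `N(control_mean + effect, noise_sd)`.
#' Includes a `D2` column so gold-standard labeling can be exercised.
#'
#' @param n_per_group animals per group (>= 2)
#' @param effect_sizes named per-feature mean shift (treated - control);
#'   unnamed features keep their defaults, `0` silences a feature
#' @param noise_sd named per-feature Gaussian SD
#' @param control_means named per-feature control means
#' @param seed integer seed
#' @return a data.frame with columns `animal_id`, `group`, `time_point`
#'   and one column per feature
#' @export
simulate_cohort <- function(n_per_group, effect_sizes = NULL, noise_sd = NULL,
                            control_means = NULL, seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop("n_per_group must be >= 2")
  eff <- override_named(default_effect_sizes, effect_sizes)
  sds <- override_named(default_noise_sd, noise_sd)
  mns <- override_named(default_control_means, control_means)
  n <- as.integer(n_per_group)
  with_seed(seed, {
    tab <- data.frame(
      animal_id = sprintf("A%03d", seq_len(2L * n)),
      group = rep(c("control", "treated"), each = n),
      time_point = "24h",
      stringsAsFactors = FALSE)
    for (ft in cohort_features) {
      mu <- c(rep(mns[[ft]], n), rep(mns[[ft]] + eff[[ft]], n))
      tab[[ft]] <- stats::rnorm(2L * n, mu, sds[[ft]])
    }
    tab
  })
}

override_named <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  if (is.null(names(user)) || any(!names(user) %in% names(defaults)))
    stop("overrides must be named with known features: ",
         paste(names(defaults), collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Write / read a feature table as CSV
#'
#' @param table data.frame as produced by [simulate_cohort()]
#' @param path CSV path
#' @return the path (write) or the table (read)
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
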