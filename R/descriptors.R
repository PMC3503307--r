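# Airspace-enlargement descriptors: equivalent diameters, the weighted
# mean diameter family Dv, and the raster-scan mean linear intercept Lm.

#' Equivalent airspace diameters from a labeled map
#'
#' The area of region i is its pixel count scaled by the calibration,
#' `A_i = area_px * pixel_size_um^2`, and the equivalent diameter is the
#' diameter of the circle with the same area, `d_i = 2 * sqrt(A_i / pi)`.
#'
#' @param map an [airspace_map()]
#' @return a `diameter_sample`: list with `diameters_um` and `areas_um2`
#'   (ordered by region label)
#' @export
equivalent_diameters <- function(map) {
  stopifnot(inherits(map, "airspace_map"))
  areas <- map$regions$area_px * map$pixel_size_um^2
  structure(list(diameters_um = 2 * sqrt(areas / pi), areas_um2 = areas),
            class = "diameter_sample")
}

#' Weighted mean diameter D_v
#'
#' `D_v = <d^(v+1)> / <d^v>`, the ratio of consecutive raw moments of the
#' equivalent-diameter distribution (`<.>` is the arithmetic mean). `D_0`
#' is the plain mean; increasing v weights enlarged airspaces ever more
#' heavily, which is why `D_2` is the most sensitive descriptor of focal
#' emphysema.
#'
#' @param sample a `diameter_sample` from [equivalent_diameters()], or a
#'   bare numeric vector of diameters
#' @param v nonnegative integer moment order
#' @return D_v in micrometres
#' @export
weighted_mean_diameter <- function(sample, v) {
  d <- sample_diameters(sample)
  if (!length(d)) stop("undefined: empty diameter sample")
  if (v < 0 || v != round(v)) stop("v must be a nonnegative integer")
  mean(d^(v + 1)) / mean(d^v)
}

sample_diameters <- function(sample) {
  d <- if (inherits(sample, "diameter_sample")) sample$diameters_um
       else as.numeric(sample)
  if (length(d) && any(d <= 0)) stop("diameters must be positive")
  d
}

#' D1 / D2 from central moments
#'
#' Expresses the moment ratios in terms of the mean, variance and skewness
#' of the diameter distribution (population 1/n convention, gamma the third
#' standardized central moment):
#' \deqn{D_1 = \mu (1 + \sigma^2/\mu^2)}
#' \deqn{D_2 = (\mu^3 + 3\mu\sigma^2 + \gamma\sigma^3) / (\mu^2 + \sigma^2)}
#' These are algebraically identical to the `<d^(v+1)>/<d^v>` ratios, and
#' the two routes are verified against each other in the test suite.
#'
#' @param mu mean diameter (> 0), micrometres
#' @param sigma2 population variance, micrometres squared
#' @param gamma standardized skewness (only used for `v = 2`)
#' @param v 1 or 2
#' @return D_v in micrometres
#' @export
d_v_from_central_moments <- function(mu, sigma2, gamma = 0, v) {
  if (mu <= 0) stop("mu must be positive")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (v == 1) return(mu * (1 + sigma2 / mu^2))
  if (v == 2) {
    s <- sqrt(sigma2)
    return((mu^3 + 3 * mu * sigma2 + gamma * s^3) / (mu^2 + sigma2))
  }
  stop("v must be 1 or 2")
}

# Population (1/n) central moments of a sample: mean, variance, skewness.
central_moments <- function(d) {
  n <- length(d)
  mu <- mean(d)
  s2 <- sum((d - mu)^2) / n
  g <- if (s2 > 0) (sum((d - mu)^3) / n) / s2^1.5 else 0
  list(mu = mu, sigma2 = s2, gamma = g)
}

#' Mean linear intercept by raster scan
#'
#' Scans each image row; every maximal run of airspace pixels bounded on
#' both ends by a non-airspace pixel contributes one intercept of length
#' `run_length * pixel_size_um`. Runs touching the image border have no
#' bounding wall on one side and are excluded. Lm is the mean of all
#' intercepts pooled over the section. An optional vertical scan pools
#' column runs as well.
#'
#' @param map an [airspace_map()]
#' @param scan_vertical also scan columns (default `FALSE`: one stated
#'   horizontal convention)
#' @return list with `Lm_um` and `n_intercepts`
#' @export
mean_linear_intercept <- function(map, scan_vertical = FALSE) {
  stopifnot(inherits(map, "airspace_map"))
  runs <- .row_intercepts(map$label_map)
  if (scan_vertical) runs <- c(runs, .row_intercepts(t(map$label_map)))
  if (!length(runs)) stop("undefined: no bounded intercepts found")
  list(Lm_um = mean(runs) * map$pixel_size_um, n_intercepts = length(runs))
}

#' Compute the full descriptor set for one section
#'
#' Bundles Lm, D0, D1, D2 and the region/intercept counts for a labeled
#' airspace map. Deterministic.
#'
#' @param map an [airspace_map()]
#' @param scan_vertical passed to [mean_linear_intercept()]
#' @return a `descriptor_set`: list with `Lm_um`, `D0_um`, `D1_um`,
#'   `D2_um`, `n_airspaces`, `n_intercepts`
#' @export
compute_descriptors <- function(map, scan_vertical = FALSE) {
  stopifnot(inherits(map, "airspace_map"))
  if (!nrow(map$regions)) stop("empty airspace map: no descriptors defined")
  ds <- equivalent_diameters(map)
  lm <- mean_linear_intercept(map, scan_vertical)
  structure(list(Lm_um = lm$Lm_um,
                 D0_um = weighted_mean_diameter(ds, 0),
                 D1_um = weighted_mean_diameter(ds, 1),
                 D2_um = weighted_mean_diameter(ds, 2),
                 n_airspaces = nrow(map$regions),
                 n_intercepts = lm$n_intercepts),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(
    "descriptors: Lm = %.2f um | D0 = %.2f | D1 = %.2f | D2 = %.2f um (%d airspaces, %d intercepts)\n",
    x$Lm_um, x$D0_um, x$D1_um, x$D2_um, x$n_airspaces, x$n_intercepts))
  invisible(x)
}

#' Aggregate per-section descriptor rows to one value per animal
#'
#' Two modes: `"pooled"` (default) re-derives each animal's descriptors
#' from the pooled diameter sample and pooled intercepts of all its
#' sections; `"mean"` averages the per-section descriptor values.
#'
#' @param rows data.frame with one row per section: `animal_id`,
#'   `n_airspaces`, `n_intercepts`, `Lm_um`, `D0_um`, `D1_um`, `D2_um`
#'   and, for pooled mode, list-columns or long-format diameter data are
#'   not required — pooled mode uses the moment identities below
#' @param mode `"pooled"` or `"mean"`
#' @return data.frame with one row per animal
#' @details Pooled mode reconstructs the pooled raw moments from each
#'   section's `n_airspaces` and its D-values: since
#'   `D0 = m1`, `D1 = m2/m1`, `D2 = m3/m2` with `m_k` the per-section mean
#'   of `d^k`, the per-section moment sums are `n*m1`, `n*m1*D1`,
#'   `n*m1*D1*D2`, which add across sections; Lm pools via intercept
#'   counts.
#' @export
aggregate_descriptors <- function(rows, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  split_rows <- split(rows, rows$animal_id)
  out <- lapply(split_rows, function(r) {
    if (mode == "mean") {
      data.frame(animal_id = r$animal_id[1],
                 n_airspaces = sum(r$n_airspaces),
                 n_intercepts = sum(r$n_intercepts),
                 Lm_um = mean(r$Lm_um), D0_um = mean(r$D0_um),
                 D1_um = mean(r$D1_um), D2_um = mean(r$D2_um))
    } else {
      s1 <- sum(r$n_airspaces * r$D0_um)
      s2 <- sum(r$n_airspaces * r$D0_um * r$D1_um)
      s3 <- sum(r$n_airspaces * r$D0_um * r$D1_um * r$D2_um)
      n <- sum(r$n_airspaces)
      data.frame(animal_id = r$animal_id[1],
                 n_airspaces = n,
                 n_intercepts = sum(r$n_intercepts),
                 Lm_um = sum(r$Lm_um * r$n_intercepts) / sum(r$n_intercepts),
                 D0_um = s1 / n, D1_um = s2 / s1, D2_um = s3 / s2)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
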