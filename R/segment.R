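# Airspace segmentation: green channel -> unimodal threshold -> tissue mask
# -> lumen labeling -> thick-wall erosion -> convex hulls -> vessel removal.

#' Extract the green channel of an RGB section raster
#'
#' H&E-stained tissue absorbs green most strongly, so the green channel has
#' the greatest tissue/background contrast; it is returned verbatim as an
#' 8-bit grayscale raster carrying the pixel calibration.
#'
#' @param image an [rgb_raster()]
#' @return a [gray_raster()]
#' @export
extract_green_channel <- function(image) {
  if (!inherits(image, "rgb_raster"))
    stop("expected an rgb_raster with 3 channels")
  gray_raster(matrix(as.integer(image$pixels[, , 2]),
                     nrow = dim(image$pixels)[1]),
              image$pixel_size_um)
}

#' Maximum-deviation (corner) threshold for unimodal histograms
#'
#' Histology green-channel histograms are unimodal (a single background
#' peak with a tissue tail), so bimodal methods such as Otsu fail. The
#' corner rule draws a straight line from the histogram peak to the last
#' nonzero bin on the tail side and returns the bin between them with the
#' largest perpendicular distance to that line. The tail side is the side
#' with the longer reach from the peak; distance ties break toward the
#' peak. A peak at the tail end (degenerate line) returns the peak index.
#'
#' @param histogram 256 nonnegative bin counts (bin i = intensity i - 1)
#' @return threshold as a 0-based intensity value in `[0, 255]`
#' @export
unimodal_threshold <- function(histogram) {
  h <- as.numeric(histogram)
  if (length(h) != 256L) stop("expected 256 histogram bins")
  if (any(h < 0)) stop("histogram counts must be nonnegative")
  nz <- which(h > 0)
  if (!length(nz)) stop("all-zero histogram")
  peak <- which.max(h)
  lo <- nz[1]; hi <- nz[length(nz)]
  tail_end <- if (peak - lo >= hi - peak) lo else hi
  if (tail_end == peak) return(peak - 1L)
  idx <- if (tail_end < peak) tail_end:peak else peak:tail_end
  # perpendicular distance from (i, h[i]) to the peak--tail_end line
  vx <- tail_end - peak; vy <- h[tail_end] - h[peak]
  d <- abs(vx * (h[idx] - h[peak]) - vy * (idx - peak)) / sqrt(vx^2 + vy^2)
  cand <- idx[d == max(d)]
  best <- cand[which.min(abs(cand - peak))] # ties toward the peak
  best - 1L
}

#' Threshold a grayscale raster into a tissue mask
#'
#' Tissue is dark in the green channel, so tissue = intensity <= threshold.
#'
#' @param gray a [gray_raster()]
#' @param threshold intensity threshold in `[0, 255]`
#' @return a [tissue_mask()]
#' @export
binarize_tissue <- function(gray, threshold) {
  stopifnot(inherits(gray, "gray_raster"))
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  tissue_mask(gray$pixels <= threshold, gray$pixel_size_um)
}

#' Label luminal structures in the inverted tissue mask
#'
#' Connected components (4-connectivity) of the non-tissue pixels;
#' components touching the image border are empty slide around the section
#' and are discarded as background. Remaining components are relabeled
#' contiguously and tabulated (pixel area, centroid).
#'
#' @param tissue a [tissue_mask()]
#' @return an [airspace_map()]
#' @export
label_lumina <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_mask"))
  lab <- .cc_label(!tissue$pixels, 4L)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- border[border > 0L]
  if (length(border)) lab[lab %in% border] <- 0L
  relabel_map(lab, tissue$pixel_size_um)
}

#' Keep only the thickest tissue walls by binary erosion
#'
#' Erodes the parenchyma mask with a structuring element of the given size
#' so only walls thicker than the element survive — these belong to vessels
#' and bronchioles, whose thin-walled neighbours (alveolar septa) vanish.
#'
#' @param tissue a [tissue_mask()]
#' @param se_size side length (square) or diameter (disk) of the
#'   structuring element, odd and >= 3; default 7
#' @param se_shape `"square"` (default) or `"disk"`
#' @return a [tissue_mask()] of the surviving thick walls
#' @export
extract_thick_walls <- function(tissue, se_size = 7L, se_shape = "square") {
  stopifnot(inherits(tissue, "tissue_mask"))
  if (se_size %% 2 == 0 || se_size < 3)
    stop("se_size must be odd and >= 3")
  r <- (se_size - 1L) / 2L
  off <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
  if (se_shape == "disk") {
    off <- off[off[, 1]^2 + off[, 2]^2 <= r^2, , drop = FALSE]
  } else if (se_shape != "square") stop("se_shape must be square or disk")
  tissue_mask(.binary_erode(tissue$pixels, off), tissue$pixel_size_um)
}

#' Convex hulls of the surviving thick walls
#'
#' The mask is first downsampled by OR-pooling over `factor x factor`
#' blocks (so no wall pixel can vanish), then each 8-connected wall
#' component's pixel set is replaced by its convex hull polygon. The hull
#' closes vessel walls around their lumina, which is what lets the
#' centroid-intersection step identify and discard them.
#'
#' @param thick_walls a [tissue_mask()] from [extract_thick_walls()]
#' @param downsample_factor block size for OR-pooling, >= 1 (default 4)
#' @return a `wall_hull_set`: list of hull polygons (matrices of
#'   `(row, col)` vertices in downsampled pixel coordinates, closed
#'   implicitly) plus the `downsample_factor`
#' @export
wall_convex_hulls <- function(thick_walls, downsample_factor = 4L) {
  stopifnot(inherits(thick_walls, "tissue_mask"))
  f <- as.integer(downsample_factor)
  if (f < 1) stop("downsample_factor must be >= 1")
  m <- or_pool(thick_walls$pixels, f)
  lab <- .cc_label(m, 8L)
  k <- max(lab)
  hulls <- vector("list", k)
  if (k > 0) {
    pix <- which(lab > 0L, arr.ind = TRUE)
    labs <- lab[lab > 0L]
    for (i in seq_len(k)) {
      pts <- pix[labs == i, , drop = FALSE]
      hull_idx <- grDevices::chull(pts[, 2], pts[, 1]) # (x, y) = (col, row)
      hulls[[i]] <- pts[hull_idx, , drop = FALSE]
    }
  }
  structure(list(hulls = hulls, downsample_factor = f),
            class = "wall_hull_set")
}

# OR-pooling downsample: block max over f x f tiles (ragged edge padded).
or_pool <- function(m, f) {
  if (f == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / f); nc2 <- ceiling(nc / f)
  padded <- matrix(FALSE, nr2 * f, nc2 * f)
  padded[seq_len(nr), seq_len(nc)] <- m
  dim(padded) <- c(f, nr2, f, nc2)
  apply(padded, c(2, 4), any)
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' Ray-casting with an explicit on-edge check; degenerate "polygons" of one
#' or two vertices are treated as a point or segment. Used to intersect
#' region centroids with wall hulls.
#'
#' @param point numeric `(row, col)`
#' @param polygon matrix of `(row, col)` vertices (implicitly closed)
#' @return logical
#' @export
point_in_polygon <- function(point, polygon) {
  n <- nrow(polygon)
  if (n == 0L) return(FALSE)
  y <- point[1]; x <- point[2]
  py <- polygon[, 1]; px <- polygon[, 2]
  eps <- 1e-9
  # on-vertex / on-edge check
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ey <- py[j] - py[i]; ex <- px[j] - px[i]
    wy <- y - py[i]; wx <- x - px[i]
    cross <- ex * wy - ey * wx
    if (abs(cross) < eps) {
      dot <- wx * ex + wy * ey
      len2 <- ex^2 + ey^2
      if (len2 < eps) { # degenerate edge = point
        if (abs(wx) < eps && abs(wy) < eps) return(TRUE)
      } else if (dot >= -eps && dot <= len2 + eps) return(TRUE)
    }
  }
  if (n < 3L) return(FALSE)
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((py[i] > y) != (py[j] > y)) {
      xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      if (x < xint) inside <- !inside
    }
  }
  inside
}

#' Remove vessels and bronchioles from a labeled lumen map
#'
#' Every labeled region whose centroid falls inside (or on) any wall hull
#' is deleted — a thick eroded wall closing around a centroid identifies
#' that lumen as a vessel or bronchiole, not an airspace. Centroids are
#' computed at full resolution and rescaled into the hulls' downsampled
#' coordinates; survivors are relabeled contiguously.
#'
#' @param lumina an [airspace_map()]
#' @param hulls a `wall_hull_set` from [wall_convex_hulls()]
#' @return an [airspace_map()] containing only accepted airspaces
#' @export
remove_vessels <- function(lumina, hulls) {
  stopifnot(inherits(lumina, "airspace_map"),
            inherits(hulls, "wall_hull_set"))
  if (!nrow(lumina$regions) || !length(hulls$hulls)) return(lumina)
  f <- hulls$downsample_factor
  # continuous mapping: full-res pixel center i -> downsampled (i - 0.5)/f + 0.5
  cr <- (lumina$regions$centroid_row - 0.5) / f + 0.5
  cc <- (lumina$regions$centroid_col - 0.5) / f + 0.5
  drop <- vapply(seq_len(nrow(lumina$regions)), function(i) {
    for (h in hulls$hulls)
      if (point_in_polygon(c(cr[i], cc[i]), h)) return(TRUE)
    FALSE
  }, logical(1))
  if (!any(drop)) return(lumina)
  lab <- lumina$label_map
  lab[lab %in% lumina$regions$label[drop]] <- 0L
  relabel_map(lab, lumina$pixel_size_um)
}

#' Segment bona-fide airspaces from an RGB section raster
#'
#' Composition of the full segmentation flowchart: green-channel
#' extraction, unimodal thresholding (unless a fixed threshold is given),
#' lumen labeling, thick-wall erosion, convex hulls at downsampled
#' resolution, and centroid-intersection vessel removal. The final label
#' map is at full resolution.
#'
#' @param image an [rgb_raster()]
#' @param threshold fixed intensity threshold, or `NULL` (default) for
#'   automatic unimodal thresholding
#' @param se_size structuring-element size for thick-wall erosion
#'   (default 7)
#' @param se_shape `"square"` or `"disk"`
#' @param downsample_factor downsampling for the hull intersection
#'   (default 4)
#' @param min_area_px optional minimum region area in pixels (default 0 =
#'   no filter)
#' @return an [airspace_map()] of accepted airspaces
#' @export
segment_section <- function(image, threshold = NULL, se_size = 7L,
                            se_shape = "square", downsample_factor = 4L,
                            min_area_px = 0) {
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("segmentation stage [", what, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  gray <- step("green channel", extract_green_channel(image))
  if (is.null(threshold)) {
    h <- step("histogram", tabulate(gray$pixels + 1L, 256L))
    threshold <- step("unimodal threshold", unimodal_threshold(h))
  }
  tissue <- step("binarize", binarize_tissue(gray, threshold))
  lumina <- step("label lumina", label_lumina(tissue))
  thick <- step("thick walls", extract_thick_walls(tissue, se_size, se_shape))
  hulls <- step("convex hulls", wall_convex_hulls(thick, downsample_factor))
  out <- step("remove vessels", remove_vessels(lumina, hulls))
  if (min_area_px > 0 && nrow(out$regions)) {
    lab <- out$label_map
    small <- out$regions$label[out$regions$area_px < min_area_px]
    if (length(small)) {
      lab[lab %in% small] <- 0L
      out <- relabel_map(lab, out$pixel_size_um)
    }
  }
  out
}
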