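#' @useDynLib lungmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' RGB raster container
#'
#' A calibrated 24-bit RGB raster. `pixels` is an `rows x cols x 3` array of
#' integers in `[0, 255]`; `pixel_size_um` is the edge length of a pixel in
#' micrometres.
#'
#' @param pixels numeric array `rows x cols x 3` with values in `[0, 255]`
#' @param pixel_size_um pixel size in micrometres per pixel (> 0)
#' @return an object of class `rgb_raster`
#' @export
rgb_raster <- function(pixels, pixel_size_um) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (dim(pixels)[3] != 3L)
    stop("rgb_raster expects 3 channels, got ", dim(pixels)[3])
  check_pixel_size(pixel_size_um)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "rgb_raster")
}

#' Grayscale raster container
#'
#' @param pixels integer matrix of 8-bit intensities in `[0, 255]`
#' @param pixel_size_um pixel size in micrometres per pixel (> 0)
#' @return an object of class `gray_raster`
#' @export
gray_raster <- function(pixels, pixel_size_um) {
  stopifnot(is.matrix(pixels))
  check_pixel_size(pixel_size_um)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "gray_raster")
}

#' Binary tissue mask
#'
#' @param pixels logical matrix, `TRUE` where parenchyma tissue (walls) is
#'   present
#' @param pixel_size_um pixel size in micrometres per pixel
#' @return an object of class `tissue_mask`
#' @export
tissue_mask <- function(pixels, pixel_size_um) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  check_pixel_size(pixel_size_um)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "tissue_mask")
}

#' Labeled airspace map
#'
#' Integer label raster (0 = wall/background) plus a per-region table with
#' pixel area and centroid. Labels are contiguous positive integers.
#'
#' @param label_map integer matrix of region labels
#' @param regions data.frame with columns `label`, `area_px`,
#'   `centroid_row`, `centroid_col`
#' @param pixel_size_um pixel size in micrometres per pixel
#' @return an object of class `airspace_map`
#' @export
airspace_map <- function(label_map, regions, pixel_size_um) {
  stopifnot(is.matrix(label_map))
  check_pixel_size(pixel_size_um)
  stopifnot(all(c("label", "area_px", "centroid_row", "centroid_col")
                %in% names(regions)))
  if (nrow(regions) && !identical(as.integer(regions$label),
                                  seq_len(nrow(regions))))
    stop("region labels must be contiguous positive integers 1..n")
  if (any(regions$area_px <= 0)) stop("all listed regions must have area > 0")
  structure(list(label_map = label_map, regions = regions,
                 pixel_size_um = pixel_size_um),
            class = "airspace_map")
}

#' @export
print.airspace_map <- function(x, ...) {
  cat("airspace_map:", nrow(x$regions), "regions,",
      paste(dim(x$label_map), collapse = " x "), "px at",
      x$pixel_size_um, "um/px\n")
  invisible(x)
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  invisible(TRUE)
}

# ---- raster file I/O -------------------------------------------------------

#' Read a calibrated RGB raster from disk
#'
#' Supported formats: PNG (8/16 bit, via the png package) and ASCII NetPBM
#' (`.ppm` P3 / `.pgm` P2, plain-text; grayscale images are expanded to three
#' identical channels). Pixel size is a user-supplied calibration, never read
#' from metadata.
#'
#' @param path image file path
#' @param pixel_size_um calibration in micrometres per pixel
#' @return an [rgb_raster()]
#' @export
read_raster <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    a <- a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE] # drop alpha
    if (dim(a)[3] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
    return(rgb_raster(round(a * 255), pixel_size_um))
  }
  if (ext %in% c("ppm", "pgm")) return(read_pnm(path, pixel_size_um))
  stop("unsupported raster format: .", ext, " (use .png, .ppm or .pgm)")
}

#' Write an RGB raster to disk
#'
#' @param image an [rgb_raster()]
#' @param path destination; format chosen by extension (`.png` or `.ppm`)
#' @return `path`, invisibly
#' @export
write_raster <- function(image, path) {
  stopifnot(inherits(image, "rgb_raster"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels / 255, path)
  } else if (ext == "ppm") {
    write_pnm(image$pixels, path)
  } else stop("unsupported output format: .", ext)
  invisible(path)
}

# Plain-text NetPBM: P2 (grayscale) and P3 (RGB), maxval 255.
read_pnm <- function(path, pixel_size_um) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3")) stop("unsupported NetPBM magic: ", magic)
  hdr <- as.integer(tok[2:4])
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  vals <- as.numeric(tok[-(1:4)]) * (255 / maxval)
  if (magic == "P2") {
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    a <- array(0, c(h, w, 3)); a[, , 1] <- m; a[, , 2] <- m; a[, , 3] <- m
  } else {
    a <- array(0, c(h, w, 3))
    v <- matrix(vals, ncol = 3, byrow = TRUE)
    for (ch in 1:3) a[, , ch] <- matrix(v[, ch], nrow = h, byrow = TRUE)
  }
  rgb_raster(round(a), pixel_size_um)
}

write_pnm <- function(pixels, path) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  v <- matrix(0L, nrow = h * w, ncol = 3)
  for (ch in 1:3) v[, ch] <- as.integer(t(pixels[, , ch]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  write(t(v), con, ncolumns = 12)
  invisible(path)
}

#' Write a label map as a 16-bit-equivalent PNG
#'
#' Labels (at most 65535) are split across two 8-bit channels of an RGB
#' PNG: the red channel holds the high byte and the green channel the low
#' byte. Use [read_label_map()] to recover the integer raster.
#'
#' @param map an [airspace_map()]
#' @param path destination `.png` path
#' @return `path`, invisibly
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "airspace_map"))
  if (max(map$label_map) > 65535L) stop("more than 65535 labels")
  a <- array(0, c(dim(map$label_map), 3))
  a[, , 1] <- (map$label_map %/% 256L) / 255
  a[, , 2] <- (map$label_map %% 256L) / 255
  png::writePNG(a, path)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path `.png` path
#' @param pixel_size_um calibration in micrometres per pixel
#' @return an [airspace_map()]
#' @export
read_label_map <- function(path, pixel_size_um) {
  m <- png::readPNG(path)
  if (length(dim(m)) != 3L || dim(m)[3] < 2L)
    stop("not a label-map PNG (expected two channels)")
  lab <- matrix(as.integer(round(m[, , 1] * 255)) * 256L +
                  as.integer(round(m[, , 2] * 255)),
                nrow = dim(m)[1])
  relabel_map(lab, pixel_size_um)
}

# Build an airspace_map from a raw integer label matrix, compacting labels.
relabel_map <- function(lab, pixel_size_um) {
  keep <- sort(unique(lab[lab > 0L]))
  lut <- integer(if (length(keep)) max(keep) else 0L)
  lut[keep] <- seq_along(keep)
  lab2 <- lab
  lab2[lab > 0L] <- lut[lab[lab > 0L]]
  stats <- .region_stats(lab2, length(keep))
  airspace_map(lab2,
               data.frame(label = seq_along(keep),
                          area_px = stats$area_px,
                          centroid_row = stats$centroid_row,
                          centroid_col = stats$centroid_col),
               pixel_size_um)
}
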