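#' Calibrated micrograph
#'
#' A light container tying a pixel grid to its physical calibration and
#' acquisition metadata. Micrographs of submerged fungal cultures are taken
#' at many magnifications (the objects of interest span spores of ~2 um to
#' pellets of ~2 mm), so every image carries its own micrometer-per-pixel
#' factor and all downstream size descriptors are reported in um / um^2.
#'
#' @param pixels Numeric matrix (grayscale, rows = y, columns = x) or a
#'   height x width x 3 array (RGB). Intensities are held as floating point
#'   on the source's declared bit range.
#' @param calibration Micrometers per pixel; must be positive.
#' @param objective_id Free-text objective label (e.g. `"40x"`).
#' @param time_hr Hours since inoculation (optional, `>= 0`).
#' @param condition Cultivation arm, `"standard"` or `"mpec"` (optional).
#' @param bit_depth Declared bit depth of the source (default 8).
#'
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `width`, `height`, `calibration`, `objective_id`, `time_hr`,
#'   `condition`, `bit_depth`.
#' @export
calibrated_image <- function(pixels, calibration, objective_id = NULL,
                             time_hr = NULL, condition = NULL, bit_depth = 8) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L))) {
    abort("`pixels` must be a numeric matrix or a height x width x 3 array.")
  }
  if (length(dim(pixels)) == 3L && dim(pixels)[3] != 3L) {
    abort(sprintf("RGB pixel arrays must have 3 channels, got %d.", dim(pixels)[3]))
  }
  if (!is.numeric(calibration) || length(calibration) != 1L ||
      is.na(calibration) || calibration <= 0) {
    abort("`calibration` (um per pixel) must be a single positive number.")
  }
  if (!is.null(time_hr) && (!is.numeric(time_hr) || time_hr < 0)) {
    abort("`time_hr` must be a non-negative number.")
  }
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("standard", "mpec"))
  }
  structure(
    list(
      pixels = pixels,
      width = ncol_px(pixels),
      height = nrow_px(pixels),
      calibration = as.numeric(calibration),
      objective_id = objective_id,
      time_hr = time_hr,
      condition = condition,
      bit_depth = bit_depth
    ),
    class = "calibrated_image"
  )
}

nrow_px <- function(pixels) dim(pixels)[1]
ncol_px <- function(pixels) dim(pixels)[2]

is_rgb <- function(img) length(dim(img$pixels)) == 3L

#' @export
print.calibrated_image <- function(x, ...) {
  kind <- if (is_rgb(x)) "RGB" else "grayscale"
  cat(sprintf("<calibrated_image> %d x %d px (%s), %.4g um/px",
              x$width, x$height, kind, x$calibration))
  if (!is.null(x$time_hr)) cat(sprintf(", t = %g hr", x$time_hr))
  if (!is.null(x$condition)) cat(sprintf(", %s", x$condition))
  cat("\n")
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) c(x$height, x$width)

#' Load a calibrated micrograph from TIFF or PNG
#'
#' Reads an 8- or 16-bit grayscale or RGB image and attaches the physical
#' calibration. The readers return intensities on \[0, 1\]; they are put
#' back on the declared bit range (0..255 or 0..65535).
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams calibrated_image
#' @return A [calibrated_image].
#' @export
load_image <- function(path, calibration, objective_id = NULL,
                       time_hr = NULL, condition = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("Image file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  bit_depth <- 8L
  if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(tiff::readTIFF(path, info = TRUE),
                   error = function(e) abort(sprintf(
                     "Failed to read TIFF '%s': %s", path, conditionMessage(e))))
    bit_depth <- attr(px, "bits.per.sample") %||% 8L
    px <- px * (2^bit_depth - 1)  # reader returns [0, 1]
  } else if (ext == "png") {
    px <- tryCatch(png::readPNG(path, info = TRUE),
                   error = function(e) abort(sprintf(
                     "Failed to read PNG '%s': %s", path, conditionMessage(e))))
    bit_depth <- attr(px, "info")$bit.depth %||% 8L
    px <- px * (2^bit_depth - 1)
  } else {
    abort(sprintf("Unsupported image format '.%s' for '%s' (use TIFF or PNG).",
                  ext, path))
  }
  # drop a trailing alpha channel if present
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  if (length(dim(px)) == 3L && dim(px)[3] == 2L) px <- px[, , 1]
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1]
  px <- px * 1.0
  calibrated_image(px, calibration, objective_id = objective_id,
                   time_hr = time_hr, condition = condition,
                   bit_depth = bit_depth)
}

#' Extract the green plane of an RGB micrograph
#'
#' Segmentation runs on the green channel of the RGB camera image; the green
#' plane of a phase-contrast micrograph carries the full object-background
#' contrast. Grayscale input is returned unchanged.
#'
#' @param img A [calibrated_image].
#' @return A grayscale [calibrated_image] with the same calibration.
#' @export
extract_green_plane <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  if (!is_rgb(img)) return(img)
  out <- img
  out$pixels <- img$pixels[, , 2]
  out
}

# Pad a matrix by `r` pixels on all sides with edge replication.
pad_replicate <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  m[c(rep(1L, r), seq_len(h), rep(h, r)),
    c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
}

# exact 3 x 3 median via Paeth's 19-comparator median-of-9 network,
# vectorized over the whole image
median9 <- function(p) {
  cmpx <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  cmpx(2, 3); cmpx(5, 6); cmpx(8, 9)
  cmpx(1, 2); cmpx(4, 5); cmpx(7, 8)
  cmpx(2, 3); cmpx(5, 6); cmpx(8, 9)
  cmpx(1, 4); cmpx(6, 9); cmpx(5, 8)
  cmpx(4, 7); cmpx(2, 5); cmpx(3, 6)
  cmpx(5, 8); cmpx(5, 3); cmpx(7, 5)
  cmpx(5, 3)
  p[[5]]
}

#' Median smoothing
#'
#' Replaces each pixel by the median of its (2 * radius + 1)^2 neighborhood,
#' smoothing object edges before edge detection. Borders are handled by edge
#' replication, so the output has the size of the input and the size and
#' shape of objects are preserved. The default 3 x 3 neighborhood is
#' computed exactly by a vectorized median-of-9 network; larger radii use
#' the constant-time median filter of EBImage on a 16-bit quantization of
#' the intensity range.
#'
#' @param img A grayscale [calibrated_image].
#' @param radius Neighborhood radius in pixels (`>= 1`).
#' @return A smoothed [calibrated_image].
#' @export
median_smooth <- function(img, radius = 1) {
  stopifnot(inherits(img, "calibrated_image"))
  if (is_rgb(img)) abort("`median_smooth()` expects a grayscale image; run `extract_green_plane()` first.")
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1 ||
      radius != round(radius)) {
    abort("`radius` must be an integer >= 1.")
  }
  radius <- as.integer(radius)
  m <- img$pixels
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(img)  # median of constants
  h <- nrow(m); w <- ncol(m)
  padded <- pad_replicate(m, radius)
  out <- img
  if (radius == 1L) {
    ri <- 1L + seq_len(h); ci <- 1L + seq_len(w)
    p <- list()
    k <- 0L
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      p[[k]] <- padded[ri + di, ci + dj, drop = FALSE]
    }
    out$pixels <- median9(p)
  } else {
    norm <- (padded - lo) / (hi - lo)
    sm <- EBImage::medianFilter(norm, size = radius)
    out$pixels <- sm[radius + seq_len(h), radius + seq_len(w)] * (hi - lo) + lo
  }
  out
}

#' Sobel gradient magnitude
#'
#' Edge detection with the standard 3 x 3 Sobel operator: per-pixel gradient
#' magnitude `sqrt(Gx^2 + Gy^2)` from the horizontal kernel
#' `[[-1,0,1],[-2,0,2],[-1,0,1]]` and its transpose. Borders are handled by
#' edge replication. Using enhanced edges rather than raw intensity makes
#' segmentation independent of the absolute shade of the mycelial objects,
#' which varies with objective and growth stage.
#'
#' @param img A grayscale [calibrated_image].
#' @return A [calibrated_image] holding the non-negative gradient magnitude.
#' @export
sobel_edge_magnitude <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  if (is_rgb(img)) abort("`sobel_edge_magnitude()` expects a grayscale image.")
  m <- img$pixels
  h <- nrow(m); w <- ncol(m)
  p <- pad_replicate(m, 1L)
  ri <- 1L + seq_len(h); ci <- 1L + seq_len(w)
  nw <- p[ri - 1L, ci - 1L, drop = FALSE]; n <- p[ri - 1L, ci, drop = FALSE]
  ne <- p[ri - 1L, ci + 1L, drop = FALSE]
  wv <- p[ri, ci - 1L, drop = FALSE];      ev <- p[ri, ci + 1L, drop = FALSE]
  sw <- p[ri + 1L, ci - 1L, drop = FALSE]; s <- p[ri + 1L, ci, drop = FALSE]
  se <- p[ri + 1L, ci + 1L, drop = FALSE]
  gx <- (ne + 2 * ev + se) - (nw + 2 * wv + sw)
  gy <- (sw + 2 * s + se) - (nw + 2 * n + ne)
  out <- img
  out$pixels <- sqrt(gx^2 + gy^2)
  out
}
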