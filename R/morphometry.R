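#' @name morphometry
#' @title Per-object size and shape descriptors
#'
#' @description
#' The descriptor suite computed for every segmented mycelial object:
#' projected area `A` (um^2), mean diameter `D` and maximum Feret diameter
#' `Dmax` (um), elongation `E` (squared ratio of longitudinal to transversal
#' pixel deviation along the principal axis; 1 = circular), roughness /
#' solidity `R` (projected over convex area; 1 = smooth convex), circularity
#' (`4 pi A / P^2`), and the dimensionless morphology number
#' `Mo = 2 sqrt(A S) / (sqrt(pi) Dmax E)`, which is 1 for an ideal disk,
#' stays near 1 (>= 0.6) for circular objects such as ungerminated spores
#' and ideal pellets, and falls below 0.5 once filamentous morphology
#' evolves.
#'
#' All operations take a logical pixel mask (rows = y, columns = x) and,
#' where a physical unit is produced, the um-per-pixel calibration.
NULL

check_mask <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 2L) {
    abort("`mask` must be a logical matrix.")
  }
  if (!any(mask)) abort("`mask` is empty: descriptors need at least one pixel.")
  invisible(mask)
}

# pixel coordinates of a mask: data frame with x (col) and y (row), 1-based
mask_xy <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  list(x = as.numeric(ij[, 2]), y = as.numeric(ij[, 1]))
}

# pixels of the mask with at least one 4-neighbor outside (or on the frame edge)
boundary_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  inside <- matrix(FALSE, h, w)
  if (h > 2 && w > 2) {
    inside[2:(h - 1), 2:(w - 1)] <-
      mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
      mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  }
  mask & !inside
}

#' Projected area
#'
#' Pixel count of the object multiplied by the squared calibration unit.
#'
#' @param mask Logical matrix marking the object's pixels.
#' @param calibration Micrometers per pixel.
#' @return Projected area in um^2.
#' @export
projected_area <- function(mask, calibration) {
  check_mask(mask)
  stopifnot(calibration > 0)
  sum(mask) * calibration^2
}

#' Mean diameter
#'
#' The average, over `n_dirs` equally spaced directions in `[0, pi)`, of the
#' chord through the object's center of gravity: in each direction the chord
#' is traced outward from the centroid in sub-pixel steps until it leaves
#' the object, so for non-convex objects it is the contiguous run containing
#' the centroid. If the centroid itself falls outside the mask (strongly
#' non-convex objects) the maximum Feret diameter is returned instead and
#' the result carries attribute `flag = "centroid_outside"`.
#'
#' @inheritParams projected_area
#' @param n_dirs Number of chord directions (default 180, i.e. 1 degree).
#' @param step Sub-pixel step along each chord, in pixels.
#' @return Mean diameter in um (attribute `flag` set when the centroid
#'   fallback is used).
#' @export
mean_diameter <- function(mask, calibration, n_dirs = 180, step = 0.25) {
  check_mask(mask)
  stopifnot(calibration > 0, n_dirs >= 1)
  xy <- mask_xy(mask)
  cx <- mean(xy$x); cy <- mean(xy$y)
  h <- nrow(mask); w <- ncol(mask)
  ci <- round(cy); cj <- round(cx)
  if (ci < 1 || ci > h || cj < 1 || cj > w || !mask[ci, cj]) {
    d <- max_diameter(mask, calibration)
    attr(d, "flag") <- "centroid_outside"
    return(d)
  }
  tmax <- sqrt(h^2 + w^2)
  tt <- seq(step, tmax, by = step)
  ray_extent <- function(ux, uy) {
    px <- round(cx + tt * ux); py <- round(cy + tt * uy)
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    inside <- ok
    inside[ok] <- mask[cbind(py[ok], px[ok])]
    k <- match(FALSE, inside)
    if (is.na(k)) tmax else (k - 0.5) * step
  }
  theta <- (seq_len(n_dirs) - 1L) * pi / n_dirs
  chords <- vapply(theta, function(th) {
    ray_extent(cos(th), sin(th)) + ray_extent(-cos(th), -sin(th))
  }, numeric(1))
  mean(chords) * calibration
}

#' Maximum Feret diameter
#'
#' The maximum pairwise distance between boundary pixel centers (computed
#' on the convex hull of the boundary for speed) plus the 1 px footprint of
#' the two end pixels, so a digital disk of radius r reports ~2r and a
#' w x h rectangle ~sqrt(w^2 + h^2). A single-pixel object reports 1 px.
#'
#' @inheritParams projected_area
#' @return Maximum diameter in um.
#' @export
max_diameter <- function(mask, calibration) {
  check_mask(mask)
  stopifnot(calibration > 0)
  xy <- mask_xy(boundary_mask(mask))
  if (length(xy$x) == 1L) return(1 * calibration)
  hull <- grDevices::chull(xy$x, xy$y)
  hx <- xy$x[hull]; hy <- xy$y[hull]
  d2 <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
  (sqrt(max(d2)) + 1) * calibration
}

#' Elongation
#'
#' The squared quotient of the longitudinal and transversal deviation of the
#' object's pixels along the regression (major principal) axis: the ratio of
#' the larger to the smaller eigenvalue of the pixel-coordinate covariance.
#' `E = 1` for an ideally circular object; the more line-like the object,
#' the larger `E`. A single-pixel object has `E = 1` by definition; a mask
#' with zero transversal spread (a perfect pixel line) returns `Inf` with
#' attribute `flag = "elongation_infinite"` and is excluded from summaries.
#'
#' @inheritParams projected_area
#' @return Dimensionless elongation `>= 1`.
#' @export
elongation <- function(mask) {
  check_mask(mask)
  xy <- mask_xy(mask)
  n <- length(xy$x)
  if (n == 1L) return(1)
  x <- xy$x - mean(xy$x); y <- xy$y - mean(xy$y)
  cov <- matrix(c(sum(x * x), sum(x * y), sum(x * y), sum(y * y)), 2, 2) / n
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) {
    out <- Inf
    attr(out, "flag") <- "elongation_infinite"
    return(out)
  }
  ev[1] / ev[2]
}

# rasterized convex-hull pixel count of a mask (pixel centers inside or on
# the hull polygon of the mask's pixel centers)
convex_hull_pixels <- function(mask) {
  xy <- mask_xy(mask)
  n <- length(xy$x)
  if (n <= 2L) return(n)
  hull <- grDevices::chull(xy$x, xy$y)
  poly_x <- xy$x[hull]; poly_y <- xy$y[hull]
  xr <- range(xy$x); yr <- range(xy$y)
  gx <- rep(xr[1]:xr[2], times = yr[2] - yr[1] + 1)
  gy <- rep(yr[1]:yr[2], each = xr[2] - xr[1] + 1)
  sum(points_in_polygon(gx, gy, poly_x, poly_y))
}

#' Roughness (solidity)
#'
#' Ratio of the projected area to the area of the rasterized convex hull of
#' the object. `R = 1` for a smooth convex object; protruding filaments on
#' the boundary (hairy pellets) push `R` down.
#'
#' @inheritParams projected_area
#' @return Dimensionless solidity in (0, 1\] up to rasterization tolerance.
#' @export
roughness <- function(mask) {
  check_mask(mask)
  sum(mask) / convex_hull_pixels(mask)
}

#' Circularity
#'
#' `4 pi A / P^2` with the perimeter `P` measured as the length of the
#' traced 8-connected boundary chain (diagonal steps weighted sqrt(2)).
#' Objects too small to trace (< 5 boundary points) fall back on the crack
#' perimeter (count of exposed pixel edges). 1 for an ideal disk, ~pi/4 for
#' a square, near 0 for a thin line.
#'
#' @inheritParams projected_area
#' @param clip Clip the value at 1 (rasterization can push a digital disk
#'   slightly above 1). Default `TRUE`.
#' @return Dimensionless circularity.
#' @export
circularity <- function(mask, clip = TRUE) {
  check_mask(mask)
  p <- mask_perimeter(mask)
  val <- 4 * pi * sum(mask) / p^2
  if (clip) min(val, 1) else val
}

mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(mask * 1L)
  pts <- if (length(oc) >= 1L) oc[[1]] else matrix(numeric(0), 0, 2)
  if (nrow(pts) >= 5L) {
    dx <- diff(c(pts[, 1], pts[1, 1]))
    dy <- diff(c(pts[, 2], pts[1, 2]))
    sum(sqrt(dx^2 + dy^2))
  } else {
    # crack perimeter: 4n minus 2 per 4-adjacent pixel pair
    n <- sum(mask)
    horiz <- sum(mask[, -ncol(mask), drop = FALSE] & mask[, -1, drop = FALSE])
    vert <- sum(mask[-nrow(mask), , drop = FALSE] & mask[-1, , drop = FALSE])
    4 * n - 2 * (horiz + vert)
  }
}

#' Morphology number
#'
#' The dimensionless composite `Mo = 2 sqrt(A S) / (sqrt(pi) Dmax E)` of
#' projected area `A`, solidity `S`, elongation `E` and maximum diameter
#' `Dmax`. For an ideal disk (`A = pi r^2`, `S = E = 1`, `Dmax = 2 r`) the
#' closed form gives exactly 1; values not lower than 0.6 indicate circular
#' objects (ungerminated spores, ideal pellets), values below 0.5
#' filamentous or irregular morphology.
#'
#' @param A Projected area, um^2 (> 0).
#' @param S Solidity / roughness (> 0; at most 1 up to rasterization
#'   tolerance).
#' @param E Elongation (>= 1). `Inf` yields `NA` (flagged objects are
#'   excluded from summaries).
#' @param Dmax Maximum Feret diameter, um (> 0).
#' @return Dimensionless morphology number in (0, 1\] up to rasterization
#'   tolerance.
#' @export
morphology_number <- function(A, S, E, Dmax) {
  stopifnot(length(A) == length(S), length(S) == length(E),
            length(E) == length(Dmax))
  bad <- is.finite(A) & is.finite(S) & is.finite(Dmax) &
    (A <= 0 | S <= 0 | Dmax <= 0 | (is.finite(E) & E <= 0))
  if (any(bad)) abort("`morphology_number()` needs strictly positive A, S, E and Dmax.")
  out <- 2 * sqrt(A * S) / (sqrt(pi) * Dmax * E)
  out[!is.finite(E)] <- NA_real_
  out
}

#' Measure all objects of a labeled scene
#'
#' Computes the full descriptor bundle for every labeled object and returns
#' one row per object. Unclipped values are reported alongside
#' clipped-to-\[0, 1\] convenience columns (`R_clip`, `circularity_clip`,
#' `Mo_clip`); rasterization can push the raw values slightly (up to ~2%)
#' above 1. Centroids are reported 0-based, x rightward, y downward.
#'
#' @param scene A [labeled_scene].
#' @param image Image identifier carried into the `image` column (default
#'   `NA`).
#' @param time_hr,condition Acquisition metadata carried into the output.
#' @param n_dirs Chord directions for [mean_diameter()].
#' @return A tibble with columns `image`, `time_hr`, `condition`,
#'   `object_id`, `n_pixels`, `A_um2`, `D_um`, `Dmax_um`, `E`, `R`,
#'   `circularity`, `Mo`, `centroid_x`, `centroid_y`, `flags`,
#'   `convex_area_um2`, `R_clip`, `circularity_clip`, `Mo_clip`. The
#'   adopted morphology-number form is recorded in attribute `mo_form`.
#' @export
measure_objects <- function(scene, image = NA_character_, time_hr = NA_real_,
                            condition = NA_character_, n_dirs = 180) {
  stopifnot(inherits(scene, "labeled_scene"))
  cal <- scene$calibration
  labs <- scene$labels
  rows <- purrr::map(object_indices(scene), function(idx) {
    cm <- crop_mask(nrow(labs), idx)
    mask <- cm$mask
    flags <- character(0)
    n_px <- sum(mask)
    A <- n_px * cal^2
    hull_px <- convex_hull_pixels(mask)
    E <- elongation(mask)
    if (!is.null(attr(E, "flag"))) flags <- c(flags, attr(E, "flag"))
    D <- mean_diameter(mask, cal, n_dirs = n_dirs)
    if (!is.null(attr(D, "flag"))) flags <- c(flags, attr(D, "flag"))
    Dmax <- max_diameter(mask, cal)
    R <- n_px / hull_px
    circ <- circularity(mask, clip = FALSE)
    Mo <- if (is.finite(E)) morphology_number(A, R, as.numeric(E), Dmax) else NA_real_
    xy <- mask_xy(mask)
    tibble::tibble(
      n_pixels = n_px, A_um2 = A,
      D_um = as.numeric(D), Dmax_um = Dmax,
      E = as.numeric(E), R = R, circularity = circ, Mo = Mo,
      centroid_x = mean(xy$x) - 1 + cm$x0, centroid_y = mean(xy$y) - 1 + cm$y0,
      flags = paste(flags, collapse = ";"),
      convex_area_um2 = hull_px * cal^2
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      n_pixels = integer(0), A_um2 = numeric(0), D_um = numeric(0),
      Dmax_um = numeric(0), E = numeric(0), R = numeric(0),
      circularity = numeric(0), Mo = numeric(0), centroid_x = numeric(0),
      centroid_y = numeric(0), flags = character(0),
      convex_area_um2 = numeric(0)
    )
  }
  out <- dplyr::mutate(out,
    image = image, time_hr = time_hr, condition = condition,
    object_id = dplyr::row_number(),
    R_clip = pmin(.data$R, 1),
    circularity_clip = pmin(.data$circularity, 1),
    Mo_clip = pmin(.data$Mo, 1)
  )
  out <- dplyr::select(out, "image", "time_hr", "condition", "object_id",
                       "n_pixels", "A_um2", "D_um", "Dmax_um", "E", "R",
                       "circularity", "Mo", "centroid_x", "centroid_y",
                       "flags", "convex_area_um2", "R_clip",
                       "circularity_clip", "Mo_clip")
  attr(out, "mo_form") <- "Mo = 2*sqrt(A*S) / (sqrt(pi)*Dmax*E)"
  out
}
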