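#' Labeled scene of mycelial objects
#'
#' An integer label grid assigning each pixel to the background (0) or to
#' one mycelial object (1..n, 8-connected, no gaps), together with the
#' physical calibration inherited from the source micrograph.
#'
#' @param labels Integer matrix of labels.
#' @param calibration Micrometers per pixel (> 0).
#' @return An object of class `labeled_scene` with fields `labels`,
#'   `calibration`, `n_objects`.
#' @export
labeled_scene <- function(labels, calibration) {
  if (!is.numeric(labels) || length(dim(labels)) != 2L) {
    abort("`labels` must be an integer matrix.")
  }
  stopifnot(calibration > 0)
  labs <- sort(unique(as.integer(labels[labels > 0])))
  n <- length(labs)
  if (n > 0 && !identical(labs, seq_len(n))) {
    abort("Object labels must be 1..n_objects with no gaps.")
  }
  structure(
    list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
         calibration = as.numeric(calibration),
         n_objects = n),
    class = "labeled_scene"
  )
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene> %d x %d px, %d object(s), %.4g um/px\n",
              ncol(x$labels), nrow(x$labels), x$n_objects, x$calibration))
  invisible(x)
}

# linear pixel indices per object, ordered by label
object_indices <- function(scene) {
  labs <- scene$labels
  pos <- which(labs > 0)
  split(pos, factor(labs[pos], levels = seq_len(scene$n_objects)))
}

# crop the pixels at linear indices `idx` (in a frame of height `h`) to
# their bounding box; returns the logical mask plus the 0-based offsets of
# the box in the full frame
crop_mask <- function(h, idx) {
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  r0 <- min(rows); c0 <- min(cols)
  mask <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  mask[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  list(mask = mask, x0 = c0 - 1L, y0 = r0 - 1L)
}

# full-frame logical mask of one object
object_mask <- function(scene, id) {
  scene$labels == id
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged with a union-find pass
label_components <- function(bw) {
  L <- EBImage::bwlabel(bw * 1)
  n <- max(L)
  if (n == 0) return(matrix(0L, nrow(bw), ncol(bw)))
  h <- nrow(L); w <- ncol(L)
  a1 <- L[-h, -w]; b1 <- L[-1, -1]   # down-right diagonal
  a2 <- L[-h, -1]; b2 <- L[-1, -w]   # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- matrix(0L, h, w)
  pos <- L > 0
  out[pos] <- remap[L[pos]]
  out
}

#' Segment mycelial objects from enhanced edges
#'
#' Turns a Sobel gradient-magnitude image into labeled objects: pixels above
#' the edge threshold form contours, the contours are morphologically closed
#' to bridge small gaps, interior holes are filled, the filled regions are
#' eroded by `edge_compensation` pixels (the Sobel ridge of a sharp boundary
#' straddles it by about one pixel on each side, so the filled region
#' over-covers the object by that much), and 8-connected components are
#' labeled 1..n.
#'
#' @param edges A [calibrated_image] holding a non-negative gradient
#'   magnitude (from [sobel_edge_magnitude()]).
#' @param edge_threshold `"otsu"` (threshold chosen by Otsu's method on the
#'   gradient histogram) or an absolute magnitude.
#' @param closing_radius Radius (px) of the morphological closing that seals
#'   1-2 px contour gaps; 0 disables it.
#' @param edge_compensation Erosion (px) applied after hole filling; 0
#'   disables it.
#' @return A [labeled_scene]; an all-zero edge image yields an empty scene.
#' @export
segment_from_edges <- function(edges, edge_threshold = "otsu",
                               closing_radius = 2, edge_compensation = 1) {
  stopifnot(inherits(edges, "calibrated_image"))
  m <- edges$pixels
  if (min(m) < 0) abort("`edges` must be a non-negative gradient image.")
  empty <- function() labeled_scene(matrix(0L, nrow(m), ncol(m)), edges$calibration)
  hi <- max(m)
  if (hi == 0) return(empty())
  if (identical(edge_threshold, "otsu")) {
    thr <- EBImage::otsu(EBImage::Image(m / hi)) * hi
  } else if (is.numeric(edge_threshold) && length(edge_threshold) == 1L) {
    thr <- edge_threshold
  } else {
    abort('`edge_threshold` must be "otsu" or a single number.')
  }
  bw <- m > thr
  if (!any(bw)) return(empty())
  if (closing_radius > 0) {
    kern <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    bw <- EBImage::closing(bw * 1, kern) > 0.5
  }
  bw <- EBImage::fillHull(bw * 1) > 0.5
  if (edge_compensation > 0) {
    # 4-neighbor structuring element: a full 3 x 3 erosion removes ~1.2 px
    # of boundary and biases small-object areas low; the cross removes ~1 px
    cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
    for (k in seq_len(round(edge_compensation))) {
      bw <- EBImage::erode(bw * 1, cross) > 0.5
    }
  }
  # 3 x 3 majority vote: rounds off the +-1 px boundary quantization the
  # thresholded edge band leaves behind, without a systematic area bias
  bw <- majority_smooth(bw)
  if (!any(bw)) return(empty())
  labeled_scene(label_components(bw), edges$calibration)
}

majority_smooth <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  p <- pad_replicate(bw * 1L, 1L)
  ri <- 1L + seq_len(h); ci <- 1L + seq_len(w)
  s <- p[ri - 1L, ci - 1L] + p[ri - 1L, ci] + p[ri - 1L, ci + 1L] +
    p[ri, ci - 1L] + p[ri, ci] + p[ri, ci + 1L] +
    p[ri + 1L, ci - 1L] + p[ri + 1L, ci] + p[ri + 1L, ci + 1L]
  s >= 5
}

#' Debris / validity filter rule
#'
#' Size and shape rules used to remove debris and invalid objects: area
#' rules in um^2, circularity rules dimensionless in (0, 1\], and
#' `border_exclusion`, which removes objects touching the frame border
#' (threshold = border margin in pixels). Mineral microparticle debris
#' (~10 um angular grains) is typically removed in spore images by a
#' minimum-circularity rule, and small debris in pellet images by a
#' minimum-area rule.
#'
#' @param kind One of `"min_area"`, `"max_area"`, `"min_circularity"`,
#'   `"max_circularity"`, `"border_exclusion"`.
#' @param threshold Positive rule threshold (see above for units).
#' @return A `filter_rule` object.
#' @export
filter_rule <- function(kind, threshold = 1) {
  kind <- match.arg(kind, c("min_area", "max_area", "min_circularity",
                            "max_circularity", "border_exclusion"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  if (grepl("circularity", kind) && threshold > 1) {
    abort("Circularity thresholds must lie in (0, 1].")
  }
  structure(list(kind = kind, threshold = threshold), class = "filter_rule")
}

# rebuild a scene keeping only `keep` (old labels), relabeled 1..n' in
# ascending old-label order; masks are preserved pixel-for-pixel
relabel_keep <- function(scene, keep) {
  labs <- scene$labels
  keep <- sort(keep)
  map <- integer(scene$n_objects)
  map[keep] <- seq_along(keep)
  pos <- labs > 0
  out <- matrix(0L, nrow(labs), ncol(labs))
  out[pos] <- map[labs[pos]]
  labeled_scene(out, scene$calibration)
}

# TRUE for each object id whose mask touches the frame border within `margin`
touches_border <- function(scene, margin = 1) {
  labs <- scene$labels
  h <- nrow(labs); w <- ncol(labs)
  margin <- max(1L, as.integer(margin))
  edge <- unique(c(labs[seq_len(min(margin, h)), ],
                   labs[seq(max(1L, h - margin + 1L), h), ],
                   labs[, seq_len(min(margin, w))],
                   labs[, seq(max(1L, w - margin + 1L), w)]))
  seq_len(scene$n_objects) %in% edge
}

#' Apply size and shape filters
#'
#' Removes every object that violates any rule and relabels the survivors
#' 1..n'. The surviving set does not depend on the order of the rules. A
#' removal report (object id and the violated rule) is attached as attribute
#' `"removals"`.
#'
#' @param scene A [labeled_scene].
#' @param rules A [filter_rule] or list of them; an empty list leaves the
#'   scene unchanged.
#' @param morpho Optional descriptor table from [measure_objects()] for this
#'   scene (computed on the fly if missing).
#' @return The filtered [labeled_scene] with attribute `removals`, a tibble
#'   with columns `object_id` (pre-filter label) and `rule`.
#' @export
apply_filters <- function(scene, rules, morpho = NULL) {
  stopifnot(inherits(scene, "labeled_scene"))
  if (inherits(rules, "filter_rule")) rules <- list(rules)
  if (!is.list(rules) || !all(vapply(rules, inherits, logical(1), "filter_rule"))) {
    abort("`rules` must be a list of `filter_rule` objects.")
  }
  if (length(rules) == 0L || scene$n_objects == 0L) {
    attr(scene, "removals") <- tibble::tibble(object_id = integer(0),
                                              rule = character(0))
    return(scene)
  }
  if (is.null(morpho)) morpho <- measure_objects(scene)
  stopifnot(nrow(morpho) == scene$n_objects)
  violated <- rep(NA_character_, scene$n_objects)
  for (rule in rules) {
    bad <- switch(rule$kind,
      min_area = morpho$A_um2 < rule$threshold,
      max_area = morpho$A_um2 > rule$threshold,
      min_circularity = morpho$circularity < rule$threshold,
      max_circularity = morpho$circularity > rule$threshold,
      border_exclusion = touches_border(scene, rule$threshold)
    )
    violated[bad & is.na(violated)] <- rule$kind
  }
  keep <- which(is.na(violated))
  out <- relabel_keep(scene, keep)
  attr(out, "removals") <- tibble::tibble(
    object_id = which(!is.na(violated)),
    rule = violated[!is.na(violated)]
  )
  out
}

# Even-odd point-in-polygon test with inclusive boundary. Coordinates are
# in the same (pixel) system for points and polygon vertices.
points_in_polygon <- function(px, py, poly_x, poly_y, eps = 1e-9) {
  n <- length(px)
  m <- length(poly_x)
  inside <- rep(FALSE, n)
  on_edge <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    x1 <- poly_x[j]; y1 <- poly_y[j]
    x2 <- poly_x[i]; y2 <- poly_y[i]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- px[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    # on-segment test
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
    on_edge <- on_edge |
      (abs(cross) <= eps * max(1, sqrt(seg_len2)) & dot >= -eps &
         dot <= seg_len2 + eps)
    j <- i
  }
  inside | on_edge
}

validate_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L || anyNA(polygon)) {
    abort("An AOI polygon needs >= 3 (x, y) vertices.")
  }
  if (nrow(unique(polygon)) < 3L) abort("Degenerate AOI polygon: fewer than 3 distinct vertices.")
  # shoelace area must be non-zero
  x <- polygon[, 1]; y <- polygon[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) < 1e-9) abort("Degenerate AOI polygon: zero area.")
  # simplicity: no two non-adjacent edges may intersect
  nv <- nrow(polygon)
  seg <- cbind(polygon, polygon[c(2:nv, 1), ])
  segs_intersect <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (nv > 3) {
    for (i in seq_len(nv - 2)) {
      for (k in seq(i + 2, nv)) {
        if (i == 1 && k == nv) next  # adjacent through the wrap
        if (segs_intersect(seg[i, ], seg[k, ])) {
          abort("AOI polygon is self-intersecting.")
        }
      }
    }
  }
  polygon
}

#' Restrict a scene to an area of interest
#'
#' Objects whose centroid falls outside the polygon are removed (centroids
#' exactly on the boundary are kept); surviving objects are relabeled.
#' Restricting by centroid rather than clipping pixels means object shapes
#' are never truncated. AOIs emulate the operator-drawn regions used to
#' avoid debris-rich parts of a micrograph.
#'
#' @param scene A [labeled_scene].
#' @param polygon An n x 2 matrix (or data frame) of (x, y) vertices in
#'   0-based pixel coordinates; must be simple with >= 3 vertices.
#' @return The restricted [labeled_scene].
#' @export
apply_aoi <- function(scene, polygon) {
  stopifnot(inherits(scene, "labeled_scene"))
  polygon <- validate_polygon(polygon)
  if (scene$n_objects == 0L) return(scene)
  cents <- purrr::map(object_indices(scene), function(idx) {
    h <- nrow(scene$labels)
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    c(mean(cols) - 1, mean(rows) - 1)  # 0-based (x, y)
  })
  cx <- vapply(cents, `[`, numeric(1), 1)
  cy <- vapply(cents, `[`, numeric(1), 2)
  keep <- which(points_in_polygon(cx, cy, polygon[, 1], polygon[, 2]))
  relabel_keep(scene, keep)
}

#' Read AOI polygons from a text file
#'
#' One polygon per line as comma-separated pixel coordinates
#' `x1,y1,x2,y2,...`.
#'
#' @param path Path to the AOI file.
#' @return A list of n x 2 polygon matrices.
#' @export
read_aoi_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("AOI file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map(lines, function(ln) {
    vals <- suppressWarnings(as.numeric(strsplit(ln, ",")[[1]]))
    if (anyNA(vals) || length(vals) %% 2 != 0) {
      abort(sprintf("Malformed AOI line: '%s'", ln))
    }
    validate_polygon(matrix(vals, ncol = 2, byrow = TRUE))
  })
}
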