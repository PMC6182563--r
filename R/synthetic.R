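#' @name synthetic_scenes
#' @title Synthetic mycelial scenes with ground truth
#'
#' @description
#' Seedable generators for phase-contrast-like micrographs of the
#' morphological stages seen in the first day of a submerged fungal
#' cultivation: spores (circular or lemon-shaped), spore agglomerates built
#' by sequential attachment, germinating objects with protruding germ
#' tubes, branching hyphal clumps, hairy / core-shell / multicore pellets,
#' and angular ~10 um mineral microparticle debris. Scenes carry exact
#' ground-truth masks; true descriptor values are computed by the same
#' morphometry operations applied to the noiseless true masks, which
#' separates rendering and segmentation error from descriptor error.
#'
#' Geometry is modeled, not physics: there is no point-spread function, no
#' phase ring, no growth kinetics and no particle-hypha adhesion. Identical
#' specifications (including the seed) produce byte-identical scenes,
#' truths and renderings.
NULL

# evaluate `code` under `seed`, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Create an empty synthetic scene
#'
#' @param width,height Frame size in pixels (defaults: the native camera
#'   resolution 2448 x 1920).
#' @param calibration Micrometers per pixel.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @param background Background intensity (8-bit scale; bright field).
#' @param object_intensity Intensity of mycelial object pixels (dark).
#' @param debris_intensity Intensity of microparticle debris pixels.
#' @param noise_sd Additive Gaussian noise SD applied at rendering.
#' @param halo_width Width (px) of the bright rim rendered around objects;
#'   0 disables it.
#' @param time_hr,condition Acquisition metadata propagated to renderings
#'   and measurements.
#' @return A `myco_scene` object.
#' @export
scene_new <- function(width = 2448, height = 1920, calibration = 1, seed = 1,
                      background = 200, object_intensity = 60,
                      debris_intensity = 110, noise_sd = 0, halo_width = 0,
                      time_hr = NULL, condition = NULL) {
  stopifnot(width >= 1, height >= 1, calibration > 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         calibration = calibration, seed = as.integer(seed),
         background = background, object_intensity = object_intensity,
         debris_intensity = debris_intensity, noise_sd = noise_sd,
         halo_width = halo_width, time_hr = time_hr, condition = condition,
         objects = list(),
         placed = data.frame(cx = numeric(0), cy = numeric(0),
                             reach = numeric(0))),
    class = "myco_scene"
  )
}

#' @export
print.myco_scene <- function(x, ...) {
  n_myc <- sum(vapply(x$objects, function(o) isTRUE(o$mycelial), logical(1)))
  cat(sprintf(
    "<myco_scene> %d x %d px, %.4g um/px, seed %d: %d mycelial object(s), %d debris\n",
    x$width, x$height, x$calibration, x$seed, n_myc,
    length(x$objects) - n_myc))
  invisible(x)
}

# ---- low-level rasterizers (linear indices into an h x w frame) ----------

lin_idx <- function(rows, cols, h) (cols - 1L) * h + rows

ellipse_idx <- function(h, w, cx, cy, a, b, phi = 0) {
  rmax <- max(a, b)
  xs <- max(1L, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  ys <- max(1L, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  if (length(xs) == 0 || length(ys) == 0) return(integer(0))
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  u <- gx * cos(phi) + gy * sin(phi)
  v <- -gx * sin(phi) + gy * cos(phi)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  lin_idx(rep(ys, times = length(xs))[sel], rep(xs, each = length(ys))[sel], h)
}

disk_idx <- function(h, w, cx, cy, r) ellipse_idx(h, w, cx, cy, r, r)

polygon_idx <- function(h, w, poly_x, poly_y) {
  xs <- max(1L, floor(min(poly_x))):min(w, ceiling(max(poly_x)))
  ys <- max(1L, floor(min(poly_y))):min(h, ceiling(max(poly_y)))
  if (length(xs) == 0 || length(ys) == 0) return(integer(0))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  sel <- points_in_polygon(gx, gy, poly_x, poly_y)
  lin_idx(gy[sel], gx[sel], h)
}

# union of disks of radius `r` stamped at the given (sub-pixel) points;
# returns list(idx, clipped)
stamp_idx <- function(h, w, xs, ys, r) {
  rr <- ceiling(r)
  off <- expand.grid(di = -rr:rr, dj = -rr:rr)
  off <- off[off$di^2 + off$dj^2 <= r^2, , drop = FALSE]
  px <- round(rep(xs, each = nrow(off)) + rep(off$dj, times = length(xs)))
  py <- round(rep(ys, each = nrow(off)) + rep(off$di, times = length(ys)))
  ok <- px >= 1 & px <= w & py >= 1 & py <= h
  list(idx = unique(lin_idx(py[ok], px[ok], h)), clipped = any(!ok))
}

# ---- placement bookkeeping ----------------------------------------------

free_center <- function(scene, reach, spacing, max_tries = 1500) {
  w <- scene$width; h <- scene$height
  if (2 * reach + 2 > min(w, h)) {
    abort("Object too large for the frame: cannot place it.")
  }
  # keep a few pixels of margin so segmentation never reaches the frame edge
  for (k in seq_len(max_tries)) {
    cx <- stats::runif(1, reach + 5, w - reach - 4)
    cy <- stats::runif(1, reach + 5, h - reach - 4)
    p <- scene$placed
    if (nrow(p) == 0 ||
        all(sqrt((p$cx - cx)^2 + (p$cy - cy)^2) > p$reach + reach + spacing)) {
      return(c(cx, cy))
    }
  }
  abort(sprintf(
    "Could not place an object of reach %.0f px after %d tries: density too high for non-overlapping placement.",
    reach, max_tries))
}

scene_add_object <- function(scene, idx, kind, stage = kind, mycelial = TRUE,
                             cores = list(), clipped = FALSE,
                             cx = NA, cy = NA, reach = NA, members = NULL) {
  if (length(idx) == 0) abort("Refusing to add an object with an empty mask.")
  scene$objects[[length(scene$objects) + 1L]] <- list(
    kind = kind, stage = stage, mycelial = mycelial, idx = sort(idx),
    cores = cores, clipped = clipped, members = members
  )
  if (!is.na(cx)) {
    scene$placed <- rbind(scene$placed,
                          data.frame(cx = cx, cy = cy, reach = reach))
  }
  scene
}

# ---- composable object adders (assume the RNG state is already seeded) ---

add_spores <- function(scene, n, diameter_um = c(2, 4), axis_ratio = 1,
                       germ_tubes = 0, germ_tube_length_um = 0,
                       germ_tube_width_px = 3, spacing_px = 10,
                       kind = NULL) {
  cal <- scene$calibration
  h <- scene$height; w <- scene$width
  if (is.null(kind)) {
    kind <- if (germ_tubes > 0) "germinating_spore"
            else if (axis_ratio > 1) "spore" else "spore"
  }
  for (i in seq_len(n)) {
    d_px <- stats::runif(1, diameter_um[1], max(diameter_um)) / cal
    a <- d_px / 2 * sqrt(axis_ratio)
    b <- d_px / 2 / sqrt(axis_ratio)
    phi <- stats::runif(1, 0, pi)
    reach <- max(a, b) + germ_tubes * (germ_tube_length_um / cal)
    # spore centers sit on the pixel grid: an off-grid rasterized disk is
    # measurably elliptical (E up to ~1.08 at 20 px), which would break the
    # generator's contract that circular spores have true E = 1 +- 0.02
    cen <- round(free_center(scene, reach, spacing_px))
    idx <- ellipse_idx(h, w, cen[1], cen[2], a, b, phi)
    clipped <- FALSE
    if (germ_tubes > 0 && germ_tube_length_um > 0) {
      for (g in seq_len(germ_tubes)) {
        ang <- stats::runif(1, 0, 2 * pi)
        r0 <- max(a, b) * 0.9
        len <- germ_tube_length_um / cal
        tt <- seq(0, len, by = 0.5)
        st <- stamp_idx(h, w, cen[1] + (r0 + tt) * cos(ang),
                        cen[2] + (r0 + tt) * sin(ang),
                        germ_tube_width_px / 2)
        idx <- union(idx, st$idx)
        clipped <- clipped || st$clipped
      }
    }
    scene <- scene_add_object(scene, idx, kind = kind, clipped = clipped,
                              cx = cen[1], cy = cen[2], reach = reach)
  }
  scene
}

add_agglomerate <- function(scene, n_members = 10, member_diameter_um = 3,
                            overlap = 0.35, germ_tubes = 0,
                            germ_tube_length_um = 0, germ_tube_width_px = 3,
                            spacing_px = 10) {
  stopifnot(n_members >= 2)
  cal <- scene$calibration
  h <- scene$height; w <- scene$width
  r_mean <- member_diameter_um / 2 / cal
  # ballistic aggregation around the origin: each member arrives along a
  # random direction with a random impact parameter and sticks to the first
  # member it hits, giving a compact cluster whose area grows ~ linearly
  # with the member count
  mx <- my <- mr <- numeric(n_members)
  mr[1] <- stats::runif(1, 0.8, 1.2) * r_mean
  for (i in seq_len(n_members - 1L)) {
    r_new <- stats::runif(1, 0.8, 1.2) * r_mean
    repeat {
      th <- stats::runif(1, 0, 2 * pi)
      ux <- cos(th); uy <- sin(th)
      vx <- -uy; vy <- ux
      xs <- mx[1:i]; ys <- my[1:i]; rs <- mr[1:i]
      r_cl <- max(sqrt(xs^2 + ys^2) + rs)
      b <- stats::runif(1, -r_cl, r_cl)
      pp <- xs * vx + ys * vy   # perpendicular coordinate of each member
      pl <- xs * ux + ys * uy   # coordinate along the arrival direction
      touch <- (rs + r_new) * (1 - overlap)
      cand <- which(abs(pp - b) < touch)
      if (length(cand) > 0) {
        k <- cand[which.max(pl[cand])]
        dx <- sqrt(max(0, touch[k]^2 - (b - pp[k])^2))
        mx[i + 1L] <- mx[k] + dx * ux + (b - pp[k]) * vx
        my[i + 1L] <- my[k] + dx * uy + (b - pp[k]) * vy
        mr[i + 1L] <- r_new
        break
      }
    }
  }
  mem <- data.frame(x = mx, y = my, r = mr)
  tubes <- NULL
  if (germ_tubes > 0 && germ_tube_length_um > 0) {
    gcx <- mean(mem$x); gcy <- mean(mem$y)
    tubes <- purrr::map(seq_len(germ_tubes), function(g) {
      base <- mem[sample.int(nrow(mem), 1), ]
      ang <- atan2(base$y - gcy, base$x - gcx) + stats::rnorm(1, 0, 0.4)
      if (!is.finite(ang)) ang <- stats::runif(1, 0, 2 * pi)
      len <- germ_tube_length_um / cal * stats::runif(1, 0.7, 1.3)
      tt <- seq(0, len, by = 0.5)
      list(x = base$x + (base$r * 0.8 + tt) * cos(ang),
           y = base$y + (base$r * 0.8 + tt) * sin(ang))
    })
  }
  all_x <- c(mem$x + mem$r, mem$x - mem$r,
             unlist(purrr::map(tubes, "x")))
  all_y <- c(mem$y + mem$r, mem$y - mem$r,
             unlist(purrr::map(tubes, "y")))
  reach <- max(abs(c(all_x, all_y))) + germ_tube_width_px + 1
  cen <- free_center(scene, reach, spacing_px)
  # rasterize on a local grid to avoid repeated set unions
  half <- ceiling(reach) + 1L
  side <- 2L * half + 1L
  loc <- matrix(FALSE, side, side)
  for (i in seq_len(nrow(mem))) {
    loc[ellipse_idx(side, side, half + 1 + mem$x[i], half + 1 + mem$y[i],
                    mem$r[i], mem$r[i])] <- TRUE
  }
  # compact the pack: crevices narrower than a member radius are closed, as
  # in a real spore agglomerate (bumpy outline, no pixel-wide fjords)
  krad <- max(1L, round(r_mean / 2))
  loc <- EBImage::closing(loc * 1, EBImage::makeBrush(2L * krad + 1L,
                                                      "disc")) > 0.5
  for (tb in tubes) {
    loc[stamp_idx(side, side, half + 1 + tb$x, half + 1 + tb$y,
                  germ_tube_width_px / 2)$idx] <- TRUE
  }
  pos <- which(loc, arr.ind = TRUE)
  px <- pos[, 2] - (half + 1) + round(cen[1])
  py <- pos[, 1] - (half + 1) + round(cen[2])
  ok <- px >= 1 & px <= w & py >= 1 & py <= h
  clipped <- any(!ok)
  idx <- lin_idx(py[ok], px[ok], h)
  scene_add_object(scene, idx, kind = "agglomerate",
                   stage = if (germ_tubes > 0) "germinating_agglomerate" else "agglomerate",
                   clipped = clipped, cx = cen[1], cy = cen[2], reach = reach,
                   members = mem)
}

add_pellet <- function(scene, core_radius_um = 50, n_filaments = 60,
                       filament_length_um = 25, filament_width_px = 2,
                       n_cores = 1, angle_jitter = 0.1, spacing_px = 10,
                       kind = NULL) {
  stopifnot(core_radius_um > 0, filament_length_um >= 0, n_cores >= 1)
  cal <- scene$calibration
  h <- scene$height; w <- scene$width
  r_core <- core_radius_um / cal
  reach <- r_core * (1 + 0.9 * (n_cores - 1)) + filament_length_um / cal + 2
  cen <- free_center(scene, reach, spacing_px)
  # cores: first at the center, extras attached in a compact cluster
  cores_xy <- data.frame(x = cen[1], y = cen[2])
  for (k in seq_len(n_cores - 1L)) {
    base <- cores_xy[sample.int(nrow(cores_xy), 1), ]
    ang <- stats::runif(1, 0, 2 * pi)
    cores_xy <- rbind(cores_xy, data.frame(x = base$x + 1.5 * r_core * cos(ang),
                                           y = base$y + 1.5 * r_core * sin(ang)))
  }
  core_list <- purrr::map(seq_len(n_cores), function(k) {
    disk_idx(h, w, cores_xy$x[k], cores_xy$y[k], r_core)
  })
  idx <- unique(unlist(core_list))
  clipped <- FALSE
  if (n_filaments > 0 && filament_length_um > 0) {
    gcx <- mean(cores_xy$x); gcy <- mean(cores_xy$y)
    len_px <- filament_length_um / cal
    for (k in seq_len(n_filaments)) {
      ang <- 2 * pi * (k - 1) / n_filaments + stats::rnorm(1, 0, angle_jitter)
      # start where the ray from the core-union centroid leaves the union
      base <- cores_xy[which.min(abs(((atan2(cores_xy$y - gcy, cores_xy$x - gcx) - ang + pi) %% (2 * pi)) - pi)), ]
      r0 <- r_core * 0.95 + sqrt((base$x - gcx)^2 + (base$y - gcy)^2)
      tt <- seq(0, len_px * stats::runif(1, 0.85, 1.15), by = 0.5)
      st <- stamp_idx(h, w, gcx + (r0 + tt) * cos(ang),
                      gcy + (r0 + tt) * sin(ang), filament_width_px / 2)
      idx <- union(idx, st$idx)
      clipped <- clipped || st$clipped
    }
  }
  if (is.null(kind)) {
    kind <- if (n_cores > 1) "multicore_pellet"
            else if (filament_length_um >= 1.5 * core_radius_um) "core_shell_pellet"
            else "hairy_pellet"
  }
  scene_add_object(scene, idx, kind = kind, cores = core_list,
                   clipped = clipped, cx = cen[1], cy = cen[2], reach = reach)
}

add_clump <- function(scene, n_steps = 150, step_px = 2, width_px = 3,
                      branch_prob = 0.05, turn_sd = 0.25, spacing_px = 10,
                      max_tips = 16) {
  stopifnot(n_steps >= 1)
  h <- scene$height; w <- scene$width
  # walk around the origin first, then place by actual extent; the number of
  # growing tips is capped so branching cannot blow up exponentially
  walkers <- list(list(x = 0, y = 0, ang = stats::runif(1, 0, 2 * pi)))
  xs <- 0; ys <- 0
  for (s in seq_len(n_steps)) {
    new_walkers <- list()
    for (wk in walkers) {
      wk$ang <- wk$ang + stats::rnorm(1, 0, turn_sd)
      wk$x <- wk$x + step_px * cos(wk$ang)
      wk$y <- wk$y + step_px * sin(wk$ang)
      xs <- c(xs, wk$x); ys <- c(ys, wk$y)
      new_walkers[[length(new_walkers) + 1L]] <- wk
      if (length(walkers) + length(new_walkers) <= max_tips &&
          stats::runif(1) < branch_prob) {
        br <- wk
        br$ang <- wk$ang + sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1.2)
        new_walkers[[length(new_walkers) + 1L]] <- br
      }
    }
    walkers <- new_walkers
  }
  reach <- min(max(abs(c(xs, ys))) + width_px, min(h, w) / 2 - 2)
  cen <- free_center(scene, reach, spacing_px)
  st <- stamp_idx(h, w, cen[1] + xs, cen[2] + ys, width_px / 2)
  kind <- if (length(walkers) > 1) "clump" else "branched_hypha"
  scene_add_object(scene, st$idx, kind = kind, clipped = st$clipped,
                   cx = cen[1], cy = cen[2], reach = reach)
}

# deterministic sinusoidal filament of a given arc length, centered in the
# frame; no randomness
add_filament_curve <- function(scene, arc_length_px = 300, width_px = 3,
                               amplitude_px = 25, wavelength_px = 150) {
  h <- scene$height; w <- scene$width
  dx <- 0.5
  xs <- 0; ys <- amplitude_px * sin(0)
  len <- 0
  x <- 0
  while (len < arc_length_px) {
    x2 <- x + dx
    y2 <- amplitude_px * sin(2 * pi * x2 / wavelength_px)
    len <- len + sqrt(dx^2 + (y2 - ys[length(ys)] )^2)
    xs <- c(xs, x2); ys <- c(ys, y2)
    x <- x2
  }
  xs <- xs - mean(range(xs)) + w / 2
  ys <- ys - mean(range(ys)) + h / 2
  st <- stamp_idx(h, w, xs, ys, width_px / 2)
  scene_add_object(scene, st$idx, kind = "branched_hypha", stage = "filament",
                   clipped = st$clipped,
                   cx = w / 2, cy = h / 2,
                   reach = (max(xs) - min(xs)) / 2 + width_px)
}

# ---- public generators ---------------------------------------------------

#' Generate a field of spores
#'
#' Places `n` non-overlapping circular or lemon-shaped (elliptical) spores.
#' Conidiospores are a few micrometers across, so spore scenes are imaged at
#' high magnification (default 0.1 um/px).
#'
#' @param n Number of spores.
#' @param diameter_um Range of spore diameters (um).
#' @param axis_ratio Major/minor axis ratio; 1 gives circular spores, 2
#'   lemon-shaped ones (true elongation ~ axis_ratio^2).
#' @param germ_tubes Number of germ tubes per spore (0 = ungerminated).
#' @param germ_tube_length_um Germ-tube length (um).
#' @param spacing_px Minimum separation between objects (px).
#' @inheritParams scene_new
#' @param ... Passed to [scene_new()].
#' @return A `myco_scene`.
#' @export
generate_spore_field <- function(n = 50, diameter_um = c(2, 4),
                                 axis_ratio = 1, germ_tubes = 0,
                                 germ_tube_length_um = 0, spacing_px = 10,
                                 width = 2448, height = 1920,
                                 calibration = 0.1, seed = 1, ...) {
  scene <- scene_new(width = width, height = height,
                     calibration = calibration, seed = seed, ...)
  with_seed(seed, add_spores(scene, n, diameter_um, axis_ratio,
                             germ_tubes, germ_tube_length_um,
                             spacing_px = spacing_px))
}

#' Generate a spore agglomerate
#'
#' One agglomerate built by sequential attachment of member spores, so the
#' union is a single 8-connected object; optional germ tubes emulate the
#' germination stage.
#'
#' @param n_members Number of member spores (>= 2).
#' @param member_diameter_um Mean member diameter (um).
#' @param overlap Fractional overlap of attached members in (0, 1).
#' @inheritParams generate_spore_field
#' @return A `myco_scene` containing one agglomerate.
#' @export
generate_agglomerate <- function(n_members = 10, member_diameter_um = 3,
                                 overlap = 0.35, germ_tubes = 0,
                                 germ_tube_length_um = 0,
                                 width = 800, height = 600,
                                 calibration = 0.1, seed = 1, ...) {
  scene <- scene_new(width = width, height = height,
                     calibration = calibration, seed = seed, ...)
  with_seed(seed, add_agglomerate(scene, n_members, member_diameter_um,
                                  overlap, germ_tubes, germ_tube_length_um))
}

#' Generate a hairy, core-shell or multicore pellet
#'
#' A disk core (or a compact cluster of `n_cores` touching cores) with
#' radially oriented filaments of jittered angle and length. The truth
#' stores each core mask separately so core/pellet diameter ratios can be
#' scored. The maximum diameter of the truth is ~2 (core radius + filament
#' length) within jitter tolerance.
#'
#' @param core_radius_um Core radius (um).
#' @param n_filaments Number of radial filaments.
#' @param filament_length_um Mean filament length (um).
#' @param filament_width_px Filament width (px, >= 1).
#' @param n_cores Number of cores (1-4 observed for multicore pellets).
#' @inheritParams generate_spore_field
#' @return A `myco_scene` containing one pellet.
#' @export
generate_hairy_pellet <- function(core_radius_um = 50, n_filaments = 60,
                                  filament_length_um = 25,
                                  filament_width_px = 2, n_cores = 1,
                                  width = 800, height = 600, calibration = 1,
                                  seed = 1, ...) {
  scene <- scene_new(width = width, height = height,
                     calibration = calibration, seed = seed, ...)
  with_seed(seed, add_pellet(scene, core_radius_um, n_filaments,
                             filament_length_um, filament_width_px, n_cores))
}

#' Generate a hyphal clump
#'
#' A branching random-walk filament of configured width: walkers step with
#' angular diffusion and branch with probability `branch_prob` per step.
#' With `branch_prob = 0` a single unbranched hypha results. Walks escaping
#' the frame are clipped and flagged.
#'
#' @param n_steps Steps per walker (>= 1).
#' @param step_px Step length (px).
#' @param width_px Filament width (px).
#' @param branch_prob Branching probability per walker per step.
#' @param turn_sd SD of the per-step direction change (radians).
#' @inheritParams generate_spore_field
#' @return A `myco_scene` containing one clump.
#' @export
generate_clump <- function(n_steps = 150, step_px = 2, width_px = 3,
                           branch_prob = 0.05, turn_sd = 0.25,
                           width = 800, height = 600, calibration = 1,
                           seed = 1, ...) {
  scene <- scene_new(width = width, height = height,
                     calibration = calibration, seed = seed, ...)
  with_seed(seed, add_clump(scene, n_steps, step_px, width_px, branch_prob,
                            turn_sd))
}

#' Generate a deterministic sinusoidal filament
#'
#' A parametric sinusoidal filament of the given arc length and width with
#' no randomness: the canonical thin filamentous object whose morphology
#' number falls in the filamentous regime (< 0.5).
#'
#' @param arc_length_px Arc length of the centerline (px).
#' @param width_px Filament width (px).
#' @param amplitude_px,wavelength_px Sinusoid geometry (px).
#' @inheritParams generate_spore_field
#' @return A `myco_scene` containing one filament.
#' @export
generate_filament <- function(arc_length_px = 300, width_px = 3,
                              amplitude_px = 25, wavelength_px = 150,
                              width = 400, height = 160, calibration = 1,
                              seed = 1, ...) {
  scene <- scene_new(width = width, height = height,
                     calibration = calibration, seed = seed, ...)
  add_filament_curve(scene, arc_length_px, width_px, amplitude_px,
                     wavelength_px)
}

#' Litter a scene with microparticle debris
#'
#' Adds `count` angular (jagged-polygon) mineral grains of ~`diameter_um`
#' (default 10 um, the mean diameter of the aluminum-oxide microparticles
#' used in microparticle-enhanced cultivation). Debris is recorded in the
#' truth as non-mycelial, so filter tests can score its removal.
#'
#' @param scene A `myco_scene`.
#' @param count Number of particles (>= 0).
#' @param diameter_um Mean particle diameter (um).
#' @param shape_jitter Spikiness of the polygon outline in (0, 1).
#' @param spacing_px Minimum separation from other objects (px).
#' @return The scene with debris objects appended.
#' @export
add_microparticles <- function(scene, count, diameter_um = 10,
                               shape_jitter = 0.55, spacing_px = 8) {
  stopifnot(inherits(scene, "myco_scene"), count >= 0)
  if (count == 0) return(scene)
  h <- scene$height; w <- scene$width
  r_px <- diameter_um / 2 / scene$calibration
  with_seed(scene$seed + 10007L, {
    for (i in seq_len(count)) {
      cen <- free_center(scene, r_px + 1, spacing_px)
      k <- sample(6:9, 1)
      # vertices at jittered regular angles; alternating long and short
      # radii give an angular, spiky grain
      angs <- stats::runif(1, 0, 2 * pi) +
        (seq_len(k) - 1) * 2 * pi / k +
        stats::runif(k, 0, 0.6 * pi / k)
      radii <- r_px * ifelse(seq_len(k) %% 2 == 0,
                             stats::runif(k, 1 - shape_jitter, 1 - shape_jitter + 0.1),
                             stats::runif(k, 0.9, 1))
      idx <- polygon_idx(h, w, cen[1] + radii * cos(angs),
                         cen[2] + radii * sin(angs))
      scene <- scene_add_object(scene, idx, kind = "microparticle",
                                mycelial = FALSE, cx = cen[1], cy = cen[2],
                                reach = r_px)
    }
    scene
  })
}

# ---- ground truth --------------------------------------------------------

#' Ground-truth descriptor table of a synthetic scene
#'
#' True descriptors are computed by the morphometry operations on the exact
#' noiseless masks. The size class at the configured threshold is included.
#'
#' @param scene A `myco_scene`.
#' @param class_threshold Two-class area threshold (um^2).
#' @return A tibble with one row per true object: `object_id`, `kind`,
#'   `stage`, `mycelial`, `clipped`, `n_cores`, `n_pixels`, `A_um2`, `E`,
#'   `R`, `Dmax_um`, `Mo`, `class`.
#' @export
scene_truth <- function(scene, class_threshold = 1e4) {
  stopifnot(inherits(scene, "myco_scene"))
  cal <- scene$calibration
  h <- scene$height
  rows <- purrr::imap(scene$objects, function(ob, i) {
    cm <- crop_mask(h, ob$idx)
    mask <- cm$mask
    n_px <- sum(mask)
    A <- n_px * cal^2
    E <- elongation(mask)
    R <- roughness(mask)
    Dmax <- max_diameter(mask, cal)
    Mo <- if (is.finite(E)) morphology_number(A, R, as.numeric(E), Dmax) else NA_real_
    tibble::tibble(
      object_id = i, kind = ob$kind, stage = ob$stage,
      mycelial = ob$mycelial, clipped = ob$clipped,
      n_cores = length(ob$cores), n_pixels = n_px, A_um2 = A,
      E = as.numeric(E), R = R, Dmax_um = Dmax, Mo = Mo
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, class = factor(
    ifelse(.data$A_um2 < class_threshold, "small", "large"),
    levels = c("small", "large")))
}

#' True label grid of a synthetic scene
#'
#' @param scene A `myco_scene`.
#' @param mycelial_only Drop debris objects from the labeling.
#' @return A [labeled_scene] built from the exact true masks.
#' @export
scene_labels <- function(scene, mycelial_only = FALSE) {
  stopifnot(inherits(scene, "myco_scene"))
  labs <- matrix(0L, scene$height, scene$width)
  objs <- scene$objects
  if (mycelial_only) {
    objs <- objs[vapply(objs, function(o) isTRUE(o$mycelial), logical(1))]
  }
  for (i in seq_along(objs)) labs[objs[[i]]$idx] <- i
  labeled_scene(labs, scene$calibration)
}

# full-frame logical mask of scene object `i`
scene_mask <- function(scene, i) {
  m <- matrix(FALSE, scene$height, scene$width)
  m[scene$objects[[i]]$idx] <- TRUE
  m
}

#' @export
tidy.myco_scene <- function(x, ...) scene_truth(x, ...)

# ---- rendering -----------------------------------------------------------

#' Render a synthetic scene as a calibrated RGB micrograph
#'
#' Emulates the phase-contrast appearance of the source data: dark objects
#' on a bright background, debris at its own intensity, an optional bright
#' halo rim, and optional additive Gaussian noise. The green plane carries
#' the full object contrast (red and blue are rendered at reduced
#' contrast), matching the pipeline's green-plane segmentation. Rendering
#' never alters the ground-truth masks, and a fixed scene seed yields
#' identical image bytes.
#'
#' @param scene A `myco_scene`.
#' @return An 8-bit RGB [calibrated_image].
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "myco_scene"))
  h <- scene$height; w <- scene$width
  base <- matrix(scene$background, h, w)
  if (scene$halo_width > 0 && length(scene$objects) > 0) {
    all_idx <- unlist(purrr::map(scene$objects, "idx"))
    mask <- matrix(0L, h, w); mask[all_idx] <- 1L
    kern <- EBImage::makeBrush(2 * scene$halo_width + 1, shape = "disc")
    halo <- EBImage::dilate(mask, kern) > 0.5 & mask == 0L
    base[halo] <- min(255, scene$background + 30)
  }
  for (ob in scene$objects) {
    base[ob$idx] <- if (isTRUE(ob$mycelial)) scene$object_intensity
                    else scene$debris_intensity
  }
  if (scene$noise_sd > 0) {
    base <- with_seed(scene$seed + 7919L,
                      base + stats::rnorm(length(base), 0, scene$noise_sd))
  }
  g <- pmin(pmax(round(base), 0), 255)
  rb <- round(scene$background - (scene$background - g) * 0.35)
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- rb; px[, , 2] <- g; px[, , 3] <- rb
  calibrated_image(px, scene$calibration, time_hr = scene$time_hr,
                   condition = scene$condition)
}

# ---- timecourse ----------------------------------------------------------

#' Species-like developmental profiles
#'
#' Four editable stage schedules matching, qualitatively only, the
#' developmental narratives of the four studied species:
#' `agglomerative-spore` (spores swell, agglomerate, germinate from the
#' agglomerate edge and form hairy pellets), `agglomerative-hyphal`
#' (germination first, then hyphal clumps that agglomerate into pellets),
#' `perithecia-seeded` (clumps seeded around a dense body grow into
#' core-shell pellets with long filaments) and `non-agglomerative`
#' (single germlings grow directly into distinct-core pellets).
#'
#' @return A named list of profile stage schedules; each stage holds
#'   `time_hr`, `stage`, `calibration` and a list of object-adder calls.
#' @export
timecourse_profiles <- function() {
  list(
    "agglomerative-spore" = list(
      list(time_hr = 0, stage = "spores", calibration = 0.1,
           add = list(list(fn = "add_spores", n = 40, diameter_um = c(2, 3)))),
      list(time_hr = 5, stage = "swollen_spores", calibration = 0.1,
           add = list(list(fn = "add_spores", n = 40, diameter_um = c(3, 4.5)))),
      list(time_hr = 8, stage = "agglomerates", calibration = 0.5,
           add = list(
             list(fn = "add_agglomerate", rep = 3, n_members = 300,
                  member_diameter_um = 8, overlap = 0.25),
             list(fn = "add_agglomerate", rep = 6, n_members = 25,
                  member_diameter_um = 8, overlap = 0.25),
             list(fn = "add_spores", n = 12, diameter_um = c(3.5, 5)))),
      list(time_hr = 12, stage = "germination", calibration = 0.5,
           add = list(
             list(fn = "add_agglomerate", rep = 3, n_members = 300,
                  member_diameter_um = 8, overlap = 0.25, germ_tubes = 16,
                  germ_tube_length_um = 60, germ_tube_width_px = 3),
             list(fn = "add_agglomerate", rep = 6, n_members = 25,
                  member_diameter_um = 8, overlap = 0.25, germ_tubes = 5,
                  germ_tube_length_um = 35, germ_tube_width_px = 3))),
      list(time_hr = 18, stage = "young_pellets", calibration = 1,
           add = list(
             list(fn = "add_pellet", rep = 5, core_radius_um = 70,
                  n_filaments = 50, filament_length_um = 25,
                  filament_width_px = 2))),
      list(time_hr = 24, stage = "pellets", calibration = 2,
           add = list(
             list(fn = "add_pellet", rep = 5, core_radius_um = 160,
                  n_filaments = 70, filament_length_um = 45,
                  filament_width_px = 2)))
    ),
    "agglomerative-hyphal" = list(
      list(time_hr = 0, stage = "spores", calibration = 0.1,
           add = list(list(fn = "add_spores", n = 40, diameter_um = c(2.5, 4)))),
      list(time_hr = 6, stage = "germination", calibration = 0.25,
           add = list(list(fn = "add_spores", n = 25, diameter_um = c(3.5, 5),
                           germ_tubes = 1, germ_tube_length_um = 12))),
      list(time_hr = 12, stage = "clumps", calibration = 1,
           add = list(list(fn = "add_clump", rep = 8, n_steps = 120,
                           branch_prob = 0.04))),
      list(time_hr = 18, stage = "agglomerated_mycelium", calibration = 1,
           add = list(list(fn = "add_pellet", rep = 5, core_radius_um = 45,
                           n_filaments = 60, filament_length_um = 45))),
      list(time_hr = 24, stage = "pellets", calibration = 2,
           add = list(list(fn = "add_pellet", rep = 5, core_radius_um = 120,
                           n_filaments = 60, filament_length_um = 60)))
    ),
    "perithecia-seeded" = list(
      list(time_hr = 0, stage = "spores", calibration = 0.1,
           add = list(list(fn = "add_spores", n = 30, diameter_um = c(4, 8),
                           axis_ratio = 2))),
      list(time_hr = 6, stage = "germination", calibration = 0.25,
           add = list(list(fn = "add_spores", n = 20, diameter_um = c(5, 8),
                           axis_ratio = 1.5, germ_tubes = 1,
                           germ_tube_length_um = 15))),
      list(time_hr = 12, stage = "clumps", calibration = 1,
           add = list(list(fn = "add_clump", rep = 8, n_steps = 150,
                           branch_prob = 0.06))),
      list(time_hr = 24, stage = "core_shell_pellets", calibration = 2,
           add = list(list(fn = "add_pellet", rep = 4, core_radius_um = 90,
                           n_filaments = 80, filament_length_um = 160,
                           filament_width_px = 2)))
    ),
    "non-agglomerative" = list(
      list(time_hr = 0, stage = "spores", calibration = 0.1,
           add = list(list(fn = "add_spores", n = 30, diameter_um = c(3, 6)))),
      list(time_hr = 8, stage = "germination", calibration = 0.25,
           add = list(list(fn = "add_spores", n = 20, diameter_um = c(4, 7),
                           germ_tubes = 2, germ_tube_length_um = 20))),
      list(time_hr = 16, stage = "branched_hyphae", calibration = 1,
           add = list(list(fn = "add_clump", rep = 6, n_steps = 200,
                           branch_prob = 0.08))),
      list(time_hr = 24, stage = "cored_pellets", calibration = 2,
           add = list(list(fn = "add_pellet", rep = 4, core_radius_um = 140,
                           n_filaments = 50, filament_length_um = 60,
                           n_cores = 2)))
    )
  )
}

#' Simulate a developmental timecourse
#'
#' Produces one synthetic scene per scheduled time point following a
#' species-like profile (see [timecourse_profiles()]). The calibration
#' changes across stages, emulating the switch to lower magnification as
#' objects grow. Per-stage seeds are derived from `seed`, so the whole
#' timecourse is reproducible.
#'
#' @param profile Profile name (see [timecourse_profiles()]) or a stage
#'   schedule in the same format.
#' @param seed Integer seed.
#' @param width,height Frame size (px) of every scene.
#' @param condition Cultivation arm recorded on the scenes.
#' @param times Optional subset of the profile's scheduled times.
#' @return A tibble with columns `time_hr`, `stage`, `condition` and a
#'   `scene` list-column of `myco_scene` objects.
#' @export
simulate_timecourse <- function(profile = "agglomerative-spore", seed = 1,
                                width = 2448, height = 1920,
                                condition = "standard", times = NULL) {
  if (is.character(profile)) {
    profs <- timecourse_profiles()
    if (!profile %in% names(profs)) {
      abort(sprintf("Unknown profile '%s'; available: %s", profile,
                    paste(names(profs), collapse = ", ")))
    }
    schedule <- profs[[profile]]
  } else {
    schedule <- profile
  }
  if (length(schedule) == 0) abort("Empty stage schedule.")
  sched_times <- vapply(schedule, `[[`, numeric(1), "time_hr")
  if (is.unsorted(sched_times, strictly = TRUE)) {
    abort("Schedule times must be strictly increasing.")
  }
  if (!is.null(times)) {
    keep <- sched_times %in% times
    if (!any(keep)) abort("None of the requested `times` are in the schedule.")
    schedule <- schedule[keep]
  }
  rows <- purrr::imap(schedule, function(stg, i) {
    scene <- scene_new(width = width, height = height,
                       calibration = stg$calibration,
                       seed = seed + 1000L * i,
                       time_hr = stg$time_hr, condition = condition)
    scene <- with_seed(seed + 1000L * i, {
      for (call in stg$add) {
        n_rep <- if (is.null(call$rep)) 1L else call$rep
        args <- call[setdiff(names(call), c("fn", "rep"))]
        for (r in seq_len(n_rep)) {
          scene <- do.call(call$fn, c(list(scene), args))
        }
      }
      scene
    })
    tibble::tibble(time_hr = stg$time_hr, stage = stg$stage,
                   condition = condition, scene = list(scene))
  })
  dplyr::bind_rows(rows)
}
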