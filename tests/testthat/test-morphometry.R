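test_that("projected_area is pixel count times squared calibration", {
  m <- matrix(FALSE, 20, 20); m[3:12, 3:12] <- TRUE  # 100 px
  expect_equal(projected_area(m, 0.5), 25)
  one <- matrix(c(TRUE), 1, 1)
  expect_equal(projected_area(one, 1), 1)
  d <- mask_disk(50)
  expect_lt(abs(projected_area(d, 1) - pi * 50^2) / (pi * 50^2), 0.01)
  expect_error(projected_area(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("mean_diameter recovers disk and square closed forms", {
  d <- mask_disk(40)
  expect_equal(as.numeric(mean_diameter(d, 1)), 80, tolerance = 0.02)
  expect_equal(as.numeric(mean_diameter(d, 0.25)), 20, tolerance = 0.02)

  # axis-aligned square of side s: mean chord = (4/pi) ln(1 + sqrt(2)) s
  s <- 101
  sq <- mask_rect(s, s)
  expect_equal(as.numeric(mean_diameter(sq, 1)),
               (4 / pi) * log(1 + sqrt(2)) * s, tolerance = 0.01)
})

test_that("mean_diameter of a thin line matches an explicit chord scan", {
  L <- 61
  line <- mask_rect(L, 1)
  got <- as.numeric(mean_diameter(line, 1, n_dirs = 180, step = 0.25))
  # independent oracle: exact chord of a 1 x L box through its center,
  # sampled at the same 180 directions
  theta <- (0:179) * pi / 180
  chord <- pmin(L / abs(cos(theta)), 1 / abs(sin(theta)))
  expect_equal(got, mean(chord), tolerance = 0.05)
})

test_that("mean_diameter flags a centroid outside the mask", {
  # annulus: the centroid falls in the hole
  ring <- mask_disk(20, pad = 6) & !mask_disk(16, pad = 10)
  d <- mean_diameter(ring, 1)
  expect_identical(attr(d, "flag"), "centroid_outside")
  expect_equal(as.numeric(d), as.numeric(max_diameter(ring, 1)))
})

test_that("max_diameter matches geometry and a brute-force pairwise oracle", {
  d <- mask_disk(35)
  expect_lte(abs(max_diameter(d, 1) - 70), 1.01)  # 2r within 1 px
  rect <- mask_rect(40, 30)
  expect_equal(max_diameter(rect, 2), sqrt(40^2 + 30^2) * 2,
               tolerance = 1.5 / 50)

  for (s in 1:20) {
    m <- random_blob_mask(s)
    b <- which(mycomorph:::boundary_mask(m), arr.ind = TRUE)
    brute <- sqrt(max(outer(b[, 1], b[, 1], "-")^2 +
                        outer(b[, 2], b[, 2], "-")^2)) + 1
    expect_equal(max_diameter(m, 1), brute)
  }
})

test_that("elongation matches discrete-moment closed forms", {
  expect_equal(elongation(mask_disk(30)), 1, tolerance = 0.02)
  # filled w x h rectangle: discrete uniform variances (w^2-1)/12, (h^2-1)/12
  rect <- mask_rect(20, 10)
  expect_equal(elongation(rect), 399 / 99, tolerance = 1e-10)
  # rotation by 90 degrees leaves E unchanged
  m <- random_blob_mask(7)
  expect_equal(elongation(m), elongation(t(m)), tolerance = 0.02)
  # degenerate objects
  expect_equal(elongation(matrix(TRUE, 1, 1)), 1)
  two <- matrix(FALSE, 3, 4); two[2, 2:3] <- TRUE
  e <- elongation(two)
  expect_identical(as.numeric(e), Inf)
  expect_identical(attr(e, "flag"), "elongation_infinite")
})

test_that("roughness equals a hull-rasterization pixel-count oracle", {
  expect_equal(roughness(mask_disk(30)), 1, tolerance = 0.02)

  spiky <- mask_spiky_disk(40, 8, 40)
  # independent oracle: convexity as intersection of hull half-planes
  xy <- which(spiky, arr.ind = TRUE)
  hull <- grDevices::chull(xy[, 2], xy[, 1])
  hx <- xy[hull, 2]; hy <- xy[hull, 1]
  grid <- expand.grid(y = seq_len(nrow(spiky)), x = seq_len(ncol(spiky)))
  inside <- rep(TRUE, nrow(grid))
  n <- length(hx)
  orient <- sign(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cross <- (hx[j] - hx[i]) * (grid$y - hy[i]) -
      (hy[j] - hy[i]) * (grid$x - hx[i])
    inside <- inside & orient * cross >= -1e-9
  }
  oracle <- sum(spiky) / sum(inside)
  expect_equal(roughness(spiky), oracle, tolerance = 1e-10)
  expect_lt(roughness(spiky), 0.6)

  # the rasterized hull of any mask is itself convex: roughness ~ 1
  hull_mask <- matrix(inside, nrow(spiky), ncol(spiky))
  expect_equal(roughness(hull_mask), 1, tolerance = 0.01)
})

test_that("circularity separates disks, squares and lines", {
  expect_gte(circularity(mask_disk(20)), 0.9)
  expect_lt(circularity(mask_rect(100, 1)), 0.1)
  expect_equal(circularity(mask_rect(50, 50)), pi / 4, tolerance = 0.06)
})

test_that("morphology_number has the disk closed form and validates input", {
  expect_equal(morphology_number(A = pi, S = 1, E = 1, Dmax = 2), 1)
  expect_error(morphology_number(-1, 1, 1, 2), "positive")
  expect_error(morphology_number(1, 0, 1, 2), "positive")
  expect_error(morphology_number(1, 1, 1, 0), "positive")
  expect_true(is.na(morphology_number(1, 1, Inf, 2)))
})

test_that("descriptors are scale-equivariant in the calibration", {
  m <- random_blob_mask(3)
  expect_equal(projected_area(m, 2), 4 * projected_area(m, 1))
  expect_equal(as.numeric(mean_diameter(m, 2)),
               2 * as.numeric(mean_diameter(m, 1)))
  expect_equal(max_diameter(m, 2), 2 * max_diameter(m, 1))
  # E, R, circularity are calibration-free by construction (mask-only)
})

test_that("E, R and Mo are rotation invariant within rasterization tolerance", {
  sc <- generate_hairy_pellet(core_radius_um = 30, n_filaments = 24,
                              filament_length_um = 15, width = 220,
                              height = 220, seed = 4)
  m <- mycomorph:::scene_mask(sc, 1)
  rot <- t(m)[, rev(seq_len(nrow(m)))]  # 90-degree rotation
  for (f in list(elongation, roughness)) {
    expect_equal(as.numeric(f(m)), as.numeric(f(rot)), tolerance = 0.03)
  }
  mo <- function(mask) {
    morphology_number(projected_area(mask, 1), roughness(mask),
                      as.numeric(elongation(mask)), max_diameter(mask, 1))
  }
  expect_equal(mo(m), mo(rot), tolerance = 0.03)
})

test_that("Mo orders disk > hairy pellet > filament and matches its closed form", {
  recs <- measure_rendered(list(mask_disk(60, pad = 10)))
  pellet <- generate_hairy_pellet(core_radius_um = 45, n_filaments = 40,
                                  filament_length_um = 40, width = 260,
                                  height = 260, seed = 2)
  fil <- generate_filament()
  mo_disk <- recs$Mo
  mo_pellet <- scene_truth(pellet)$Mo
  mo_fil <- scene_truth(fil)$Mo
  expect_gt(mo_disk, mo_pellet)
  expect_gt(mo_pellet, mo_fil)

  # per object, the Mo column equals the closed form of its own descriptors
  sf <- generate_spore_field(n = 10, width = 500, height = 400,
                             calibration = 0.1, seed = 8)
  rec <- analyze_image(render_scene(sf), image_kind = "none")
  expect_equal(rec$Mo, 2 * sqrt(rec$A_um2 * rec$R) /
                 (sqrt(pi) * rec$Dmax_um * rec$E))
})

test_that("measure_objects reports the documented schema and 0-based centroids", {
  m <- matrix(FALSE, 10, 12); m[3:5, 4:6] <- TRUE
  scene <- labeled_scene(m * 1L, calibration = 0.5)
  rec <- measure_objects(scene)
  expect_named(rec, c("image", "time_hr", "condition", "object_id",
                      "n_pixels", "A_um2", "D_um", "Dmax_um", "E", "R",
                      "circularity", "Mo", "centroid_x", "centroid_y",
                      "flags", "convex_area_um2", "R_clip",
                      "circularity_clip", "Mo_clip"))
  expect_equal(rec$centroid_x, 4)  # columns 4:6, 1-based -> 0-based mean 4
  expect_equal(rec$centroid_y, 3)
  expect_equal(rec$n_pixels, 9L)
  expect_equal(rec$A_um2, 9 * 0.25)
  expect_match(attr(rec, "mo_form"), "sqrt\\(A\\*S\\)")
})
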