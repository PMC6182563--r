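edges_of <- function(mask, calibration = 1) {
  img <- calibrated_image(ifelse(mask, 60, 200), calibration)
  sobel_edge_magnitude(median_smooth(img, 1))
}

test_that("segment_from_edges recovers single and multiple disks", {
  d <- mask_disk(30, pad = 15)
  scene <- segment_from_edges(edges_of(d))
  expect_equal(scene$n_objects, 1)
  got <- scene$labels == 1
  expect_gte(sum(got & d) / sum(d), 0.95)

  two <- mask_disk(15, pad = 8)
  frame <- matrix(FALSE, nrow(two), 2 * ncol(two) + 20)
  frame[, seq_len(ncol(two))] <- two
  frame[, ncol(frame) - ncol(two) + seq_len(ncol(two))] <- two
  expect_equal(segment_from_edges(edges_of(frame))$n_objects, 2)
})

test_that("closed contours are filled and empty edge images give empty scenes", {
  ring <- mask_disk(20, pad = 8) & !mask_disk(18, pad = 10)
  edges <- calibrated_image(ifelse(ring, 100, 0), 1)
  scene <- segment_from_edges(edges, edge_threshold = 50,
                              closing_radius = 0, edge_compensation = 0)
  expect_equal(scene$n_objects, 1)
  # the hole is filled: the object covers the inner disk
  expect_true(all(scene$labels[mask_disk(18, pad = 10)] == 1))

  zero <- calibrated_image(matrix(0, 40, 40), 1)
  empty <- segment_from_edges(zero)
  expect_equal(empty$n_objects, 0)
  expect_true(all(empty$labels == 0))
  expect_error(segment_from_edges(calibrated_image(matrix(-1, 4, 4), 1)),
               "non-negative")
})

test_that("objects are labeled as 8-connected components", {
  m <- matrix(0, 7, 7)
  m[2, 2] <- 1; m[3, 3] <- 1  # touch only diagonally
  m[6, 6] <- 1                # separate
  labs <- mycomorph:::label_components(m > 0)
  expect_equal(max(labs), 2)
  expect_equal(labs[2, 2], labs[3, 3])
})

test_that("segmentation recovers the exact object count on well-separated scenes", {
  for (s in 1:3) {
    sf <- generate_spore_field(n = 12, width = 600, height = 450,
                               calibration = 0.1, seed = s, spacing_px = 10)
    scene <- attr(analyze_image(render_scene(sf), image_kind = "none"), "scene")
    expect_equal(scene$n_objects, 12)
  }
})

test_that("apply_filters removes rule violators and reports removals", {
  disk <- mask_disk(20, pad = 5)   # circularity ~ 1
  rod <- mask_rect(60, 3, pad = 4)
  frame <- matrix(FALSE, 80, 140)
  frame[10 + seq_len(nrow(disk)), 5 + seq_len(ncol(disk))] <- disk
  frame[40 + seq_len(nrow(rod)), 70 + seq_len(ncol(rod))] <- rod
  labs <- matrix(0L, 80, 140)
  labs[10 + seq_len(nrow(disk)), 5 + seq_len(ncol(disk))][disk] <- 1L
  labs[40 + seq_len(nrow(rod)), 70 + seq_len(ncol(rod))][rod] <- 2L
  scene <- labeled_scene(labs, 1)

  out <- apply_filters(scene, filter_rule("min_circularity", 0.6))
  expect_equal(out$n_objects, 1)
  rem <- attr(out, "removals")
  expect_equal(rem$object_id, 2L)
  expect_equal(rem$rule, "min_circularity")
  # surviving mask preserved pixel-for-pixel under relabeling
  expect_identical(out$labels == 1, scene$labels == 1)
})

test_that("a minimum-area rule removes a 10 um microparticle disk", {
  # 10 um disk at 0.5 um/px: radius 10 px, area ~ pi * 5^2 = 78.5 um^2
  deb <- mask_disk(10, pad = 6)
  big <- mask_disk(50, pad = 6)
  frame_h <- max(nrow(deb), nrow(big))
  labs <- matrix(0L, frame_h + 10, ncol(deb) + ncol(big) + 30)
  labs[5 + seq_len(nrow(big)), 5 + seq_len(ncol(big))][big] <- 1L
  labs[5 + seq_len(nrow(deb)), 15 + ncol(big) + seq_len(ncol(deb))][deb] <- 2L
  scene <- labeled_scene(labs, 0.5)
  morpho <- measure_objects(scene)
  expect_equal(morpho$A_um2[2], pi * 5^2, tolerance = 0.03)
  out <- apply_filters(scene, filter_rule("min_area", 1000), morpho = morpho)
  expect_equal(out$n_objects, 1)
  expect_equal(attr(out, "removals")$object_id, 2L)
})

test_that("apply_filters with no rules is the identity and kinds are validated", {
  sf <- generate_spore_field(n = 5, width = 300, height = 300,
                             calibration = 0.1, seed = 2)
  scene <- scene_labels(sf)
  out <- apply_filters(scene, list())
  expect_identical(out$labels, scene$labels)
  expect_error(filter_rule("min_feret", 1), "arg")
  expect_error(filter_rule("min_area", -5), "positive")
  expect_error(filter_rule("min_circularity", 1.5), "\\(0, 1\\]")
})

test_that("the surviving set does not depend on rule order", {
  sf <- generate_spore_field(n = 8, width = 500, height = 400,
                             calibration = 0.1, seed = 9)
  sf <- add_microparticles(sf, 6)
  scene <- scene_labels(sf)
  morpho <- measure_objects(scene)
  rules <- list(filter_rule("min_circularity", 0.75),
                filter_rule("min_area", 5),
                filter_rule("max_area", 1e6),
                filter_rule("border_exclusion", 1))
  surviving <- function(perm) {
    out <- apply_filters(scene, rules[perm], morpho = morpho)
    sort(setdiff(morpho$object_id, attr(out, "removals")$object_id))
  }
  base <- surviving(1:4)
  set.seed(1)
  for (k in 1:5) expect_identical(surviving(sample(4)), base)
})

test_that("border_exclusion removes frame-touching objects", {
  labs <- matrix(0L, 30, 30)
  labs[1:5, 10:14] <- 1L          # touches the top border
  labs[15:19, 10:14] <- 2L        # interior
  scene <- labeled_scene(labs, 1)
  out <- apply_filters(scene, filter_rule("border_exclusion", 1))
  expect_equal(out$n_objects, 1)
  expect_equal(attr(out, "removals")$object_id, 1L)
})

test_that("apply_aoi keeps objects by inclusive centroid test", {
  labs <- matrix(0L, 100, 200)
  labs[46:54, 46:54] <- 1L    # centroid x = 49 (0-based)
  labs[46:54, 146:154] <- 2L  # centroid x = 149
  scene <- labeled_scene(labs, 1)

  whole <- cbind(c(0, 199, 199, 0), c(0, 0, 99, 99))
  expect_identical(apply_aoi(scene, whole)$labels, scene$labels)

  left <- cbind(c(0, 99.5, 99.5, 0), c(0, 0, 99, 99))
  out <- apply_aoi(scene, left)
  expect_equal(out$n_objects, 1)
  expect_true(all(which(out$labels == 1) == which(scene$labels == 1)))

  # centroid exactly on the boundary is kept
  on_edge <- cbind(c(0, 49, 49, 0), c(0, 0, 99, 99))
  expect_equal(apply_aoi(scene, on_edge)$n_objects, 1)
})

test_that("degenerate AOI polygons are rejected", {
  scene <- labeled_scene(matrix(0L, 10, 10), 1)
  expect_error(apply_aoi(scene, cbind(c(0, 1), c(0, 1))), ">= 3")
  expect_error(apply_aoi(scene, cbind(c(0, 5, 10), c(0, 0, 0))), "zero area")
  bowtie <- cbind(c(0, 10, 2, 10), c(0, 10, 8, 0))
  expect_error(apply_aoi(scene, bowtie), "self-intersecting")
})

test_that("AOI files parse one polygon per line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0,0,100,0,100,80,0,80", "10,10,50,10,30,40"), f)
  polys <- read_aoi_file(f)
  expect_length(polys, 2)
  expect_equal(nrow(polys[[1]]), 4)
  writeLines("1,2,3", f)
  expect_error(read_aoi_file(f), "Malformed")
})
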