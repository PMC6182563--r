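test_that("spore fields have the requested count, shape and determinism", {
  sf <- generate_spore_field(n = 50, diameter_um = c(2, 2), width = 1000,
                             height = 800, calibration = 0.1, seed = 3)
  tr <- scene_truth(sf)
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$mycelial))
  # 2 um spores at 0.1 um/px are ~20 px across
  expect_true(all(abs(tr$Dmax_um / 0.1 - 20) < 3))
  # circular spores are not elongated
  expect_true(all(abs(tr$E - 1) < 0.02 + 0.03))

  sf2 <- generate_spore_field(n = 50, diameter_um = c(2, 2), width = 1000,
                              height = 800, calibration = 0.1, seed = 3)
  expect_identical(lapply(sf$objects, `[[`, "idx"),
                   lapply(sf2$objects, `[[`, "idx"))
  expect_identical(render_scene(sf)$pixels, render_scene(sf2)$pixels)
})

test_that("lemon-shaped spores have the moment-oracle elongation", {
  sf <- generate_spore_field(n = 12, diameter_um = c(6, 6), axis_ratio = 2,
                             width = 900, height = 700, calibration = 0.1,
                             seed = 5)
  tr <- scene_truth(sf)
  # axis ratio 2 -> principal-variance ratio ~ 4 on the rasterized ellipse
  expect_true(all(abs(tr$E - 4) / 4 < 0.1))
})

test_that("overcrowded placement fails with an explicit error", {
  expect_error(
    generate_spore_field(n = 500, diameter_um = c(4, 4), width = 120,
                         height = 120, calibration = 0.1, seed = 1),
    "density|too large")
})

test_that("agglomerates are one 8-connected component with consistent truth", {
  ag <- generate_agglomerate(n_members = 10, member_diameter_um = 3,
                             overlap = 0.35, width = 900, height = 700,
                             calibration = 0.1, seed = 6)
  tr <- scene_truth(ag)
  expect_equal(nrow(tr), 1)
  m <- mycomorph:::scene_mask(ag, 1)
  expect_equal(max(mycomorph:::label_components(m)), 1)
  # truth A equals an independent count of the union mask
  expect_equal(tr$A_um2, sum(m) * 0.1^2)
  # with positive overlap the union is smaller than the sum of member disks
  mem <- ag$objects[[1]]$members
  expect_lt(sum(m), sum(pi * mem$r^2))
  expect_equal(nrow(mem), 10)
})

test_that("hairy pellets lose solidity as filaments are added", {
  rs <- sapply(c(0, 20, 60), function(k) {
    p <- generate_hairy_pellet(core_radius_um = 40, n_filaments = k,
                               filament_length_um = 40, width = 400,
                               height = 300, seed = 11)
    scene_truth(p)$R
  })
  expect_gte(rs[1], 0.98)        # bare disk is convex
  expect_lt(rs[2], rs[1])        # any filaments cut solidity well below it
  expect_lt(rs[3], 0.9)

  p3 <- generate_hairy_pellet(core_radius_um = 30, n_filaments = 20,
                              filament_length_um = 20, n_cores = 3,
                              width = 500, height = 400, seed = 2)
  tr <- scene_truth(p3)
  expect_equal(tr$n_cores, 3)
  expect_equal(tr$kind, "multicore_pellet")

  # Dmax ~ 2 (core radius + filament length) within jitter tolerance
  p1 <- generate_hairy_pellet(core_radius_um = 50, n_filaments = 60,
                              filament_length_um = 25, width = 400,
                              height = 300, seed = 7)
  expect_equal(scene_truth(p1)$Dmax_um, 2 * (50 + 25), tolerance = 0.2)
})

test_that("clumps branch, elongate and sit in the filamentous Mo regime", {
  un <- generate_clump(n_steps = 60, branch_prob = 0, width = 400,
                       height = 300, seed = 4)
  expect_equal(un$objects[[1]]$kind, "branched_hypha")

  fil <- generate_filament(arc_length_px = 300, width_px = 3)
  tr <- scene_truth(fil)
  expect_gt(tr$E, 4)
  expect_lt(tr$Mo, 0.5)
})

test_that("microparticle debris is booked as non-mycelial at the right scale", {
  sf <- generate_spore_field(n = 5, width = 1600, height = 1200,
                             calibration = 0.25, seed = 13)
  expect_identical(add_microparticles(sf, 0), sf)
  lit <- add_microparticles(sf, 100)
  tr <- scene_truth(lit)
  deb <- tr[!tr$mycelial, ]
  expect_equal(nrow(deb), 100)
  expect_true(all(deb$kind == "microparticle"))
  # the default angular grains are same-order but smaller than a 10 um disk
  expect_gt(mean(deb$A_um2), 0.2 * 78.5)
  expect_lt(mean(deb$A_um2), 0.9 * 78.5)

  # near-circular particles at the stated diameter approach pi * 5^2 um^2
  round_deb <- add_microparticles(sf, 50, shape_jitter = 0.05)
  tr2 <- scene_truth(round_deb)
  expect_equal(mean(tr2$A_um2[!tr2$mycelial]), pi * 25, tolerance = 0.3)
})

test_that("rendering honors intensities, green contrast and determinism", {
  sf <- generate_spore_field(n = 4, width = 300, height = 240,
                             calibration = 0.1, seed = 21)
  img <- render_scene(sf)
  g <- extract_green_plane(img)
  idx <- sf$objects[[1]]$idx
  expect_true(all(g$pixels[idx] == 60))
  expect_true(all(g$pixels[-unlist(lapply(sf$objects, `[[`, "idx"))] == 200))
  # green carries full contrast; red/blue are muted
  expect_gt(200 - 60, max(img$pixels[, , 1]) - min(img$pixels[, , 1]))
  # masks unaffected by rendering noise
  sf_noisy <- generate_spore_field(n = 4, width = 300, height = 240,
                                   calibration = 0.1, seed = 21, noise_sd = 5)
  expect_identical(lapply(sf$objects, `[[`, "idx"),
                   lapply(sf_noisy$objects, `[[`, "idx"))
  expect_identical(render_scene(sf)$pixels, img$pixels)
})

test_that("timecourse profiles follow the staged development", {
  tc <- simulate_timecourse("agglomerative-spore", seed = 2)
  expect_equal(tc$time_hr, c(0, 5, 8, 12, 18, 24))
  truths <- lapply(tc$scene, scene_truth)

  # t = 0: spores only, circular regime
  expect_true(all(truths[[1]]$kind == "spore"))
  expect_gte(mean(truths[[1]]$Mo), 0.6)

  # germination dips below the start, pellet stage rises again
  mo <- vapply(truths, function(t) mean(t$Mo, na.rm = TRUE), numeric(1))
  germ <- which(tc$stage == "germination")
  expect_lt(mo[germ], mo[1] - 0.2)
  expect_gt(mo[length(mo)], mo[germ] + 0.2)

  # mean projected area is non-decreasing for a growth profile
  a <- vapply(truths, function(t) mean(t$A_um2), numeric(1))
  expect_true(all(diff(a) > -1e-9))

  # the agglomerate stage straddles the 1e4 um^2 class threshold
  agg <- which(tc$stage == "agglomerates")
  expect_gt(sum(truths[[agg]]$class == "small"), 0)
  expect_gt(sum(truths[[agg]]$class == "large"), 0)
})

test_that("timecourses are reproducible and validate their inputs", {
  t1 <- simulate_timecourse("agglomerative-spore", seed = 5, times = c(0, 5))
  t2 <- simulate_timecourse("agglomerative-spore", seed = 5, times = c(0, 5))
  expect_identical(lapply(t1$scene[[1]]$objects, `[[`, "idx"),
                   lapply(t2$scene[[1]]$objects, `[[`, "idx"))
  expect_error(simulate_timecourse("martian-mold"), "available")
  expect_error(simulate_timecourse(list()), "Empty")
  expect_length(timecourse_profiles(), 4)
})
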