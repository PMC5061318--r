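test_that("rendering is deterministic under a fixed seed", {
  spec <- larva_spec(axis_angle = 33)
  a <- render_pose(spec, rng_seed = 5)
  b <- render_pose(spec, rng_seed = 5)
  expect_identical(a$brightfield, b$brightfield)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("noise-free healthy render shows exactly n_neurons disjoint disks in focus", {
  spec <- larva_spec(axis_angle = 120, noise_sd = 0)
  pose <- render_pose(spec, rng_seed = 7)
  focus <- pose$fluorescence[, , spec$focus_slice + 1L]
  # neurons are far brighter than eyes/yolk/head; count components above
  # half the dimmest neuron amplitude
  thr <- 0.5 * 0.8 * spec$neuron_intensity
  labs <- multipose:::label_components(focus > thr)
  expect_equal(max(labs), spec$n_neurons)
  expect_equal(nrow(pose$ground_truth$neurons), spec$n_neurons)
})

test_that("full ablation leaves yolk but no neuron disks", {
  spec <- larva_spec(axis_angle = 10, ablation_fraction = 1, noise_sd = 0)
  pose <- render_pose(spec, rng_seed = 8)
  focus <- pose$fluorescence[, , spec$focus_slice + 1L]
  labs <- multipose:::label_components(focus > 0.5 * 0.8 * spec$neuron_intensity)
  expect_equal(max(labs), 0L)
  expect_equal(nrow(pose$ground_truth$neurons), 0L)
  # the yolk blob is still present caudally
  ax <- multipose:::body_axes(spec)
  yc <- round(spec$head_center + ax$t * 300)
  expect_gt(focus[yc[1], yc[2]], spec$fluor_offset + 0.5 * spec$yolk_intensity)
})

test_that("geometry placing eyes outside the frame is rejected", {
  expect_error(larva_spec(head_center = c(30, 30)), "outside")
  expect_error(render_pose(larva_spec(head_center = c(520, 1330))), "outside")
})

test_that("bright-field has bright background, dark eyes flanking the midline", {
  fx <- fx_dorsal()
  bf <- fx$pose$brightfield
  gt <- fx$pose$ground_truth
  expect_gt(median(bf), 2800)
  for (i in 1:2) {
    ec <- round(gt$eye_centroids[i, ])
    expect_lt(bf[ec[1], ec[2]], 500)
  }
  # eye centroids symmetric about the rostro-caudal axis
  ax <- multipose:::body_axes(fx$spec)
  off <- sweep(gt$eye_centroids, 2, gt$head_center)
  lat <- off %*% ax$p
  expect_equal(lat[1], -lat[2], tolerance = 1e-9)
  expect_equal(abs(lat[1]), fx$spec$eye_separation_px / 2, tolerance = 2)
})

test_that("defocus grows away from the focus slice", {
  spec <- larva_spec(axis_angle = 0, noise_sd = 0)
  pose <- render_pose(spec, rng_seed = 4)
  # the focus slice has the sharpest (largest) maximum
  maxima <- apply(pose$fluorescence, 3, max)
  expect_equal(which.max(maxima), spec$focus_slice + 1L)
  # projection dominates every slice pixelwise
  proj <- max_project(pose$fluorescence)
  for (z in 1:7) expect_true(all(proj >= pose$fluorescence[, , z]))
})

test_that("orientation draws follow p_dorsal", {
  w1 <- simulate_well(n_cycles = 5, p_dorsal = 1, rng_seed = 3, render = FALSE)
  expect_true(all(vapply(w1, function(p) p$ground_truth$orientation,
                         character(1)) == "dorsal_down"))
  w0 <- simulate_well(n_cycles = 5, p_dorsal = 0, rng_seed = 3, render = FALSE)
  expect_true(all(vapply(w0, function(p) p$ground_truth$orientation,
                         character(1)) != "dorsal_down"))
})

test_that("cumulative dorsal-pose fraction matches the binomial complement", {
  p <- 0.688; cycles <- 4L; n_wells <- 10000L
  got <- vapply(seq_len(n_wells), function(i) {
    w <- simulate_well(n_cycles = cycles, p_dorsal = p, rng_seed = i,
                       render = FALSE)
    any(vapply(w, function(x) x$ground_truth$orientation, character(1)) ==
          "dorsal_down")
  }, logical(1))
  expected <- 1 - (1 - p)^cycles
  se <- sqrt(expected * (1 - expected) / n_wells)
  expect_lt(abs(mean(got) - expected), 3 * se)
})

test_that("synthetic_crop stamps the requested disjoint disks", {
  cr <- synthetic_crop(12, rng_seed = 3)
  expect_equal(nrow(cr$disks), 12)
  labs <- multipose:::label_components(cr$image > 0)
  expect_equal(max(labs), 12L)
  cr0 <- synthetic_crop(0)
  expect_true(all(cr0$image == 0))
})

test_that("simulate_plate refuses duplicate wells and defaults to healthy", {
  expect_error(plate_layout(c("A1", "A1"), condition = "DMSO"), "duplicate")
  lay2 <- plate_layout(c("A1", "B2"), condition = "DMSO", arm = "+")
  dir <- withr::local_tempdir()
  small <- larva_spec(image_shape = c(420L, 460L))
  sim <- simulate_plate(lay2, dir = dir, spec = small, n_cycles = 1,
                        p_dorsal = 1, rng_seed = 9)
  expect_true(all(sim$ground_truth$ablation_fraction == 0))
  expect_equal(nrow(sim$manifest), 2 * 8)
})

test_that("simulate_plate output is reproducible byte-for-byte", {
  lay <- plate_layout("C3", condition = "DMSO", arm = "+")
  small <- larva_spec(image_shape = c(420L, 460L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_plate(lay, dir = d1, spec = small, n_cycles = 1, rng_seed = 4)
  s2 <- simulate_plate(lay, dir = d2, spec = small, n_cycles = 1, rng_seed = 4)
  for (i in seq_len(nrow(s1$manifest))) {
    f1 <- file.path(d1, basename(s1$manifest$path[i]))
    f2 <- file.path(d2, basename(s2$manifest$path[i]))
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})
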