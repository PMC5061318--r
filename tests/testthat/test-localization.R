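test_that("max projection behaves as a pixelwise maximum", {
  one <- array(matrix(1:12, 3, 4), dim = c(3, 4, 1))
  expect_equal(max_project(one), matrix(1:12, 3, 4))
  st <- array(0, dim = c(4, 5, 3))
  st[2, 3, 2] <- 7
  pr <- max_project(st)
  expect_equal(sum(pr == 7), 1L)
  expect_equal(pr[2, 3], 7)
  expect_error(max_project(array(0, dim = c(3, 3, 0))))
})

test_that("circular Hough recovers a head-sized blob and rejects others", {
  img <- matrix(100, 1040, 1392)
  img <- multipose:::stamp_ellipse(img, c(430, 710), 55, 55, 0, 600)
  img <- gauss_blur(img, 6)
  h <- detect_head(img)
  expect_true(h$ok)
  expect_lt(sqrt(sum((h$center - c(430, 710))^2)), 5)
  expect_gt(h$radius, 40); expect_lt(h$radius, 75)

  blank <- matrix(100, 1040, 1392)
  expect_false(detect_head(blank)$ok)

  small <- gauss_blur(multipose:::stamp_ellipse(matrix(100, 1040, 1392),
                                                c(500, 600), 20, 20, 0, 600), 4)
  expect_false(detect_head(small)$ok)
})

test_that("orientation normalization leaves the axis vertical, head up", {
  fx <- fx_dorsal()
  expect_true(fx$loc$ok)
  # residual axis angle below 2 degrees (axis rendered at 37 degrees)
  resid <- abs(((fx$loc$angle + fx$spec$axis_angle + 180) %% 360) - 180)
  expect_lt(resid, 2)

  # an already head-up larva needs (nearly) no rotation
  up <- render_pose(larva_spec(axis_angle = 0), rng_seed = 11)
  proj <- max_project(up$fluorescence)
  h <- detect_head(up$fluorescence[, , 1])
  o <- orient_head_up(proj, up$brightfield, h$center)
  expect_lt(abs(o$angle), 2)

  # head initially at the bottom: rotation includes the 180-degree flip
  down <- render_pose(larva_spec(axis_angle = 180, head_center = c(720, 696)),
                      rng_seed = 12)
  projd <- max_project(down$fluorescence)
  hd <- detect_head(down$fluorescence[, , 1])
  od <- orient_head_up(projd, down$brightfield, hd$center)
  expect_lt(od$head_center[1], (nrow(projd) + 1) / 2)
  expect_lt(abs(abs(od$angle) - 180), 2)
})

test_that("eye detection finds both eyes on dorsal poses and fails otherwise", {
  fx <- fx_dorsal()
  eyes_gt <- transform_points(fx$pose$ground_truth$eye_centroids,
                              fx$loc$angle, dim(fx$pose$brightfield),
                              scale = 0.5)
  eyes_gt <- eyes_gt[order(eyes_gt[, 2]), ]
  expect_lt(max(sqrt(rowSums((eyes_gt - fx$loc$eyes)^2))), 5)
  # left eye first
  expect_lt(fx$loc$eyes[1, 2], fx$loc$eyes[2, 2])

  lat <- fx_lateral()
  latloc <- multipose:::localize_pose(lat$brightfield, lat$fluorescence)
  expect_false(latloc$ok)

  gray <- matrix(2000, 1040, 1392)
  expect_false(detect_eyes(gray)$ok)
})

test_that("brain centre is the eye midpoint offset caudally", {
  bc <- locate_brain_center(c(100, 80), c(100, 120))
  expect_equal(bc$half, c(135, 100))
  expect_equal(bc$full, c(270, 200))

  # tilted eye segment: verify against rotating the level case
  a <- c(100, 80); b <- c(110, 120)
  bc_t <- locate_brain_center(a, b)
  tilt <- atan2(b[1] - a[1], b[2] - a[2])
  mid <- (a + b) / 2
  expected <- mid + 35 * c(cos(tilt), -sin(tilt))
  expect_equal(bc_t$half, expected, tolerance = 1e-12)
  expect_gte(bc_t$half[1], mid[1])  # caudal = increasing rows

  # symmetric under eye order swap
  expect_equal(locate_brain_center(b, a)$full, bc_t$full)
  expect_error(locate_brain_center(a, a), "coincident")
})

test_that("brain crop has the exact shape, pads edges, and masks the eyes", {
  fx <- fx_dorsal()
  crop <- fx$loc$crop
  expect_equal(dim(crop$image), c(190L, 220L))
  expect_equal(dim(crop$eye_mask), c(190L, 220L))
  expect_length(crop$qc_flags, 0)

  # near-edge centre: same shape, edge_pad flag, zero padding
  proj <- max_project(fx$pose$fluorescence)
  edge <- crop_brain(proj, fx$pose$brightfield, c(10, 700))
  expect_equal(dim(edge$image), c(190L, 220L))
  expect_true("edge_pad" %in% edge$qc_flags)
  expect_true(all(edge$image[1:10, ] == 0))
  expect_error(crop_brain(proj, fx$pose$brightfield, c(-5, 700)), "outside")

  # eye mask covers at least 90% of each rendered eye ellipse in the crop
  gt <- fx$pose$ground_truth
  spec <- fx$spec
  ax <- multipose:::body_axes(spec)
  ctr_crop <- round(fx$loc$brain_center_full) - c(95, 110)
  for (i in 1:2) {
    th <- seq(0, 2 * pi, length.out = 120)
    rr <- seq(0.1, 0.9, by = 0.2)
    pts <- do.call(rbind, lapply(rr, function(f)
      sweep(cbind(f * spec$eye_axes_px[2] / 2 * cos(th),
                  f * spec$eye_axes_px[1] / 2 * sin(th)) %*%
              rbind(ax$t, ax$p), 2, gt$eye_centroids[i, ], "+")))
    pts_rot <- transform_points(pts, fx$loc$angle, dim(fx$pose$brightfield))
    ij <- round(sweep(pts_rot, 2, ctr_crop))
    keep <- ij[, 1] >= 1 & ij[, 1] <= 190 & ij[, 2] >= 1 & ij[, 2] <= 220
    ij <- ij[keep, , drop = FALSE]
    expect_gt(nrow(ij), 0)
    expect_gt(mean(fx$loc$crop$eye_mask[ij]), 0.9)
  }
})

test_that("best-pose selection honours overrides, ties, and unique successes", {
  fx <- fx_dorsal()
  lat <- fx_lateral()
  dorsal_pose <- list(brightfield = fx$pose$brightfield,
                      fluorescence = fx$pose$fluorescence, cycle = 3L)
  lateral_pose <- function(cy) list(brightfield = lat$brightfield,
                                    fluorescence = lat$fluorescence, cycle = cy)

  # unique success: only the dorsal cycle is usable
  sel <- select_best_pose(list(lateral_pose(1L), lateral_pose(2L), dorsal_pose))
  expect_true(sel$ok)
  expect_equal(sel$chosen_cycle, 3L)

  # manual override is used verbatim
  two <- list(dorsal_pose,
              list(brightfield = fx$pose$brightfield,
                   fluorescence = fx$pose$fluorescence, cycle = 5L))
  man <- select_best_pose(two, manual_choice = 5L)
  expect_equal(man$chosen_cycle, 5L)

  # identical successful poses: tie broken by the lower cycle index
  tie <- select_best_pose(two)
  expect_equal(tie$chosen_cycle, 3L)
})

test_that("localize_well reports unusable wells and is deterministic", {
  lat <- fx_lateral()
  poses <- list(list(brightfield = lat$brightfield,
                     fluorescence = lat$fluorescence, cycle = 1L))
  r <- localize_well(poses, well = "B7")
  expect_false(r$usable)
  expect_equal(nrow(r$provenance), 1L)
  expect_false(r$provenance$ok[1])

  fx <- fx_dorsal()
  dp <- list(list(brightfield = fx$pose$brightfield,
                  fluorescence = fx$pose$fluorescence, cycle = 1L))
  r1 <- localize_well(dp, well = "A1")
  r2 <- localize_well(dp, well = "A1")
  expect_identical(r1$crop$image, r2$crop$image)
  expect_identical(r1$angle, r2$angle)
})
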