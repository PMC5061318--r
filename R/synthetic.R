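#' Specification of a synthetic larva acquisition
#'
#' Describes one stylized zebrafish larva and the acquisition geometry used by
#' [render_pose()]. Defaults are sized so that the pipeline's fixed detection
#' parameters apply: the head blob falls inside the 80--150 px circular Hough
#' range, and the half-size eyes (about 45 x 65 px) respond to the fixed
#' 60 x 90 px oval eye filter.
#'
#' @param image_shape integer (rows, cols) of each frame.
#' @param orientation `"dorsal_down"` (both eyes flank the midline and the
#'   brain is in clear view), `"lateral_down"` (one eye lies over the brain
#'   area) or `"not_imageable"` (no larva in view).
#' @param axis_angle rostro-caudal axis angle in degrees, in `[0, 360)`;
#'   0 means head-up (rostral toward row 0).
#' @param head_center (row, col) of the head centre in full-size pixels.
#' @param head_diameter_px diameter of the diffuse head autofluorescence blob.
#' @param eye_axes_px (minor, major) full-size eye ellipse axis lengths.
#' @param eye_separation_px distance between the two eye centres.
#' @param n_neurons number of fluorescent neurons in the cluster.
#' @param neuron_diameter_px (min, max) neuron disk diameters in pixels.
#' @param neuron_intensity neuron fluorescence amplitude in camera counts.
#' @param cluster_radius_px radius of the disc holding the neuron cluster.
#' @param ablation_fraction fraction of neurons ablated, in `[0, 1]`; each
#'   neuron independently survives with probability `1 - ablation_fraction`.
#' @param yolk_intensity peak of the diffuse yolk autofluorescence blob
#'   (set 0 to disable).
#' @param texture_intensity amplitude of the smooth dim autofluorescence
#'   texture covering the body and head (the diffuse neuropil/tissue
#'   fluorescence that real larvae show; it forms the extended dim background
#'   class that intensity thresholds calibrate against).
#' @param texture_sigma correlation length of that texture, pixels.
#' @param eye_fluor_intensity eye autofluorescence level in the fluorescence
#'   channel (the reason the pipeline masks eyes before scoring).
#' @param noise_sd Gaussian camera noise standard deviation in counts.
#' @param focus_slice z-index (0-based, 0--6) of the in-focus slice.
#' @param bf_background,bf_body,bf_eye bright-field levels in counts:
#'   transmitted-light background, (PTU-treated, nearly transparent) body,
#'   and heavily pigmented eye.
#' @param fluor_offset camera offset of the fluorescence channel.
#'
#' @return a `larva_spec` list.
#' @seealso [render_pose()], [simulate_well()], [simulate_plate()]
#' @export
larva_spec <- function(image_shape = c(1040L, 1392L),
                       orientation = c("dorsal_down", "lateral_down", "not_imageable"),
                       axis_angle = 0,
                       head_center = NULL,
                       head_diameter_px = 110,
                       eye_axes_px = c(90, 130),
                       eye_separation_px = 160,
                       n_neurons = 30L,
                       neuron_diameter_px = c(8, 14),
                       neuron_intensity = 8000,
                       cluster_radius_px = 65,
                       ablation_fraction = 0,
                       yolk_intensity = 1200,
                       texture_intensity = 120,
                       texture_sigma = 3,
                       eye_fluor_intensity = 800,
                       noise_sd = 50,
                       focus_slice = 3L,
                       bf_background = 3000,
                       bf_body = 2800,
                       bf_eye = 150,
                       fluor_offset = 100) {
  orientation <- match.arg(orientation)
  if (is.null(head_center)) head_center <- (image_shape + 1) / 2
  axis_angle <- axis_angle %% 360
  stopifnot(length(image_shape) == 2, all(image_shape > 0),
            ablation_fraction >= 0, ablation_fraction <= 1,
            focus_slice >= 0, focus_slice <= 6,
            n_neurons >= 0, length(neuron_diameter_px) == 2,
            eye_separation_px > 0, length(eye_axes_px) == 2)
  spec <- list(
    image_shape = as.integer(image_shape), orientation = orientation,
    axis_angle = axis_angle, head_center = as.numeric(head_center),
    head_diameter_px = head_diameter_px, eye_axes_px = eye_axes_px,
    eye_separation_px = eye_separation_px, n_neurons = as.integer(n_neurons),
    neuron_diameter_px = neuron_diameter_px,
    neuron_intensity = neuron_intensity,
    cluster_radius_px = cluster_radius_px,
    ablation_fraction = ablation_fraction,
    yolk_intensity = yolk_intensity,
    texture_intensity = texture_intensity,
    texture_sigma = texture_sigma,
    eye_fluor_intensity = eye_fluor_intensity,
    noise_sd = noise_sd, focus_slice = as.integer(focus_slice),
    bf_background = bf_background, bf_body = bf_body, bf_eye = bf_eye,
    fluor_offset = fluor_offset
  )
  class(spec) <- "larva_spec"
  validate_larva_geometry(spec)
  spec
}

# Unit vectors of the body frame: `t` points head -> tail, `p` is the
# perpendicular (left-right) direction.
body_axes <- function(spec) {
  th <- spec$axis_angle * pi / 180
  list(t = c(cos(th), sin(th)), p = c(-sin(th), cos(th)))
}

eye_centers <- function(spec) {
  ax <- body_axes(spec)
  if (spec$orientation == "dorsal_down") {
    rbind(spec$head_center + ax$p * spec$eye_separation_px / 2,
          spec$head_center - ax$p * spec$eye_separation_px / 2)
  } else if (spec$orientation == "lateral_down") {
    rbind(spec$head_center)
  } else {
    matrix(numeric(0), 0, 2)
  }
}

validate_larva_geometry <- function(spec) {
  ec <- eye_centers(spec)
  if (nrow(ec) == 0) return(invisible(spec))
  reach <- max(spec$eye_axes_px) / 2
  lo <- apply(ec, 2, min) - reach
  hi <- apply(ec, 2, max) + reach
  if (any(lo < 1) || hi[1] > spec$image_shape[1] || hi[2] > spec$image_shape[2]) {
    stop("larva geometry places an eye outside the image frame")
  }
  invisible(spec)
}

# Defocus model: Gaussian blur whose sigma grows linearly with the distance
# from the focus slice. Simplest monotone defocus proxy; sufficient for
# testing maximum-intensity projection behaviour.
defocus_sigma <- function(z, focus_slice, sigma0 = 1.5, slope = 2.5) {
  sigma0 + slope * abs(z - focus_slice)
}

# Rejection-sample non-overlapping neuron centres inside the cluster disc,
# avoiding the (dorsal-view) eye ellipses: in the dorsal pose the DA cluster
# sits between/behind the eyes with an unobstructed view, which is the
# premise of the assay. Draws use the current RNG stream. Guarantees
# pairwise gaps >= min_gap so that, without noise, rendered disks stay
# disjoint.
place_neurons <- function(spec, min_gap = 4) {
  n <- spec$n_neurons
  if (n == 0L) {
    return(tibble::tibble(row = numeric(), col = numeric(),
                          diameter = numeric(), intensity = numeric()))
  }
  ax <- body_axes(spec)
  ctr <- spec$head_center + ax$t * 70
  # dorsal eye positions, used as exclusion zones in every orientation
  eye_ctrs <- rbind(spec$head_center + ax$p * spec$eye_separation_px / 2,
                    spec$head_center - ax$p * spec$eye_separation_px / 2)
  in_eye <- function(cand, margin) {
    a <- spec$eye_axes_px[2] / 2 + margin   # along the body axis
    b <- spec$eye_axes_px[1] / 2 + margin   # across it
    for (j in 1:2) {
      off <- cand - eye_ctrs[j, ]
      u <- sum(off * ax$t); v <- sum(off * ax$p)
      if ((u / a)^2 + (v / b)^2 <= 1) return(TRUE)
    }
    FALSE
  }
  d <- runif(n, spec$neuron_diameter_px[1], spec$neuron_diameter_px[2])
  # sequential rejection sampling with whole-configuration restarts: a bad
  # early arrangement can strand the last disks, so retry from scratch
  for (attempt in seq_len(20L)) {
    rows <- cols <- numeric(n)
    placed <- TRUE
    for (i in seq_len(n)) {
      done <- FALSE
      for (try in seq_len(400L)) {
        ang <- runif(1, 0, 2 * pi)
        rad <- spec$cluster_radius_px * sqrt(runif(1))
        # offsets drawn in the body frame, so the same seed renders the
        # same larva irrespective of its axis angle
        cand <- ctr + rad * cos(ang) * ax$t + rad * sin(ang) * ax$p
        ok <- !in_eye(cand, margin = d[i] / 2 + 2)
        if (ok && i > 1L) {
          dd <- sqrt((rows[seq_len(i - 1)] - cand[1])^2 +
                     (cols[seq_len(i - 1)] - cand[2])^2)
          ok <- all(dd >= (d[seq_len(i - 1)] + d[i]) / 2 + min_gap)
        }
        if (ok) { rows[i] <- cand[1]; cols[i] <- cand[2]; done <- TRUE; break }
      }
      if (!done) { placed <- FALSE; break }
    }
    if (placed) break
    if (attempt == 20L) stop("could not place neurons without overlap; ",
                             "reduce n_neurons or enlarge cluster_radius_px")
  }
  tibble::tibble(row = rows, col = cols, diameter = d,
                 intensity = spec$neuron_intensity * runif(n, 0.8, 1.2))
}

# Render one pose using the *current* RNG stream (callers seed it).
render_pose_impl <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ax <- body_axes(spec)
  ec <- eye_centers(spec)
  brain_center <- spec$head_center + ax$t * 70

  neurons <- place_neurons(spec)
  if (nrow(neurons) > 0 && spec$ablation_fraction > 0) {
    survive <- if (spec$ablation_fraction >= 1) rep(FALSE, nrow(neurons)) else
      runif(nrow(neurons)) >= spec$ablation_fraction
    neurons <- neurons[survive, , drop = FALSE]
  }

  # ---- bright-field ----
  body <- if (spec$orientation != "not_imageable") {
    capsule_mask(c(nr, nc), spec$head_center - ax$t * 40,
                 spec$head_center + ax$t * 480, 85)
  } else NULL
  bf <- matrix(spec$bf_background, nr, nc)
  if (spec$orientation != "not_imageable") {
    bf[body] <- spec$bf_body
    for (i in seq_len(nrow(ec))) {
      bf <- stamp_ellipse(bf, ec[i, ], a = spec$eye_axes_px[2] / 2,
                          b = spec$eye_axes_px[1] / 2,
                          theta_deg = spec$axis_angle, value = spec$bf_eye)
    }
    bf <- cpp_gauss_blur(bf, 2)
  }
  bf <- matrix(cpp_noise_quantize(bf, spec$noise_sd), nr, nc)

  # ---- fluorescence scene (in-focus) ----
  sc <- matrix(spec$fluor_offset, nr, nc)
  if (spec$orientation != "not_imageable") {
    sc[body] <- spec$fluor_offset + 40
    if (spec$texture_intensity > 0) {
      # diffuse tissue autofluorescence: half-rectified correlated noise
      tex <- cpp_gauss_blur(matrix(rnorm(nr * nc), nr, nc), spec$texture_sigma)
      tex <- pmax(tex / stats::sd(tex), 0) * spec$texture_intensity
      sc[body] <- sc[body] + tex[body]
    }
    sc <- stamp_ellipse(sc, spec$head_center, a = spec$head_diameter_px / 2,
                        b = spec$head_diameter_px / 2, theta_deg = 0,
                        value = spec$fluor_offset + 250)
    for (i in seq_len(nrow(ec))) {
      sc <- stamp_ellipse(sc, ec[i, ], a = spec$eye_axes_px[2] / 2,
                          b = spec$eye_axes_px[1] / 2,
                          theta_deg = spec$axis_angle,
                          value = spec$fluor_offset + spec$eye_fluor_intensity)
    }
    if (spec$yolk_intensity > 0) {
      sc <- stamp_gaussian_blob(sc, spec$head_center + ax$t * 300, 70,
                                spec$yolk_intensity)
    }
    for (i in seq_len(nrow(neurons))) {
      sc <- stamp_ellipse(sc, c(neurons$row[i], neurons$col[i]),
                          a = neurons$diameter[i] / 2,
                          b = neurons$diameter[i] / 2, theta_deg = 0,
                          value = neurons$intensity[i] + spec$fluor_offset)
    }
  }

  sigmas <- defocus_sigma(0:6, spec$focus_slice)
  fluo <- cpp_render_stack(sc, sigmas, spec$noise_sd)

  gt <- list(
    orientation = spec$orientation,
    axis_angle = spec$axis_angle,
    head_center = spec$head_center,
    eye_centroids = ec,
    brain_center = brain_center,
    neurons = neurons
  )
  list(brightfield = bf, fluorescence = fluo, ground_truth = gt, spec = spec)
}

#' Render one synthetic pose acquisition
#'
#' Renders one bright-field frame plus a seven-slice fluorescence z-stack of a
#' stylized larva, with per-pixel ground truth. The bright-field shows a
#' bright transmitted-light background, a faint body and near-black eye
#' ellipses; the fluorescence scene contains the neuron cluster near the brain
#' centre, diffuse head and eye autofluorescence and a caudal yolk blob.
#' Out-of-focus slices are blurred proportionally to their distance from the
#' focus slice, then Gaussian camera noise is added and intensities are
#' quantized to 16-bit counts. Identical `(spec, rng_seed)` give bit-identical
#' output.
#'
#' @param spec a [larva_spec()].
#' @param rng_seed integer seed controlling all randomness of the render.
#' @return list with elements `brightfield` (matrix), `fluorescence`
#'   (`rows x cols x 7` array), `ground_truth` (orientation, axis angle, eye
#'   centroids, brain centre, surviving neuron table) and `spec`.
#' @export
render_pose <- function(spec, rng_seed = 1L) {
  stopifnot(inherits(spec, "larva_spec"))
  validate_larva_geometry(spec)
  withr::with_seed(as.integer(rng_seed), render_pose_impl(spec))
}

# Draw per-cycle orientations; dorsal with probability p_dorsal, the
# remainder split between lateral (90%) and not-imageable (10%).
draw_orientations <- function(n_cycles, p_dorsal) {
  u <- runif(n_cycles)
  ifelse(u < p_dorsal, "dorsal_down",
         ifelse(u < p_dorsal + (1 - p_dorsal) * 0.9,
                "lateral_down", "not_imageable"))
}

#' Simulate repeated reposing of one well
#'
#' Each cycle independently draws an orientation (dorsal-side-down with
#' probability `p_dorsal`, mirroring the round-bottom-plate posing rate) and a
#' fresh uniform axis angle and head position, then renders the acquisition.
#' Orientation draws are independent across cycles.
#'
#' @param spec base [larva_spec()]; orientation, axis angle and head centre
#'   are redrawn per cycle.
#' @param n_cycles number of imaging/re-posing cycles (the assay uses 5).
#' @param p_dorsal probability of a dorsal-side-down pose per cycle (0.688 is
#'   the observed round-bottom plate rate).
#' @param rng_seed integer seed.
#' @param render if `FALSE`, skip image rendering and return pose metadata and
#'   ground truth only (fast path for pose-statistics simulations).
#' @return list of per-cycle entries: `cycle`, `orientation`, `ground_truth`
#'   and (when rendered) `brightfield`/`fluorescence`.
#' @export
simulate_well <- function(spec = larva_spec(), n_cycles = 5L, p_dorsal = 0.688,
                          rng_seed = 1L, render = TRUE) {
  stopifnot(n_cycles >= 1, p_dorsal >= 0, p_dorsal <= 1)
  withr::with_seed(as.integer(rng_seed), {
    orientations <- draw_orientations(n_cycles, p_dorsal)
    lapply(seq_len(n_cycles), function(cy) {
      ang <- runif(1, 0, 360)
      jit_ang <- runif(1, 0, 2 * pi)
      jit_rad <- 60 * sqrt(runif(1))
      ctr <- (spec$image_shape + 1) / 2 +
        jit_rad * c(cos(jit_ang), sin(jit_ang))
      sp <- spec
      sp$orientation <- orientations[cy]
      sp$axis_angle <- ang
      sp$head_center <- ctr
      class(sp) <- "larva_spec"
      if (render) {
        out <- render_pose_impl(sp)
        out$cycle <- cy
        out
      } else {
        list(cycle = cy, ground_truth = list(
          orientation = sp$orientation, axis_angle = sp$axis_angle,
          head_center = sp$head_center), spec = sp)
      }
    })
  })
}

#' Simulate a whole assay plate and write it to disk
#'
#' Renders every well of a plate layout, writes 16-bit TIFFs plus a CSV
#' manifest readable by [read_manifest()], and returns the per-well ground
#' truth (applied ablation fraction and surviving neuron count). Per-well
#' neuron and yolk brightness are jittered log-normally to emulate
#' larva-to-larva expression variability.
#'
#' @param layout plate layout tibble from [plate_layout()] (columns `well`,
#'   `condition`, `arm`).
#' @param effect_map named numeric vector mapping well id to ablation
#'   fraction; wells not named are healthy (ablation 0).
#' @param dir output directory (created if needed).
#' @param spec base [larva_spec()].
#' @param n_cycles,p_dorsal per-well posing parameters, as [simulate_well()].
#' @param rng_seed integer seed; per-well sub-seeds are derived from it.
#' @param plate plate identifier written to the manifest.
#' @return invisibly, a list with `manifest` (tibble), `ground_truth`
#'   (tibble: well, condition, ablation_fraction, n_neurons_surviving per
#'   cycle), and the file paths written.
#' @export
simulate_plate <- function(layout, effect_map = numeric(), dir,
                           spec = larva_spec(), n_cycles = 1L, p_dorsal = 1,
                           rng_seed = 1L, plate = "plate1") {
  stopifnot(is.data.frame(layout), all(c("well", "condition") %in% names(layout)))
  if (anyDuplicated(layout$well)) stop("duplicate well IDs in layout")
  if (length(effect_map) && anyDuplicated(names(effect_map)))
    stop("duplicate well IDs in effect_map")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  wells <- layout$well
  manifest <- list(); gt_rows <- list()
  withr::with_seed(as.integer(rng_seed), {
    well_seeds <- sample.int(.Machine$integer.max - 1L, length(wells))
  })
  for (i in seq_along(wells)) {
    w <- wells[i]
    abl <- if (w %in% names(effect_map)) unname(effect_map[[w]]) else 0
    sp <- spec
    sp$ablation_fraction <- abl
    withr::with_seed(well_seeds[i], {
      sp$neuron_intensity <- spec$neuron_intensity * exp(rnorm(1, 0, 0.10))
      sp$yolk_intensity <- spec$yolk_intensity * exp(rnorm(1, 0, 0.15))
      class(sp) <- "larva_spec"
      poses <- simulate_well(sp, n_cycles = n_cycles, p_dorsal = p_dorsal,
                             rng_seed = sample.int(.Machine$integer.max - 1L, 1))
    })
    for (p in poses) {
      cy <- p$cycle
      bf_path <- file.path(dir, sprintf("%s_%s_c%d_BF.tif", plate, w, cy))
      write_count_tiff(p$brightfield, bf_path)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        plate = plate, well = w, cycle = cy, channel = "BF", z_index = 0L,
        path = basename(bf_path))
      for (z in 0:6) {
        fl_path <- file.path(dir, sprintf("%s_%s_c%d_FLUO_z%d.tif", plate, w, cy, z))
        write_count_tiff(p$fluorescence[, , z + 1L], fl_path)
        manifest[[length(manifest) + 1L]] <- tibble::tibble(
          plate = plate, well = w, cycle = cy, channel = "FLUO",
          z_index = z, path = basename(fl_path))
      }
      gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
        plate = plate, well = w, cycle = cy,
        condition = layout$condition[i],
        orientation = p$ground_truth$orientation,
        ablation_fraction = abl,
        n_neurons_surviving = nrow(p$ground_truth$neurons),
        brain_center_row = p$ground_truth$brain_center[1],
        brain_center_col = p$ground_truth$brain_center[2])
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  gt <- dplyr::bind_rows(gt_rows)
  manifest_path <- file.path(dir, "manifest.csv")
  gt_path <- file.path(dir, "ground_truth.csv")
  readr::write_csv(manifest, manifest_path)
  readr::write_csv(gt, gt_path)
  invisible(list(manifest = manifest, ground_truth = gt,
                 manifest_path = manifest_path, ground_truth_path = gt_path,
                 dir = dir))
}

#' Construct a ground-truthed synthetic brain crop
#'
#' Stamps `n_disks` non-overlapping hard-edged disks of known diameter onto a
#' zero background at crop scale — the noise-free fixture for validating
#' neuron segmentation and scoring, where the true object count and geometry
#' are known by construction.
#'
#' @param n_disks number of disks.
#' @param diameter_range (min, max) disk diameters in pixels.
#' @param intensity disk intensity in counts.
#' @param shape crop dimensions (rows, cols).
#' @param min_gap minimum edge-to-edge gap between disks, pixels.
#' @param rng_seed integer seed.
#' @return list with `image` (matrix) and `disks` (tibble: row, col,
#'   diameter).
#' @export
synthetic_crop <- function(n_disks, diameter_range = c(8, 14),
                           intensity = 8000, shape = c(190L, 220L),
                           min_gap = 5, rng_seed = 1L) {
  withr::with_seed(as.integer(rng_seed), {
    img <- matrix(0, shape[1], shape[2])
    if (n_disks == 0L) {
      return(list(image = img,
                  disks = tibble::tibble(row = numeric(), col = numeric(),
                                         diameter = numeric())))
    }
    d <- runif(n_disks, diameter_range[1], diameter_range[2])
    margin <- max(d) / 2 + 2
    rows <- cols <- numeric(n_disks)
    for (i in seq_len(n_disks)) {
      for (try in seq_len(1000L)) {
        cand <- c(runif(1, margin, shape[1] - margin),
                  runif(1, margin, shape[2] - margin))
        ok <- i == 1L ||
          all(sqrt((rows[seq_len(i - 1)] - cand[1])^2 +
                   (cols[seq_len(i - 1)] - cand[2])^2) >=
              (d[seq_len(i - 1)] + d[i]) / 2 + min_gap)
        if (ok) { rows[i] <- cand[1]; cols[i] <- cand[2]; break }
        if (try == 1000L) stop("could not place disks without overlap")
      }
    }
    for (i in seq_len(n_disks)) {
      img <- stamp_ellipse(img, c(rows[i], cols[i]), d[i] / 2, d[i] / 2, 0,
                           intensity)
    }
    list(image = img, disks = tibble::tibble(row = rows, col = cols,
                                             diameter = d))
  })
}

# 16-bit unsigned TIFF I/O in camera counts.
write_count_tiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_count_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  round(x * 65535)
}
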