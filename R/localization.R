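#' Maximum intensity projection of a fluorescence stack
#'
#' @param stack `rows x cols x z` numeric array (at least one slice), or a
#'   matrix (returned unchanged).
#' @return matrix of per-pixel maxima over z.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L, dim(stack)[3] >= 1L)
  out <- stack[, , 1L]
  for (z in seq_len(dim(stack)[3])[-1L]) out <- pmax(out, stack[, , z])
  out
}

#' Detect the larval head by circular Hough transform
#'
#' Gradient-voting circular Hough transform: the image is lightly smoothed,
#' strong gradient pixels vote for circle centres along their gradient
#' direction over the search radius range, votes are accumulated on a coarse
#' grid, and the peak is refined to the vote centroid. Run on the first
#' (most defocused) fluorescence z-slice at full size, searching the standard
#' 80--150 px diameter range of this assay.
#'
#' @param fluor_slice 2-D fluorescence image.
#' @param d_min,d_max circle diameter search range in pixels.
#' @param smooth_sigma pre-smoothing sigma before gradients are taken.
#' @param n_edge number of strongest gradient pixels that vote.
#' @param bin accumulator bin size in pixels.
#' @param min_confidence minimum fraction of edge votes in the peak
#'   neighbourhood for a detection to count.
#' @return list with `ok`, `center` (row, col), `radius`, `confidence`, and
#'   `reason` when `ok` is `FALSE`.
#' @export
detect_head <- function(fluor_slice, d_min = 80, d_max = 150,
                        smooth_sigma = 3, n_edge = 4000L, bin = 4,
                        min_confidence = 0.04) {
  stopifnot(is.matrix(fluor_slice), all(dim(fluor_slice) > 4))
  nr <- nrow(fluor_slice); nc <- ncol(fluor_slice)
  sm <- cpp_gauss_blur(fluor_slice, smooth_sigma)
  # central-difference gradients
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  # strongest-gradient pixels vote; threshold from a subsampled quantile
  q <- 1 - n_edge / length(mag)
  thr_mag <- quantile(mag[seq(1L, length(mag), by = 7L)], q, names = FALSE)
  keep <- which(mag >= thr_mag)
  if (length(keep) > 1.5 * n_edge)
    keep <- keep[order(mag[keep], decreasing = TRUE)[seq_len(n_edge)]]
  if (length(keep) == 0L || max(mag[keep]) <= 0) {
    return(list(ok = FALSE, reason = "no_gradient"))
  }
  er <- ((keep - 1L) %% nr) + 1L
  ec <- ((keep - 1L) %/% nr) + 1L
  ur <- gr[keep] / mag[keep]
  uc <- gc[keep] / mag[keep]

  radii <- seq(d_min / 2, d_max / 2, by = 2.5)
  nbr <- ceiling(nr / bin); nbc <- ceiling(nc / bin)
  votes_r <- votes_c <- votes_rad <- numeric(0)
  for (r in radii) {
    # gradient points uphill, toward the bright interior: centre is at +r
    vr <- er + r * ur; vc <- ec + r * uc
    inside <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    votes_r <- c(votes_r, vr[inside])
    votes_c <- c(votes_c, vc[inside])
    votes_rad <- c(votes_rad, rep(r, sum(inside)))
  }
  if (length(votes_r) == 0L) return(list(ok = FALSE, reason = "no_votes"))
  br <- pmin(ceiling(votes_r / bin), nbr)
  bc <- pmin(ceiling(votes_c / bin), nbc)
  acc <- matrix(tabulate(br + (bc - 1L) * nbr, nbins = nbr * nbc), nbr, nbc)
  # smooth the accumulator over a 3x3 neighbourhood before peak-picking
  acc_s <- cpp_gauss_blur(acc, 1)

  # phase 2: walk the strongest accumulator peaks and keep the first whose
  # circle is supported by inward-pointing gradients along its perimeter --
  # this rejects vote pile-ups that do not correspond to a circle in the
  # searched radius range (e.g. blobs smaller than d_min)
  # magnitude floor for perimeter support: above the image's typical
  # (noise/texture) gradient, not tied to the strongest edges, so that
  # faint-but-real circular structures still validate
  mag_floor <- max(3 * median(mag[seq(1L, length(mag), by = 7L)]),
                   0.05 * thr_mag)
  support_fraction <- function(center, radius) {
    phi <- seq(0, 2 * pi, length.out = 73L)[-73L]
    pr <- round(center[1] + radius * cos(phi))
    pc <- round(center[2] + radius * sin(phi))
    inb <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
    if (!any(inb)) return(0)
    idx <- cbind(pr[inb], pc[inb])
    g <- cbind(gr[idx], gc[idx])
    gm <- sqrt(rowSums(g^2))
    to_ctr <- cbind(center[1] - pr[inb], center[2] - pc[inb]) / radius
    alignment <- rowSums(g * to_ctr) / pmax(gm, 1e-12)
    mean(gm > mag_floor & alignment > 0.6) * mean(inb)
  }
  acc_work <- acc_s
  best <- NULL
  min_support <- 0.35
  for (cand in seq_len(12L)) {
    pk <- which(acc_work == max(acc_work), arr.ind = TRUE)[1, ]
    if (acc_work[pk[1], pk[2]] <= 0) break
    pk_center <- c((pk[1] - 0.5) * bin, (pk[2] - 0.5) * bin)
    near <- sqrt((votes_r - pk_center[1])^2 +
                 (votes_c - pk_center[2])^2) <= 2.5 * bin
    confidence <- sum(near) / length(keep)
    if (confidence >= min_confidence) {
      center <- c(mean(votes_r[near]), mean(votes_c[near]))
      radius <- mean(votes_rad[near])
      sup <- support_fraction(center, radius)
      if (sup >= min_support && (is.null(best) || sup > best$support)) {
        best <- list(ok = TRUE, center = center, radius = radius,
                     confidence = confidence, support = sup)
      }
    }
    # suppress this peak neighbourhood and move on
    sr <- max(1, pk[1] - 4):min(nbr, pk[1] + 4)
    sc2 <- max(1, pk[2] - 4):min(nbc, pk[2] + 4)
    acc_work[sr, sc2] <- 0
  }
  if (is.null(best)) return(list(ok = FALSE, reason = "no_circle"))
  best
}

#' Rotate the acquisition to a head-up orientation
#'
#' The fluorescence projection is binarized with Otsu's threshold and a
#' principal component analysis of the foreground pixel coordinates gives the
#' long (rostro-caudal) axis of the fish. Both images are rotated about the
#' frame centre so that this axis is vertical; the 180-degree ambiguity is
#' resolved so that the head centre maps into the upper half of the frame.
#'
#' @param fluor_proj fluorescence maximum-intensity projection.
#' @param brightfield bright-field frame (same size).
#' @param head_center (row, col) head position from [detect_head()].
#' @return list with `ok`, rotated `fluor`, rotated `brightfield`, `angle`
#'   applied in degrees (in (-180, 180]), and the rotated `head_center`.
#' @export
orient_head_up <- function(fluor_proj, brightfield, head_center) {
  stopifnot(all(dim(fluor_proj) == dim(brightfield)))
  if (any(head_center < 1) || head_center[1] > nrow(fluor_proj) ||
      head_center[2] > ncol(fluor_proj)) {
    stop("head_center outside the frame")
  }
  # Otsu binarization of the projection. With a handful of very bright
  # somata the first split can isolate them alone, far too little area to
  # define a body axis; in that case the threshold is recomputed on the
  # remaining (sub-threshold) intensities, recovering the fish-versus-
  # background separation.
  v <- fluor_proj[seq(1, length(fluor_proj), by = 4L)]
  thr <- otsu_threshold(v)
  min_frac <- 0.005
  for (i in 1:2) {
    if (mean(v > thr) >= min_frac) break
    thr <- otsu_threshold(v[v <= thr])
  }
  fg <- which(fluor_proj > thr, arr.ind = TRUE)
  if (nrow(fg) < 16L) return(list(ok = FALSE, reason = "empty_foreground"))
  cov_fg <- stats::cov(fg)
  v1 <- eigen(cov_fg, symmetric = TRUE)$vectors[, 1]
  angle <- -atan2(v1[2], v1[1]) * 180 / pi
  # 180-degree ambiguity: the head must sit rostral of the body mass, i.e.
  # above the foreground centroid (which the yolk and trunk pull caudally)
  # in the head-up frame.
  centroid <- colMeans(fg)
  hc <- transform_points(head_center, angle, dim(fluor_proj))
  ce <- transform_points(centroid, angle, dim(fluor_proj))
  if (hc[1, 1] > ce[1, 1]) {
    angle <- angle + 180
    hc <- transform_points(head_center, angle, dim(fluor_proj))
  }
  angle <- ((angle + 180) %% 360) - 180
  # constant fill from subsampled medians (avoids dark rotation corners)
  fill_f <- median(v)
  fill_b <- median(brightfield[seq(1, length(brightfield), by = 4L)])
  list(ok = TRUE,
       fluor = rotate_image(fluor_proj, angle, fill = fill_f),
       brightfield = rotate_image(brightfield, angle, fill = fill_b),
       angle = angle,
       head_center = hc[1, ])
}

# Zero-mean matched filter for a dark oval of the given size (width x height
# in pixels): negative response to the bright surround, positive to the dark
# oval once the bright-field is inverted.
oval_kernel <- function(width = 60, height = 90) {
  hr <- floor(height / 2); hc <- floor(width / 2)
  rr <- -hr:hr; cc <- -hc:hc
  inside <- outer((rr / (height / 2))^2, (cc / (width / 2))^2, "+") <= 1
  k <- inside / sum(inside) - 1 / length(inside)
  k
}

#' Detect the two eyes in the head-up bright-field image
#'
#' The bright-field is downscaled to half size, inverted, and convolved with
#' a zero-mean matched filter for a dark 60 (wide) x 90 (tall) px oval. The
#' response is thresholded with Otsu's method and the centroids of the two
#' largest connected regions are returned (left eye first, i.e. smaller
#' column). Fails when fewer than two regions are found or the eye separation
#' is implausible (outside `[40, 120]` half-size pixels, a gate that rejects
#' yolk and frame-edge artifacts).
#'
#' @param brightfield_rotated full-size head-up bright-field image.
#' @param oval (width, height) of the eye filter in half-size pixels.
#' @param separation_range plausible eye-separation gate, half-size pixels.
#' @return list with `ok`, `eyes` (2 x 2 matrix of half-size (row, col)
#'   centroids), and `reason` when `ok` is `FALSE`.
#' @export
detect_eyes <- function(brightfield_rotated, oval = c(60, 90),
                        separation_range = c(40, 120)) {
  half <- resize_half(brightfield_rotated)
  inv <- max(half) - half
  resp <- EBImage::filter2(inv, oval_kernel(oval[1], oval[2]))
  resp <- matrix(as.numeric(resp), nrow(half), ncol(half))
  thr <- otsu_threshold(resp)
  mask <- resp > thr
  labs <- label_components(mask)
  stats <- component_stats(labs)
  if (nrow(stats) < 2L) return(list(ok = FALSE, reason = "fewer_than_two_regions"))
  stats <- stats[order(stats$area, decreasing = TRUE), ][1:2, ]
  stats <- stats[order(stats$col), ]
  eyes <- as.matrix(stats[, c("row", "col")])
  sep <- sqrt(sum((eyes[1, ] - eyes[2, ])^2))
  if (sep < separation_range[1] || sep > separation_range[2]) {
    return(list(ok = FALSE, reason = "implausible_separation", eyes = eyes,
                separation = sep))
  }
  list(ok = TRUE, eyes = eyes, separation = sep)
}

#' Locate the brain centre from the two eye centroids
#'
#' The brain centre is 35 half-size pixels from the midpoint of the eye-to-eye
#' segment, along the perpendicular pointing caudally (toward increasing rows
#' in the head-up frame); the result is scaled into full-size coordinates.
#'
#' @param eye_a,eye_b (row, col) eye centroids in half-size coordinates.
#' @param offset perpendicular offset in half-size pixels.
#' @return list with `half` and `full` (row, col) brain-centre coordinates.
#' @export
locate_brain_center <- function(eye_a, eye_b, offset = 35) {
  d <- eye_b - eye_a
  len <- sqrt(sum(d^2))
  if (len == 0) stop("coincident eye centroids")
  n <- c(-d[2], d[1]) / len
  if (n[1] < 0) n <- -n
  half <- (eye_a + eye_b) / 2 + offset * n
  list(half = half, full = half * 2)
}

#' Crop the brain region and its eye mask
#'
#' Crops a 190-row x 220-column region centred on the brain from the head-up
#' fluorescence projection. The head-up bright-field is Otsu-thresholded and
#' its dark class, cropped identically, becomes the eye mask. Crop areas
#' falling outside the frame are zero-padded and flagged `edge_pad`.
#'
#' @param fluor_proj_full head-up full-size fluorescence projection.
#' @param brightfield_full head-up full-size bright-field.
#' @param brain_center_full (row, col) brain centre, full-size coordinates.
#' @param crop_size (rows, cols) of the crop.
#' @return a `brain_crop` object: list with `image`, `eye_mask`,
#'   `brain_center_full` and `qc_flags`.
#' @export
crop_brain <- function(fluor_proj_full, brightfield_full, brain_center_full,
                       crop_size = c(190L, 220L)) {
  nr <- nrow(fluor_proj_full); nc <- ncol(fluor_proj_full)
  if (any(brain_center_full < 1) || brain_center_full[1] > nr ||
      brain_center_full[2] > nc) {
    stop("brain centre outside the frame")
  }
  thr <- otsu_threshold(brightfield_full[seq(1, nr * nc, by = 4L)])
  eye_mask_full <- brightfield_full < thr

  ctr <- round(brain_center_full)
  r0 <- ctr[1] - floor((crop_size[1] - 1) / 2)
  c0 <- ctr[2] - floor((crop_size[2] - 1) / 2)
  rows <- r0:(r0 + crop_size[1] - 1L)
  cols <- c0:(c0 + crop_size[2] - 1L)
  qc <- character(0)
  img <- matrix(0, crop_size[1], crop_size[2])
  msk <- matrix(FALSE, crop_size[1], crop_size[2])
  in_r <- rows >= 1 & rows <= nr
  in_c <- cols >= 1 & cols <= nc
  if (!all(in_r) || !all(in_c)) qc <- c(qc, "edge_pad")
  img[in_r, in_c] <- fluor_proj_full[rows[in_r], cols[in_c]]
  msk[in_r, in_c] <- eye_mask_full[rows[in_r], cols[in_c]]
  structure(list(image = img, eye_mask = msk,
                 brain_center_full = brain_center_full, qc_flags = qc),
            class = "brain_crop")
}

# Full localization chain for a single pose. Returns a record with ok flag,
# reason on failure, and the brain_crop plus landmarks on success.
localize_pose <- function(brightfield, fluorescence, config = default_config()) {
  loc <- config$localization
  proj <- max_project(fluorescence)
  first_slice <- if (is.matrix(fluorescence)) fluorescence else fluorescence[, , 1L]
  head <- detect_head(first_slice, d_min = loc$hough_d_min, d_max = loc$hough_d_max)
  if (!head$ok) return(list(ok = FALSE, reason = head$reason))
  orient <- orient_head_up(proj, brightfield, head$center)
  if (!orient$ok) return(list(ok = FALSE, reason = orient$reason))
  eyes <- detect_eyes(orient$brightfield, oval = loc$eye_oval,
                      separation_range = loc$eye_separation_range)
  if (!eyes$ok) return(list(ok = FALSE, reason = eyes$reason, angle = orient$angle))
  bc <- locate_brain_center(eyes$eyes[1, ], eyes$eyes[2, ],
                            offset = loc$brain_offset)
  crop <- tryCatch(
    crop_brain(orient$fluor, orient$brightfield, bc$full,
               crop_size = loc$crop_size),
    error = function(e) NULL)
  if (is.null(crop)) return(list(ok = FALSE, reason = "center_outside_frame",
                                 angle = orient$angle))
  crop$rotation_angle <- orient$angle
  crop$eye_centroids_half <- eyes$eyes
  list(ok = TRUE, crop = crop, angle = orient$angle, eyes = eyes$eyes,
       brain_center_full = bc$full, head = head,
       frame_total_fluor = sum(proj))
}

#' Select the best pose of a well
#'
#' Runs the localization chain on every pose; among successful poses the one
#' with the highest total fluorescence inside its brain crop is chosen (ties
#' broken by the lowest cycle index). A manual choice, when given, is used
#' verbatim.
#'
#' @param poses list of pose acquisitions (elements with `brightfield`,
#'   `fluorescence`, and optionally `cycle`).
#' @param manual_choice optional 1-based cycle index overriding the automatic
#'   selection.
#' @param config pipeline configuration, see [default_config()].
#' @return list with `ok`, `chosen_cycle`, `result` (the successful
#'   localization record) and per-cycle `provenance` tibble.
#' @export
select_best_pose <- function(poses, manual_choice = NULL,
                             config = default_config()) {
  stopifnot(length(poses) >= 1)
  cycles <- vapply(seq_along(poses), function(i) {
    cy <- poses[[i]]$cycle
    if (is.null(cy)) i else as.integer(cy)
  }, integer(1))
  if (!is.null(manual_choice)) {
    i <- match(as.integer(manual_choice), cycles)
    if (is.na(i)) stop("manual_choice cycle not present in poses")
    res <- localize_pose(poses[[i]]$brightfield, poses[[i]]$fluorescence, config)
    prov <- tibble::tibble(cycle = cycles[i], ok = res$ok,
                           reason = if (res$ok) NA_character_ else res$reason,
                           score = if (res$ok) sum(res$crop$image) else NA_real_,
                           manual = TRUE)
    return(list(ok = res$ok, chosen_cycle = cycles[i], result = res,
                provenance = prov))
  }
  results <- lapply(poses, function(p)
    localize_pose(p$brightfield, p$fluorescence, config))
  scores <- vapply(results, function(r)
    if (r$ok) sum(r$crop$image) else NA_real_, numeric(1))
  prov <- tibble::tibble(
    cycle = cycles,
    ok = vapply(results, function(r) r$ok, logical(1)),
    reason = vapply(results, function(r)
      if (r$ok) NA_character_ else r$reason, character(1)),
    score = scores, manual = FALSE)
  if (all(is.na(scores))) {
    return(list(ok = FALSE, chosen_cycle = NA_integer_, result = NULL,
                provenance = prov))
  }
  best <- which(scores == max(scores, na.rm = TRUE))
  i <- best[which.min(cycles[best])]
  list(ok = TRUE, chosen_cycle = cycles[i], result = results[[i]],
       provenance = prov)
}

#' Localize the brain for one well across its poses
#'
#' Composes head detection, orientation normalization, eye detection and
#' brain cropping over all poses of a well, choosing the best pose (or a
#' manual override) and recording an audit trail. Wells where every pose
#' fails are reported as unusable rather than raising an error.
#'
#' @inheritParams select_best_pose
#' @param well well identifier carried into the output.
#' @return list with `well`, `usable`, `chosen_cycle`, `crop` (a
#'   `brain_crop`, `NULL` if unusable), `angle`, `eyes`, `brain_center_full`
#'   and `provenance`.
#' @export
localize_well <- function(poses, manual_choice = NULL, well = NA_character_,
                          config = default_config()) {
  sel <- select_best_pose(poses, manual_choice = manual_choice, config = config)
  if (!sel$ok) {
    return(list(well = well, usable = FALSE, chosen_cycle = NA_integer_,
                crop = NULL, provenance = sel$provenance))
  }
  res <- sel$result
  list(well = well, usable = TRUE, chosen_cycle = sel$chosen_cycle,
       crop = res$crop, angle = res$angle, eyes = res$eyes,
       brain_center_full = res$brain_center_full,
       frame_total_fluor = res$frame_total_fluor,
       provenance = sel$provenance)
}
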