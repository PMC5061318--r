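#' Mask the eye regions out of a brain crop
#'
#' Pixels under the bright-field-derived eye mask are set to zero, removing
#' eye autofluorescence before scoring; all other pixels are unchanged.
#'
#' @param image brain crop image (matrix).
#' @param eye_mask logical matrix of the same shape.
#' @return masked image.
#' @export
mask_eyes <- function(image, eye_mask) {
  if (!all(dim(image) == dim(eye_mask))) stop("image/eye_mask shape mismatch")
  image[eye_mask] <- 0
  image
}

#' Subtract the local background of a fluorescence image
#'
#' The image is smoothed with a Gaussian of the given full width at
#' half-maximum (sigma = FWHM / 2.3548) and the smoothed image is subtracted
#' from the original, removing broad background while preserving
#' neuron-scale structure. Negative residuals are clipped to zero.
#'
#' @param image numeric matrix.
#' @param fwhm full width at half-maximum of the smoothing Gaussian, pixels.
#' @return background-subtracted image.
#' @export
subtract_local_background <- function(image, fwhm = 12) {
  stopifnot(fwhm > 0)
  pmax(image - cpp_gauss_blur(image, fwhm / 2.3548), 0)
}

#' Segment neurons in a background-subtracted brain crop
#'
#' Intensity threshold set to `correction_factor` times the two-class Otsu
#' threshold of the background-subtracted image (see [otsu_threshold()] for
#' the tie-break that anchors the Otsu split just above the background
#' class, which the correction factor then calibrates upward). Connected
#' components whose equivalent-circle diameter (from area) falls outside
#' `diameter_range` are removed and the remainder relabelled from 1.
#'
#' @param image background-subtracted image.
#' @param diameter_range admissible object diameters in pixels.
#' @param correction_factor multiplier on the Otsu threshold.
#' @return a `neuron_segmentation`: list with `labels` (integer matrix,
#'   0 = background), `objects` (tibble: label, row, col, area,
#'   equiv_diameter) and `threshold`.
#' @export
segment_neurons <- function(image, diameter_range = c(5, 20),
                            correction_factor = 5) {
  t0 <- if (any(image > 0)) otsu_threshold(image) else NA_real_
  empty <- tibble::tibble(label = integer(), row = numeric(), col = numeric(),
                          area = numeric(), equiv_diameter = numeric())
  if (is.na(t0)) {
    return(structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                          objects = empty, threshold = NA_real_),
                     class = "neuron_segmentation"))
  }
  thr <- correction_factor * t0
  labs <- label_components(image > thr)
  st <- component_stats(labs)
  st$equiv_diameter <- 2 * sqrt(st$area / pi)
  keep <- st$equiv_diameter >= diameter_range[1] &
          st$equiv_diameter <= diameter_range[2]
  st <- st[keep, , drop = FALSE]
  relab <- matrix(0L, nrow(image), ncol(image))
  if (nrow(st) > 0) {
    map <- integer(max(labs))
    map[st$label] <- seq_len(nrow(st))
    nz <- labs > 0L
    relab[nz] <- map[labs[nz]]
    st$label <- seq_len(nrow(st))
  }
  structure(list(labels = relab, objects = st, threshold = thr),
            class = "neuron_segmentation")
}

#' Measure per-object and per-image features
#'
#' Overlays the segmentation on an intensity image (typically the original,
#' eye-masked fluorescence crop) and measures object area, integrated and
#' mean intensity, plus image-level totals.
#'
#' @param segmentation a [segment_neurons()] result.
#' @param image intensity image aligned with the segmentation.
#' @return list with `objects` (tibble: label, row, col, area,
#'   equiv_diameter, total_fluor, mean_fluor) and `image` (one-row tibble:
#'   n_objects, total_fluor, mean_fluor of the whole image).
#' @export
measure_features <- function(segmentation, image) {
  stopifnot(inherits(segmentation, "neuron_segmentation"),
            all(dim(segmentation$labels) == dim(image)))
  obj <- segmentation$objects
  if (nrow(obj) > 0) {
    lab <- segmentation$labels
    idx <- which(lab > 0L)
    tot <- as.numeric(tapply(image[idx], lab[idx], sum))
    obj$total_fluor <- tot
    obj$mean_fluor <- tot / obj$area
  } else {
    obj$total_fluor <- numeric(0)
    obj$mean_fluor <- numeric(0)
  }
  list(objects = obj,
       image = tibble::tibble(n_objects = nrow(obj),
                              total_fluor = sum(image),
                              mean_fluor = mean(image)))
}

# integer-pixel shift with zero fill
shift_int <- function(img, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(img), ncol(img))
  sr <- seq_len(nrow(img)) - dr
  sc <- seq_len(ncol(img)) - dc
  ok_r <- sr >= 1 & sr <= nrow(img)
  ok_c <- sc >= 1 & sc <= ncol(img)
  out[ok_r, ok_c] <- img[sr[ok_r], sc[ok_c]]
  out
}

# Best circular-correlation shift between two mean/sd-normalized images,
# limited to |shift| <= max_shift. Returns list(dr, dc, score).
best_shift <- function(ref_n, mov_n, max_shift = 25) {
  cc <- Re(stats::fft(stats::fft(ref_n) * Conj(stats::fft(mov_n)),
                      inverse = TRUE)) / length(ref_n)
  nr <- nrow(cc); nc <- ncol(cc)
  dr_axis <- c(0:(nr %/% 2), -((nr - 1) %/% 2):-1)
  dc_axis <- c(0:(nc %/% 2), -((nc - 1) %/% 2):-1)
  ok_r <- abs(dr_axis) <= max_shift
  ok_c <- abs(dc_axis) <= max_shift
  sub <- cc[ok_r, ok_c, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  list(dr = dr_axis[ok_r][pk[1]], dc = dc_axis[ok_c][pk[2]],
       score = max(sub) / length(ref_n))
}

normalize_img <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

# Rigid (rotation + translation) registration of `mov` onto `ref` by
# normalized cross-correlation with a multi-start search over rotation.
register_rigid <- function(mov, ref, angle_grid = seq(-15, 15, by = 3),
                           max_shift = 25) {
  ref_n <- normalize_img(ref)
  best <- NULL
  for (a in angle_grid) {
    rot <- if (a == 0) mov else rotate_image(mov, a, fill = stats::median(mov))
    sh <- best_shift(ref_n, normalize_img(rot), max_shift)
    if (is.null(best) || sh$score > best$score) {
      best <- list(angle = a, dr = sh$dr, dc = sh$dc, score = sh$score, rot = rot)
    }
  }
  img <- shift_int(best$rot, best$dr, best$dc, fill = stats::median(mov))
  list(image = img, angle = best$angle, dr = best$dr, dc = best$dc,
       score = best$score)
}

#' Build the idealized healthy-brain template
#'
#' Registers healthy brain crops to the first crop with a rigid
#' (rotation + translation) transform found by normalized cross-correlation
#' with a multi-start search over rotation, averages the registered stack,
#' subtracts the smooth background (rolling ball, implemented as a
#' morphological opening with a disc of the stated radius), applies a
#' Gaussian blur, and rescales the result to `[0, 1]`.
#'
#' @param crops list of brain crop images (matrices of identical shape), or
#'   of `brain_crop` objects.
#' @param rolling_ball_radius radius of the background structuring element.
#' @param blur_sigma sigma of the final idealizing Gaussian blur, pixels.
#' @param register if `FALSE`, skip registration (images already aligned).
#' @return a `brain_template`: list with `M` (matrix in `[0, 1]`),
#'   `n_source_images` and `provenance` (per-crop transforms).
#' @export
build_template <- function(crops, rolling_ball_radius = 150, blur_sigma = 7,
                           register = TRUE) {
  if (length(crops) == 0) stop("empty crop list")
  imgs <- lapply(crops, function(x) if (inherits(x, "brain_crop")) x$image else x)
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all crops must share the same shape")
  prov <- tibble::tibble(index = seq_along(imgs), angle = 0, dr = 0L, dc = 0L)
  acc <- imgs[[1]]
  if (length(imgs) > 1) {
    for (i in seq_along(imgs)[-1]) {
      if (register) {
        reg <- register_rigid(imgs[[i]], imgs[[1]])
        prov$angle[i] <- reg$angle; prov$dr[i] <- reg$dr; prov$dc[i] <- reg$dc
        acc <- acc + reg$image
      } else {
        acc <- acc + imgs[[i]]
      }
    }
  }
  avg <- acc / length(imgs)
  bg <- EBImage::opening(avg / 65535,
                         EBImage::makeBrush(2 * rolling_ball_radius + 1, "disc")) * 65535
  sub <- pmax(avg - matrix(as.numeric(bg), nrow(avg), ncol(avg)), 0)
  m <- cpp_gauss_blur(sub, blur_sigma)
  m <- m - min(m)
  mx <- max(m)
  if (mx == 0) stop("degenerate template: no signal after background subtraction")
  structure(list(M = m / mx, n_source_images = length(imgs),
                 provenance = prov,
                 params = list(rolling_ball_radius = rolling_ball_radius,
                               blur_sigma = blur_sigma)),
            class = "brain_template")
}

#' Brain Health Score
#'
#' `BHS = log2( sum_ij I_ij * M_ij )`: the log of the (uncentered) covariance
#' between a brain image and the idealized template. The input image is the
#' eye-masked (not background-subtracted) brain crop. When the sum is zero
#' the score is undefined and `NA` is returned with a `"zero_overlap"` qc
#' attribute rather than `-Inf`, keeping downstream robust statistics
#' meaningful.
#'
#' @param I brain image (matrix), eye-masked fluorescence crop in counts.
#' @param M a `brain_template` or a template matrix with values in `[0, 1]`.
#' @return numeric BHS (dimensionless, log2 counts x template units); `NA`
#'   with attribute `qc = "zero_overlap"` when the overlap sum is zero.
#' @export
brain_health_score <- function(I, M) {
  m <- if (inherits(M, "brain_template")) M$M else M
  if (!all(dim(I) == dim(m))) stop("image/template shape mismatch")
  s <- sum(I * m)
  if (s <= 0) return(structure(NA_real_, qc = "zero_overlap"))
  log2(s)
}

# Score one localized well: eye masking, BHS against the template, neuron
# segmentation and feature measurement. Returns a one-row tibble.
score_crop <- function(crop, template, config = default_config(),
                       well = NA_character_, condition = NA_character_,
                       chosen_cycle = NA_integer_,
                       frame_total_fluor = NA_real_) {
  sc <- config$scoring
  masked <- mask_eyes(crop$image, crop$eye_mask)
  sub <- subtract_local_background(masked, fwhm = sc$smooth_fwhm)
  seg <- segment_neurons(sub, diameter_range = sc$diameter_range,
                         correction_factor = sc$correction_factor)
  feats <- measure_features(seg, masked)
  bhs_input <- if (identical(sc$bhs_input, "subtracted")) sub else masked
  bhs <- brain_health_score(bhs_input, template)
  flags <- crop$qc_flags
  if (is.na(bhs)) flags <- c(flags, attr(bhs, "qc"))
  tibble::tibble(
    well = well, condition = condition, chosen_cycle = chosen_cycle,
    bhs = as.numeric(bhs),
    n_objects = feats$image$n_objects,
    total_fluor = feats$image$total_fluor,
    mean_fluor = feats$image$mean_fluor,
    frame_total_fluor = frame_total_fluor,
    flags = paste(flags, collapse = ";"))
}
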