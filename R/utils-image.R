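#' Image utilities shared across the pipeline
#'
#' All images in this package are plain numeric matrices in camera counts
#' (16-bit range, 0--65535), indexed `[row, col]` with the origin at the
#' top-left. Fluorescence stacks are `row x col x z` arrays. Angles are in
#' degrees; a rotation by angle `theta` moves a point offset `(dr, dc)` from
#' the frame centre to `(dr*cos - dc*sin, dr*sin + dc*cos)`.
#'
#' @name image-conventions
NULL

#' Gaussian blur of an image
#'
#' Separable Gaussian filter with replicate borders; constant images are
#' preserved exactly. Used for the synthetic defocus model and for the
#' local-background smoothing step.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation of the Gaussian kernel in pixels.
#' @return blurred matrix of the same dimensions.
#' @export
gauss_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(sigma), sigma >= 0)
  cpp_gauss_blur(x, sigma)
}

#' Two-class Otsu threshold
#'
#' Threshold maximizing the between-class variance on a 256-bin histogram of
#' the data range. When the histogram has an empty gap between its classes
#' the variance is constant across the gap; the smallest maximizing bin
#' centre is returned (the scikit-image convention), i.e. the threshold sits
#' just above the background class. Pinning this tie-break matters when a
#' threshold correction factor is applied on top (see [segment_neurons()]).
#'
#' @param x numeric matrix or vector.
#' @param levels number of histogram bins.
#' @return threshold on the intensity scale of `x`; pixels strictly above it
#'   are foreground.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no finite values for Otsu threshold")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  width <- (rng[2] - rng[1]) / levels
  bins <- pmin(floor((v - rng[1]) / width) + 1L, levels)
  counts <- tabulate(bins, nbins = levels)
  p <- counts / length(v)
  mids <- rng[1] + (seq_len(levels) - 0.5) * width
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mu <- m1[levels]
  sb <- (mu * w1 - m1)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb) | w1 <= 0 | w1 >= 1] <- -Inf
  mids[which.max(sb)]
}

#' Rotate an image about its centre
#'
#' Bilinear interpolation, output size preserved, out-of-frame areas filled
#' with a constant (by default the image median, so rotation does not
#' introduce spurious dark corners that could be mistaken for eyes).
#'
#' @param x numeric matrix.
#' @param angle rotation angle in degrees (see [image-conventions]).
#' @param fill fill value for pixels rotated in from outside the frame.
#' @return rotated matrix, same dimensions as `x`.
#' @export
rotate_image <- function(x, angle, fill = stats::median(x)) {
  stopifnot(is.matrix(x))
  r <- EBImage::rotate(x, angle, output.dim = dim(x), bg.col = fill)
  matrix(as.numeric(r), nrow(x), ncol(x))
}

#' Map point coordinates through a centre rotation and optional rescale
#'
#' Applies the same coordinate transform that [rotate_image()] applies to
#' pixel content: rotation by `angle` about the frame centre, then
#' multiplication by `scale` (e.g. 0.5 for half-size coordinates).
#'
#' @param points numeric matrix with columns (row, col), or a length-2 vector.
#' @param angle rotation angle in degrees.
#' @param dim dimensions (rows, cols) of the frame the points live in.
#' @param scale scalar applied after rotation (default 1).
#' @return matrix with columns (row, col).
#' @export
transform_points <- function(points, angle, dim, scale = 1) {
  if (is.null(nrow(points))) points <- matrix(points, nrow = 1)
  ctr <- (dim + 1) / 2
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  off <- sweep(points, 2, ctr)
  out <- sweep(off %*% t(R), 2, ctr, "+")
  colnames(out) <- c("row", "col")
  out * scale
}

#' Downscale an image to half size
#'
#' Bilinear resize to `floor(dim/2)`, the "resized to half its original size"
#' step used before gross anatomical feature detection.
#'
#' @param x numeric matrix.
#' @return matrix with half the rows and columns.
#' @export
resize_half <- function(x) {
  nr <- floor(nrow(x) / 2)
  nc <- floor(ncol(x) / 2)
  r <- EBImage::resize(x, w = nr, h = nc)
  matrix(as.numeric(r), nr, nc)
}

# Connected-component labelling (8-connectivity) of a logical matrix.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# Centroids and sizes of labelled components, ordered by label.
component_stats <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), row = numeric(),
                          col = numeric(), area = numeric()))
  }
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  tibble::tibble(
    label = sort(unique(lab)),
    row = as.numeric(tapply(rr, lab, mean)),
    col = as.numeric(tapply(cc, lab, mean)),
    area = as.numeric(tapply(lab, lab, length))
  )
}

# Stamp value `value` into `img` over an ellipse; a (axis semi-length along
# the direction `theta_deg`), b (perpendicular semi-length). Returns img.
stamp_ellipse <- function(img, center, a, b, theta_deg, value) {
  th <- theta_deg * pi / 180
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(nrow(img), ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(ncol(img), ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  patch <- img[rr, cc, drop = FALSE]
  patch[inside] <- value
  img[rr, cc] <- patch
  img
}

# Add a radially Gaussian blob of peak `amplitude` and width `sigma`.
stamp_gaussian_blob <- function(img, center, sigma, amplitude) {
  ext <- ceiling(3 * sigma)
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(nrow(img), ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(ncol(img), ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, rep(1, length(cc))) +
        outer(rep(1, length(rr)), (cc - center[2])^2)
  img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

# Capsule (thick segment) mask: pixels within `radius` of the segment A-B.
# Computed on a `step`-downsampled grid and block-upsampled; the body edge is
# soft anyway and the few-pixel roughness is immaterial.
capsule_mask <- function(dim, a, b, radius, step = 4L) {
  rr <- seq(1, dim[1], by = step); cc <- seq(1, dim[2], by = step)
  dr <- outer(rr - a[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - a[2])
  ab <- b - a
  len2 <- sum(ab^2)
  t <- (dr * ab[1] + dc * ab[2]) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  coarse <- (dr - t * ab[1])^2 + (dc - t * ab[2])^2 <= radius^2
  fine <- coarse[rep(seq_along(rr), each = step),
                 rep(seq_along(cc), each = step), drop = FALSE]
  fine[seq_len(dim[1]), seq_len(dim[2]), drop = FALSE]
}
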