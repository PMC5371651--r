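#' One-dimensional Gaussian convolution kernel
#'
#' Truncated at 4 standard deviations (radius `ceiling(4 * sigma)`) and
#' normalized to unit sum.
#'
#' @param sigma standard deviation in pixels.
#' @return numeric vector of odd length.
#' @keywords internal
gaussian_kernel1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Two-dimensional circular-symmetric Gaussian kernel (unit sum)
#' @inheritParams gaussian_kernel1d
#' @keywords internal
gaussian_kernel2d <- function(sigma) {
  k <- gaussian_kernel1d(sigma)
  outer(k, k)
}

# Symmetric (mirror, edge included) index folding for padding.
mirror_idx <- function(n, pad) {
  i <- (1L - pad):(n + pad)
  j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

# Band matrix applying a 1D kernel to a padded axis: out length n from
# padded length n + 2*pad, kernel length 2*pad + 1.
band_matrix <- function(n, k) {
  pad <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n + 2L * pad)
  for (u in seq_along(k)) B[cbind(seq_len(n), seq_len(n) + u - 1L)] <- k[u]
  B
}

#' Local mean of an image (Gaussian blur with mirror padding)
#'
#' The image is padded on all sides by `ceiling(4 * sigma)` pixels with
#' mirror reflections of the pixel values near its edges, convolved with a
#' circular-symmetric Gaussian of standard deviation `sigma`, and cropped
#' back to the original size.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return matrix of the same size as `image`.
#' @export
local_mean <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  k <- gaussian_kernel1d(sigma)
  pad <- (length(k) - 1L) %/% 2L
  P <- image[mirror_idx(nrow(image), pad), mirror_idx(ncol(image), pad)]
  Bh <- band_matrix(nrow(image), k)
  Bw <- band_matrix(ncol(image), k)
  Bh %*% P %*% t(Bw)
}

#' Convert a grayscale image to non-negative ON/OFF contrast channels
#'
#' The local mean `Ibar` (see [local_mean()]) is subtracted from the image
#' to give the relative intensity `X = I - Ibar`.  The positive part of `X`
#' forms the ON channel and the rectified negative part the OFF channel, so
#' the input to the network is non-negative.  Both channels are then
#' rescaled jointly by one divisor so the values fill the range `[0, 1]`
#' (a constant image yields all-zero channels).
#'
#' @param image numeric matrix of finite pixel values.
#' @param sigma standard deviation (pixels) of the Gaussian used for the
#'   local mean; must be positive.
#' @return an object of class `contrast_input`: list with non-negative
#'   matrices `on` and `off` (same size as `image`) and `sigma`.
#' @export
local_contrast <- function(image, sigma) {
  if (!is.matrix(image) || !is.numeric(image)) stop("image must be a numeric matrix")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  X <- image - local_mean(image, sigma)
  on <- pmax(X, 0)
  off <- pmax(-X, 0)
  mx <- max(on, off)
  # a (numerically) constant image has no contrast: both channels all-zero
  # rather than rescaled floating-point noise
  if (mx > 1e-10 * max(1, max(abs(image)))) {
    on <- on / mx
    off <- off / mx
  } else {
    on[] <- 0
    off[] <- 0
  }
  structure(list(on = on, off = off, sigma = sigma), class = "contrast_input")
}

#' Flatten a contrast input into the matrix-form input vector
#'
#' Concatenates the ON channel followed by the OFF channel, both in
#' column-major order.
#'
#' @param ci a `contrast_input`.
#' @return numeric vector of length `2 * prod(dim(image))`.
#' @export
contrast_vector <- function(ci) {
  stopifnot(inherits(ci, "contrast_input"))
  c(as.numeric(ci$on), as.numeric(ci$off))
}

#' Stack a contrast input into the convolutional-form channel array
#' @param ci a `contrast_input`.
#' @return `h x w x 2` array (ON channel first).
#' @export
contrast_stack <- function(ci) {
  stopifnot(inherits(ci, "contrast_input"))
  array(c(ci$on, ci$off), dim = c(dim(ci$on), 2L))
}

#' Zero-mean normalized cross correlation between two patches
#'
#' `sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))`, a similarity in `[-1, 1]` invariant to affine
#' intensity changes with positive gain.  A zero-variance patch makes the
#' similarity undefined; 0 is returned with a warning.
#'
#' @param patch_a,patch_b numeric matrices (or vectors) of the same shape.
#' @return scalar in `[-1, 1]`.
#' @export
zmncc <- function(patch_a, patch_b) {
  if (length(patch_a) != length(patch_b)) {
    stop("patches have different sizes")
  }
  a <- as.numeric(patch_a) - mean(patch_a)
  b <- as.numeric(patch_b) - mean(patch_b)
  da <- sum(a^2); db <- sum(b^2)
  if (da == 0 || db == 0) {
    warning("zero-variance patch: ZMNCC undefined, returning 0")
    return(0)
  }
  sum(a * b) / sqrt(da * db)
}

#' Smooth a map with a unit-integral Gaussian (zero padding)
#' @param map numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the map
#'   unchanged.
#' @return matrix of the same size.
#' @export
gaussian_smooth <- function(map, sigma) {
  if (sigma <= 0) return(map)
  xcorr_same(map, gaussian_kernel2d(sigma))
}

# Bilinear sampling of img at (possibly fractional) coordinates R, C
# (1-based); samples outside the image are `fill`.
bilinear_sample <- function(img, R, C, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(R); c0 <- floor(C)
  fr <- R - r0; fc <- C - c0
  gv <- function(rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    out <- array(fill, dim = dim(rr))
    out[ok] <- img[cbind(rr[ok], cc[ok])]
    out
  }
  v <- gv(r0, c0) * (1 - fr) * (1 - fc) +
    gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc +
    gv(r0 + 1, c0 + 1) * fr * fc
  matrix(v, nrow(R), ncol(R))
}

#' Resize an image by bilinear interpolation
#' @param image numeric matrix.
#' @param factor scale factor (> 0); the output is
#'   `round(dim(image) * factor)` pixels.
#' @return resized matrix.
#' @export
resize_bilinear <- function(image, factor) {
  stopifnot(factor > 0)
  h2 <- max(1L, round(nrow(image) * factor))
  w2 <- max(1L, round(ncol(image) * factor))
  sr <- nrow(image) / h2
  sc <- ncol(image) / w2
  rr <- (seq_len(h2) - 0.5) * sr + 0.5
  cc <- (seq_len(w2) - 0.5) * sc + 0.5
  rr <- pmin(pmax(rr, 1), nrow(image))
  cc <- pmin(pmax(cc, 1), ncol(image))
  R <- matrix(rr, h2, w2)
  C <- matrix(cc, h2, w2, byrow = TRUE)
  bilinear_sample(image, R, C)
}

#' Affine warp of an image about its centre
#'
#' Rotates by `angle_deg` (counter-clockwise), scales by `scale`, and
#' translates by `(dr, dc)` pixels, sampling bilinearly with `fill`
#' outside the source image.
#'
#' @param image numeric matrix.
#' @param angle_deg rotation in degrees.
#' @param scale isotropic scale factor.
#' @param dr,dc translation in pixels (rows, cols).
#' @param fill value used outside the source image; default 0.
#' @return matrix of the same size as `image`.
#' @export
warp_affine <- function(image, angle_deg = 0, scale = 1, dr = 0, dc = 0,
                        fill = 0) {
  stopifnot(scale > 0)
  h <- nrow(image); w <- ncol(image)
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  th <- angle_deg * pi / 180
  R <- matrix(seq_len(h), h, w) - ctr[1L] - dr
  C <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2L] - dc
  # inverse transform: un-rotate then un-scale
  Rs <- (cos(th) * R + sin(th) * C) / scale + ctr[1L]
  Cs <- (-sin(th) * R + cos(th) * C) / scale + ctr[2L]
  bilinear_sample(image, Rs, Cs, fill = fill)
}
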