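# Background-suppression preprocessing chain:
# ExG -> local variance -> non-linear normalization -> exponential
# enhancement -> Otsu -> morphology -> mask application.
#
# Image convention throughout the package: numeric arrays H x W x 3 (RGB) or
# H x W matrices (gray), values in [0, 1], row = image row. EBImage stores
# images x-major, so I/O helpers transpose at the boundary.

#' Read an RGB image
#'
#' Reads PNG or JPEG into an H x W x 3 array in \[0,1\]. Grayscale files are
#' replicated across channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return An H x W x 3 numeric array.
#' @export
read_rgb <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- as.array(img)
  if (length(d) == 2L) a <- array(rep(a, 3L), c(d, 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2L, 1L, 3L))
}

#' Write an RGB image
#' @param img H x W x 3 array in \[0,1\].
#' @param path output path; format chosen from the extension (.png/.jpg).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  assert_rgb(img)
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical H x W matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path PNG file path.
#' @return A logical H x W matrix (pixel > 0.5).
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) > 2L) a <- a[, , 1L]
  t(a) > 0.5
}

#' Excess-green (2G-R-B) vegetation index
#'
#' Converts RGB to chromatic coordinates r = R/(R+G+B), g = G/(R+G+B),
#' b = B/(R+G+B) (which cancel global brightness), then computes
#' ExG = 2g - r - b where 2g >= r + b and 0 elsewhere. The raw index lies in
#' \[0,2\]; it is divided by 2 so the returned gray image lies in \[0,1\].
#' Pixels with R+G+B = 0 map to 0.
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @return An H x W gray matrix in \[0,1\], high on green vegetation.
#' @export
compute_exg <- function(img) {
  assert_rgb(img)
  s <- img[, , 1L] + img[, , 2L] + img[, , 3L]
  g <- ifelse(s > 0, img[, , 2L] / s, 1 / 3)
  # 2g - r - b = 3g - 1 since r + g + b = 1
  pmax(3 * g - 1, 0) / 2
}

#' Chromatic green coordinate
#'
#' g = G/(R+G+B); offered as an alternative gray channel for the
#' enhancement stage (see `gray_source` in [segment_plant()]).
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @return An H x W gray matrix in \[0,1\].
#' @export
chromatic_g <- function(img) {
  assert_rgb(img)
  s <- img[, , 1L] + img[, , 2L] + img[, , 3L]
  ifelse(s > 0, img[, , 2L] / s, 0)
}

#' Local variance over a 3x3 neighborhood
#'
#' At each pixel, the variance of the nine gray values in the centered 3x3
#' window (population variance, divisor 9), using replicate padding at the
#' borders. Low on smooth leaf interiors, high on fine-grained texture such
#' as dense turf.
#'
#' @param gray H x W gray matrix, H and W >= 3.
#' @return An H x W matrix of non-negative variances.
#' @export
local_variance <- function(gray) {
  assert_gray(gray)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3L || w < 3L) stop_config("image must be at least 3 x 3 (got %d x %d)", h, w)
  xp <- gray[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  s1 <- matrix(0, h, w)
  s2 <- matrix(0, h, w)
  for (di in 0:2) {
    for (dj in 0:2) {
      blk <- xp[di + seq_len(h), dj + seq_len(w)]
      s1 <- s1 + blk
      s2 <- s2 + blk * blk
    }
  }
  mu <- s1 / 9
  pmax(s2 / 9 - mu * mu, 0)
}

#' Non-linear normalization of a local-variance map
#'
#' The raw variance map is first scaled linearly to \[0,1\] by its maximum
#' (an all-zero map stays zero), then passed through the concave rational
#' map V = a*v / (b*v + (a - b)), which fixes 0 and 1, is strictly
#' increasing, and lifts small variances above the linear diagonal so that
#' sparse- and dense-texture backgrounds both become separable from smooth
#' foreground.
#'
#' @param v H x W matrix of raw local variances (>= 0).
#' @param p an [enhance_params()] object supplying `a` and `b`.
#' @return An H x W matrix of normalized variances in \[0,1\].
#' @export
normalize_variance <- function(v, p = enhance_params()) {
  assert_gray(v, "v")
  if (min(v) < 0) stop_config("raw variances must be non-negative")
  if (!inherits(p, "enhance_params")) p <- do.call(enhance_params, p)
  vmax <- max(v)
  if (vmax == 0) return(matrix(0, nrow(v), ncol(v)))
  u <- v / vmax
  p$a * u / (p$b * u + (p$a - p$b))
}

#' Exponential gray-level enhancement
#'
#' Multiplies the gray image by the gain 1 / (exp(k*V^2) - m) and clips to
#' \[0,1\]. With the defaults k = 50, m = 0.99 the gain exceeds 1 wherever
#' the normalized variance is below the crossover
#' V* = sqrt(log(1+m)/k) (about 0.117): smooth foreground is brightened by
#' up to 1/(1-m) = 100x while high-variance background is driven to zero.
#'
#' @param gray H x W gray matrix in \[0,1\] (the image f being enhanced).
#' @param V H x W normalized variance map, same shape as `gray`.
#' @param p an [enhance_params()] object supplying `k` and `m`.
#' @return An H x W enhanced gray matrix in \[0,1\].
#' @export
enhance <- function(gray, V, p = enhance_params()) {
  assert_gray(gray); assert_gray(V, "V")
  if (!all(dim(gray) == dim(V))) stop_config("`gray` and `V` shapes differ")
  if (!inherits(p, "enhance_params")) p <- do.call(enhance_params, p)
  gain <- 1 / (exp(p$k * V * V) - p$m)
  clamp01(gray * gain)
}

#' Enhancement gain crossover
#'
#' The normalized-variance value at which the enhancement gain
#' 1/(exp(k*V^2) - m) equals 1: the boundary between gray-level enhancement
#' (below) and suppression (above).
#'
#' @param k enhancement sharpness (> 0).
#' @param m gain offset in (0,1).
#' @return V* = sqrt(log(1+m)/k).
#' @export
enhancement_crossover <- function(k = 50, m = 0.99) {
  if (k <= 0) stop_config("`k` must be positive")
  if (m <= 0 || m >= 1) stop_config("`m` must lie in (0, 1)")
  sqrt(log(1 + m) / k)
}

#' Binarize an enhanced gray image
#'
#' Global Otsu threshold by default; foreground is every pixel strictly
#' above the threshold. A fixed threshold may be supplied instead. A
#' constant image yields an all-background mask with a warning.
#'
#' @param gray H x W gray matrix in \[0,1\].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold in \[0,1\] when `method = "fixed"`.
#' @return A logical H x W mask (TRUE = foreground).
#' @export
binarize <- function(gray, method = c("otsu", "fixed"), threshold = NULL) {
  assert_gray(gray)
  method <- match.arg(method)
  rng <- range(gray)
  if (rng[1] == rng[2]) {
    warning("constant image: returning an all-background mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  th <- if (method == "fixed") {
    if (is.null(threshold)) stop_config("`threshold` required for method = \"fixed\"")
    threshold
  } else {
    as.numeric(EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1)))
  }
  gray > th
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening (removes isolated noise specks) followed by binary
#' closing (fills small holes) with the configured structuring element.
#'
#' @param mask logical H x W mask.
#' @param mp a [morphology_params()] object.
#' @return The cleaned logical mask.
#' @export
morph_cleanup <- function(mask, mp = morphology_params()) {
  assert_mask(mask)
  shape <- if (mp$selem_shape == "disk") "disc" else "box"
  kern <- EBImage::makeBrush(2L * mp$selem_radius + 1L, shape = shape)
  x <- EBImage::Image(t(mask * 1))
  x <- EBImage::opening(x, kern)
  x <- EBImage::closing(x, kern)
  t(as.array(x)) > 0.5
}

#' Apply a binary mask to an RGB image
#'
#' Foreground pixels keep their RGB values; background pixels become black.
#'
#' @param img H x W x 3 RGB array.
#' @param mask logical H x W mask of the same spatial size.
#' @return The masked H x W x 3 array.
#' @export
apply_mask <- function(img, mask) {
  assert_rgb(img); assert_mask(mask)
  if (!all(dim(img)[1:2] == dim(mask))) stop_config("image and mask shapes differ")
  img * array(rep(mask, 3L), dim(img))
}

#' Full plant segmentation pipeline
#'
#' Composition of the preprocessing chain: vegetation index, 3x3 local
#' variance, non-linear normalization, exponential enhancement (applied to
#' the index image as the gray channel f), Otsu binarization, morphological
#' cleanup, and masking of the original RGB image.
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @param p [enhance_params()].
#' @param mp [morphology_params()].
#' @param gray_source gray channel fed to the enhancement: the rescaled
#'   excess-green index (`"exg"`, default) or the chromatic green
#'   coordinate (`"chromatic_g"`).
#' @param binarize_method passed to [binarize()].
#' @param threshold fixed threshold when `binarize_method = "fixed"`.
#' @return A list with elements `image` (masked RGB), `mask` (logical),
#'   `gray` (the index image), `variance` (normalized variance map) and
#'   `enhanced` (enhanced gray image).
#' @export
segment_plant <- function(img, p = enhance_params(), mp = morphology_params(),
                          gray_source = c("exg", "chromatic_g"),
                          binarize_method = "otsu", threshold = NULL) {
  assert_rgb(img)
  gray_source <- match.arg(gray_source)
  f <- if (gray_source == "exg") compute_exg(img) else chromatic_g(img)
  v <- local_variance(f)
  V <- normalize_variance(v, p)
  g <- enhance(f, V, p)
  mask <- suppressWarnings(binarize(g, method = binarize_method,
                                    threshold = threshold))
  mask <- morph_cleanup(mask, mp)
  list(image = apply_mask(img, mask), mask = mask,
       gray = f, variance = V, enhanced = g)
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal size.
#' @return IoU in \[0,1\]; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  if (!all(dim(a) == dim(b))) stop_config("mask shapes differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
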