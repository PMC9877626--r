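# Synthetic plant-like imagery with exact ground truth.
#
# The generator reproduces the texture contrast the preprocessing chain
# exploits: broad smooth leaves (low local variance of the vegetation
# index) over either brown soil or fine-grained green turf whose per-pixel
# chromatic noise drives the normalized local variance into the
# suppression regime (> the ~0.12 gain crossover), while leaf interiors
# stay below it.

#' Fixture generation parameters
#'
#' @param image_size square image side in pixels.
#' @param n_leaves number of elliptical leaves (>= 0).
#' @param leaf_scale typical semi-major axis of a leaf, pixels.
#' @param background `"soil"` (brown, near-zero vegetation index),
#'   `"turf"` (green with fine-grained chromatic noise) or `"mixed"`
#'   (left half turf, right half soil).
#' @param turf_frequency texture granularity in (0, 1\]: 1 gives per-pixel
#'   noise; smaller values give coarser blobs.
#' @param noise_sigma global additive Gaussian sigma applied to the final
#'   image (gray-level units).
#' @param seed integer seed; output is deterministic per seed.
#' @param class_label label stored with the fixture.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(image_size = 128L, n_leaves = 3L, leaf_scale = 18,
                         background = c("turf", "soil", "mixed"),
                         turf_frequency = 1, noise_sigma = 0.005,
                         seed = 1L, class_label = "weed") {
  background <- match.arg(background)
  image_size <- as.integer(image_size)
  if (image_size < 8L) stop_config("`image_size` must be >= 8")
  if (n_leaves < 0L) stop_config("`n_leaves` must be >= 0")
  if (turf_frequency <= 0 || turf_frequency > 1) {
    stop_config("`turf_frequency` must lie in (0, 1]")
  }
  if (noise_sigma < 0) stop_config("`noise_sigma` must be >= 0")
  structure(list(image_size = image_size, n_leaves = as.integer(n_leaves),
                 leaf_scale = leaf_scale, background = background,
                 turf_frequency = turf_frequency, noise_sigma = noise_sigma,
                 seed = as.integer(seed), class_label = class_label),
            class = "fixture_spec")
}

turf_channel_noise <- function(n, freq, amp) {
  # value noise: draw at a coarser grid, upscale by nearest neighbour
  g <- max(2L, as.integer(round(n * freq)))
  field <- matrix(runif(g * g, -amp, amp), g, g)
  idx <- pmin(g, floor((seq_len(n) - 1) * g / n) + 1L)
  field[idx, idx]
}

paint_background <- function(n, background, freq) {
  img <- array(0, c(n, n, 3L))
  fill_turf <- function(cols) {
    img[, cols, 1L] <<- clamp01(0.22 + turf_channel_noise(n, freq, 0.10)[, seq_along(cols)])
    img[, cols, 2L] <<- clamp01(0.42 + turf_channel_noise(n, freq, 0.30)[, seq_along(cols)])
    img[, cols, 3L] <<- clamp01(0.16 + turf_channel_noise(n, freq, 0.08)[, seq_along(cols)])
  }
  fill_soil <- function(cols) {
    img[, cols, 1L] <<- clamp01(0.42 + matrix(rnorm(n * length(cols), 0, 0.02), n))
    img[, cols, 2L] <<- clamp01(0.31 + matrix(rnorm(n * length(cols), 0, 0.02), n))
    img[, cols, 3L] <<- clamp01(0.18 + matrix(rnorm(n * length(cols), 0, 0.02), n))
  }
  if (background == "turf") {
    fill_turf(seq_len(n))
  } else if (background == "soil") {
    fill_soil(seq_len(n))
  } else {
    half <- n %/% 2L
    fill_turf(seq_len(half))
    fill_soil((half + 1L):n)
  }
  img
}

#' Generate one synthetic plant fixture
#'
#' Smooth, gently shaded green ellipses ("leaves") are painted over the
#' configured background; the exact painted region is returned as the
#' ground-truth mask. Leaves overflowing the frame are clipped to bounds.
#' The leaf shading scales all three channels equally, so the chromatic
#' coordinates — and hence the vegetation index — stay uniform inside a
#' leaf, mimicking broad-leaf seedlings.
#'
#' @param spec a [fixture_spec()].
#' @return A list with `image` (H x W x 3 array), `mask` (logical matrix,
#'   TRUE on leaves), `label` (character) and `spec`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$image_size
  with_seed(spec$seed, {
    img <- paint_background(n, spec$background, spec$turf_frequency)
    mask <- matrix(FALSE, n, n)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    if (spec$n_leaves > 0L) {
      for (i in seq_len(spec$n_leaves)) {
        cy <- runif(1, 0.2 * n, 0.8 * n)
        cx <- runif(1, 0.2 * n, 0.8 * n)
        a_len <- spec$leaf_scale * runif(1, 0.75, 1.3)
        b_len <- a_len * runif(1, 0.4, 0.7)
        th <- runif(1, 0, pi)
        hue <- runif(1, -0.05, 0.05)
        dy <- rows - cy
        dx <- cols - cx
        u <- (dx * cos(th) + dy * sin(th)) / a_len
        v <- (-dx * sin(th) + dy * cos(th)) / b_len
        d2 <- u * u + v * v
        inside <- d2 <= 1
        shade <- 1 - 0.25 * d2        # gentle radial shading, equal per channel
        base <- c(0.16, 0.55 + hue, 0.12)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[inside] <- clamp01(base[ch] * shade[inside])
          img[, , ch] <- plane
        }
        mask <- mask | inside
      }
    }
    if (spec$noise_sigma > 0) {
      img <- clamp01(img + array(rnorm(length(img), 0, spec$noise_sigma),
                                 dim(img)))
    }
    list(image = img, mask = mask, label = spec$class_label, spec = spec)
  })
}

#' Generate a labelled classification set
#'
#' Classes differ systematically in leaf count and leaf size so that a
#' small classifier can separate them. Returns in-memory images together
#' with a manifest compatible with the dataset module; when `dir` is
#' given, images are also written as PNGs (with a companion `masks/`
#' directory) and the manifest paths point at the files.
#'
#' @param n_classes number of classes (>= 2).
#' @param per_class images per class (scalar or length-`n_classes` vector).
#' @param seed integer seed.
#' @param image_size square image side in pixels.
#' @param background fixture background type.
#' @param materialize generate pixel data (`TRUE`) or manifest rows only.
#' @param dir optional output directory for PNGs.
#' @return A list with `manifest` (a `weed_manifest`), `images` (list of
#'   arrays, or NULL when `materialize = FALSE`), `labels` (integer class
#'   indices) and `classes` (class names).
#' @export
make_classification_set <- function(n_classes = 2L, per_class = 20L,
                                    seed = 1L, image_size = 48L,
                                    background = "turf",
                                    materialize = TRUE, dir = NULL) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop_config("`n_classes` must be >= 2")
  per_class <- as.integer(per_class)
  if (any(per_class < 1L)) stop_config("`per_class` must be >= 1")
  if (length(per_class) == 1L) per_class <- rep(per_class, n_classes)
  if (length(per_class) != n_classes) {
    stop_config("`per_class` must have length 1 or `n_classes`")
  }
  classes <- sprintf("class_%02d", seq_len(n_classes))
  # class signatures: leaf count cycles 1,4,2,6,3,5,...; size shrinks as count grows
  count_cycle <- c(1L, 4L, 2L, 6L, 3L, 5L)
  leaf_counts <- count_cycle[((seq_len(n_classes) - 1L) %% length(count_cycle)) + 1L]
  cls_vec <- rep(classes, per_class)
  labels <- rep(seq_len(n_classes), per_class)
  paths <- sprintf("%s_img%04d.png", cls_vec,
                   unlist(lapply(per_class, seq_len)))
  man <- manifest(cls_vec, paths)
  images <- NULL
  if (materialize) {
    images <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      k <- labels[i]
      sp <- fixture_spec(image_size = image_size,
                         n_leaves = leaf_counts[k],
                         leaf_scale = image_size * 0.30 / sqrt(leaf_counts[k]),
                         background = background,
                         seed = seed * 100000L + i,
                         class_label = classes[k])
      images[[i]] <- make_fixture(sp)$image
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(images)) {
        write_rgb(images[[i]], file.path(dir, paths[i]))
      }
    }
  }
  list(manifest = man, images = images, labels = labels, classes = classes)
}

#' Stack a list of equally sized RGB images into a 4-D batch tensor
#' @param images list of H x W x 3 arrays.
#' @return An H x W x 3 x N array.
#' @export
stack_images <- function(images) {
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1L]])
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}
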