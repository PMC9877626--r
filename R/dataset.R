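# Dataset manifests, two-method augmentation (doubling), resize/center-crop
# and train/test splitting.

#' Per-class image counts of the 12-class seedling benchmark
#'
#' The published per-class image counts of the Aarhus University crop/weed
#' seedling collection (12 species, 5,539 images), used as reference class
#' sizes when emulating that dataset's structure, together with the counts
#' after one round of doubling augmentation.
#'
#' @return A data.frame with columns `class`, `raw`, `extended`.
#' @export
seedling_class_counts <- function() {
  d <- data.frame(
    class = c("black_grass", "charlock", "cleavers", "common_chickweed",
              "common_wheat", "fat_hen", "loose_silky_bent", "maize",
              "scentless_mayweed", "shepherd_purse",
              "small_flowered_cranesbill", "sugar_beet"),
    raw = c(309L, 452L, 335L, 713L, 253L, 538L, 762L, 257L, 607L, 274L,
            576L, 463L),
    stringsAsFactors = FALSE
  )
  d$extended <- 2L * d$raw
  d
}

#' Build a dataset manifest
#'
#' A manifest records one row per image: its class, a path (or symbolic
#' identifier), whether it is a raw capture or an augmented copy, and its
#' split assignment.
#'
#' @param class character vector of class labels, one per image.
#' @param path character vector of image paths or identifiers.
#' @return An object of class `weed_manifest` (a data.frame with columns
#'   `class`, `path`, `origin`, `split`, `aug_kind`).
#' @export
manifest <- function(class, path) {
  if (length(class) == 0L) stop_config("manifest must contain at least one entry")
  if (length(class) != length(path)) stop_config("`class` and `path` lengths differ")
  out <- data.frame(class = as.character(class), path = as.character(path),
                    origin = "raw", split = "unassigned", aug_kind = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("weed_manifest", "data.frame")
  out
}

#' Build a symbolic manifest from per-class counts
#'
#' Creates a manifest with `raw[i]` placeholder entries per class; useful
#' for exercising the augmentation/split arithmetic without image files.
#'
#' @param counts data.frame with columns `class` and `raw`, e.g.
#'   [seedling_class_counts()].
#' @return A `weed_manifest`.
#' @export
manifest_from_counts <- function(counts = seedling_class_counts()) {
  cls <- rep(counts$class, counts$raw)
  idx <- unlist(lapply(counts$raw, seq_len))
  manifest(cls, sprintf("%s_%04d", cls, idx))
}

#' Per-class raw/extended summary of a manifest
#' @param man a `weed_manifest`.
#' @return A data.frame with columns `class`, `raw`, `extended`.
#' @export
manifest_summary <- function(man) {
  stopifnot(inherits(man, "weed_manifest"))
  cls <- sort(unique(man$class))
  data.frame(
    class = cls,
    raw = vapply(cls, function(k) sum(man$class == k & man$origin == "raw"), 0L),
    extended = vapply(cls, function(k) sum(man$class == k), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Augment a single image
#'
#' Two augmentation methods: additive Gaussian noise (clipped to \[0,1\])
#' and directional mirror flipping. Deterministic given `seed`.
#'
#' @param img H x W x 3 RGB array in \[0,1\].
#' @param kind `"add_noise"` or `"random_flip"`.
#' @param noise_sigma Gaussian standard deviation in gray-level units
#'   (default 0.02).
#' @param flip_axis `"horizontal"`, `"vertical"`, `"both"`, or NULL to draw
#'   the axis at random (seeded).
#' @param seed integer seed.
#' @return The augmented H x W x 3 array.
#' @export
augment_image <- function(img, kind = c("add_noise", "random_flip"),
                          noise_sigma = 0.02, flip_axis = NULL, seed = 1L) {
  assert_rgb(img)
  kind <- match.arg(kind)
  if (kind == "add_noise") {
    if (noise_sigma < 0) stop_config("`noise_sigma` must be >= 0")
    if (noise_sigma == 0) return(img)
    return(with_seed(seed, clamp01(img + array(rnorm(length(img), 0, noise_sigma),
                                               dim(img)))))
  }
  axis <- flip_axis %||% with_seed(seed, sample(c("horizontal", "vertical", "both"), 1L))
  if (!axis %in% c("horizontal", "vertical", "both")) {
    stop_config("unknown flip axis: %s", axis)
  }
  out <- img
  if (axis %in% c("horizontal", "both")) out <- out[, rev(seq_len(ncol(out))), , drop = FALSE]
  if (axis %in% c("vertical", "both")) out <- out[rev(seq_len(nrow(out))), , , drop = FALSE]
  out
}

#' Double a dataset by augmentation
#'
#' For every raw entry, exactly one augmented copy is added, its method a
#' seeded uniform choice between additive noise and a random flip, so each
#' class's extended count is exactly twice its raw count. When `image_dir`
#' and `out_dir` are given the augmented images are materialized as PNGs;
#' otherwise only the manifest rows are created (augmented paths get an
#' `_aug` suffix).
#'
#' @param man a `weed_manifest` containing raw entries only.
#' @param seed integer seed governing method choices and the augmentations.
#' @param noise_sigma Gaussian sigma for the noise method.
#' @param image_dir directory holding the raw images (optional).
#' @param out_dir directory to write augmented images to (optional).
#' @return The extended `weed_manifest`.
#' @export
expand_dataset <- function(man, seed = 1L, noise_sigma = 0.02,
                           image_dir = NULL, out_dir = NULL) {
  stopifnot(inherits(man, "weed_manifest"))
  if (nrow(man) == 0L) stop_config("manifest is empty")
  if (any(man$origin != "raw")) stop_config("manifest already contains augmented entries")
  n <- nrow(man)
  kinds <- with_seed(seed, sample(c("add_noise", "random_flip"), n, replace = TRUE))
  aug <- man
  aug$origin <- "augmented"
  aug$aug_kind <- kinds
  aug$path <- sub("(\\.[A-Za-z]+)?$", "_aug\\1", man$path)
  if (!is.null(image_dir) && !is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      src <- file.path(image_dir, man$path[i])
      img <- read_rgb(src)
      out <- augment_image(img, kinds[i], noise_sigma = noise_sigma,
                           seed = seed + i)
      dst <- file.path(out_dir, paste0(tools::file_path_sans_ext(basename(man$path[i])),
                                       "_aug.png"))
      write_rgb(out, dst)
      aug$path[i] <- basename(dst)
    }
  }
  out <- rbind(man, aug)
  class(out) <- c("weed_manifest", "data.frame")
  out
}

#' Resize then center-crop an image
#'
#' Bilinear resize to `resize_to` x `resize_to`, then the central
#' `crop_to` x `crop_to` window (offset floor((resize_to - crop_to)/2) on
#' each axis). Defaults follow the standard 256 -> 224 training input.
#'
#' @param img H x W x 3 RGB array.
#' @param resize_to square resize target in pixels (default 256).
#' @param crop_to square crop size in pixels (default 224).
#' @return A `crop_to` x `crop_to` x 3 array.
#' @export
resize_center_crop <- function(img, resize_to = 256L, crop_to = 224L) {
  assert_rgb(img)
  if (crop_to > resize_to) stop_config("`crop_to` must not exceed `resize_to`")
  r <- if (all(dim(img)[1:2] == resize_to)) {
    img
  } else {
    x <- EBImage::resize(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                        colormode = "Color"),
                         w = resize_to, h = resize_to)
    aperm(as.array(x), c(2L, 1L, 3L))
  }
  off <- (resize_to - crop_to) %/% 2L
  clamp01(r[off + seq_len(crop_to), off + seq_len(crop_to), , drop = FALSE])
}

#' Assign train/test splits
#'
#' Seeded global shuffle; the first floor(ratio * N) entries become the
#' training set and the remainder the test set. With ratio 0.8 an extended
#' 11,078-entry manifest splits 8,862 / 2,216. A stratified per-class split
#' is available but off by default.
#'
#' @param man a `weed_manifest`.
#' @param ratio training fraction in (0, 1). Default 0.8.
#' @param seed integer seed.
#' @param stratify split within each class instead of globally.
#' @return The manifest with its `split` column assigned.
#' @export
split_dataset <- function(man, ratio = 0.8, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(man, "weed_manifest"))
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop_config("`ratio` must lie strictly between 0 and 1")
  }
  assign_split <- function(idx, seed) {
    n <- length(idx)
    ord <- with_seed(seed, sample.int(n))
    n_train <- floor(ratio * n)
    list(train = idx[ord[seq_len(n_train)]],
         test = idx[ord[setdiff(seq_len(n), seq_len(n_train))]])
  }
  man$split <- "unassigned"
  if (stratify) {
    for (k in unique(man$class)) {
      idx <- which(man$class == k)
      a <- assign_split(idx, seed + match(k, sort(unique(man$class))))
      man$split[a$train] <- "train"
      man$split[a$test] <- "test"
    }
  } else {
    a <- assign_split(seq_len(nrow(man)), seed)
    man$split[a$train] <- "train"
    man$split[a$test] <- "test"
  }
  man
}

#' Write a manifest to CSV
#' @param man a `weed_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(man, path) {
  stopifnot(inherits(man, "weed_manifest"))
  write.csv(as.data.frame(man), path, row.names = FALSE)
  invisible(path)
}

#' Read a manifest from CSV
#' @param path CSV path written by [write_manifest()].
#' @return A `weed_manifest`.
#' @export
read_manifest <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "path", "origin", "split", "aug_kind")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_config("manifest CSV lacks column(s): %s",
                                paste(miss, collapse = ", "))
  d$aug_kind <- as.character(d$aug_kind)
  class(d) <- c("weed_manifest", "data.frame")
  d
}

#' Write a per-class JSON summary of a manifest
#' @param man a `weed_manifest`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest_summary <- function(man, path) {
  jsonlite::write_json(manifest_summary(man), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
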