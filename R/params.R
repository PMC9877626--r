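#' Enhancement parameters
#'
#' Coefficients of the non-linear variance normalization and the exponential
#' gray-level enhancement. The normalization maps a max-scaled local variance
#' v through a*v / (b*v + (a - b)), a concave bijection of \[0,1\] that
#' expands contrast among small variances. The enhancement multiplies the
#' gray image by the gain 1 / (exp(k*V^2) - m): below the crossover variance
#' V* = sqrt(log(1+m)/k) the gain exceeds 1 (smooth leaf regions are
#' brightened), above it the gain collapses towards zero (fine-textured
#' background is suppressed).
#'
#' @param a normalization numerator coefficient, > 0. Default 6.
#' @param b normalization denominator coefficient, 0 < b < a. Default 5.
#' @param k enhancement sharpness, > 0. Default 50.
#' @param m gain offset in (0, 1). Default 0.99.
#' @return An object of class `enhance_params`.
#' @examples
#' p <- enhance_params()
#' enhancement_crossover(p$k, p$m) # ~0.117, rounds to 0.12
#' @export
enhance_params <- function(a = 6, b = 5, k = 50, m = 0.99) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0) {
    stop_config("`a` and `b` must be positive")
  }
  if (a <= b) stop_config("`a` must exceed `b` (a=%g, b=%g)", a, b)
  if (k <= 0) stop_config("`k` must be positive")
  if (m <= 0 || m >= 1) stop_config("`m` must lie in (0, 1)")
  structure(list(a = a, b = b, k = k, m = m), class = "enhance_params")
}

#' Morphological cleanup parameters
#'
#' @param selem_shape structuring element shape, `"disk"` or `"square"`.
#' @param selem_radius structuring element radius in pixels, >= 1.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(selem_shape = c("disk", "square"),
                              selem_radius = 2L) {
  selem_shape <- match.arg(selem_shape)
  selem_radius <- as.integer(selem_radius)
  if (selem_radius < 1L) stop_config("`selem_radius` must be >= 1")
  structure(list(selem_shape = selem_shape, selem_radius = selem_radius,
                 order = c("open", "close")),
            class = "morphology_params")
}

#' Default run configuration
#'
#' A nested list of every tunable parameter in the pipeline with its
#' default value: enhancement and morphology coefficients, ECA attention
#' coefficients, architecture sizes, training hyperparameters and fixture
#' generator defaults. Written to / read from YAML so that any run is
#' reproducible from its echoed configuration plus a seed.
#'
#' @return A named list of parameter groups.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    enhance = list(a = 6, b = 5, k = 50, m = 0.99),
    morphology = list(selem_shape = "disk", selem_radius = 2L),
    binarize = list(method = "otsu", threshold = NULL),
    segmentation = list(gray_source = "exg"),
    dataset = list(resize_to = 256L, crop_to = 224L, split_ratio = 0.8,
                   noise_sigma = 0.02, split_mode = "split_after_augment"),
    eca = list(gamma = 2, beta = 1),
    model = list(block_sizes = c(6L, 12L, 24L, 16L), growth_rate = 32L,
                 dropout = 0.5, input_size = 224L, num_classes = 12L,
                 stem_kernel = 7L, use_eca = TRUE, use_stem_pool = TRUE,
                 final_block_layers = 1L, compression = 0.5),
    train = list(optimizer = "adam", learning_rate = 1e-4, batch_size = 64L,
                 epochs = 40L),
    fixture = list(image_size = 128L, n_leaves = 3L, leaf_scale = 18,
                   background = "turf", turf_frequency = 1, noise_sigma = 0.005)
  )
}

#' Write a configuration to YAML
#' @param config a configuration list, e.g. [default_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration from YAML, filling defaults
#'
#' Unknown top-level keys are rejected so that typos fail loudly; missing
#' keys fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop_config("unknown config key(s): %s",
                               paste(bad, collapse = ", "))
  merge_lists(base, user)
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
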