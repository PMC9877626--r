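# End-to-end plumbing behind the command-line interface: fixture synthesis
# to disk, directory segmentation with IoU reporting, augmentation/split
# materialization, and a desk-scale train/eval loop. Every run writes its
# effective configuration and a machine-readable summary.json under the
# run directory, so any run is reproducible from config + seed.

#' Write a directory of synthetic fixtures
#'
#' Generates `n_classes * per_class` fixtures (classes differ by leaf
#' count/size as in [make_classification_set()]), writing `images/*.png`,
#' ground-truth `masks/*.png` and `manifest.csv` under `out_dir`.
#'
#' @param out_dir output directory (created).
#' @param n_classes,per_class set size.
#' @param image_size square image side, pixels.
#' @param background fixture background type.
#' @param seed integer seed.
#' @return The manifest (invisibly), with paths relative to `out_dir`.
#' @export
synth_fixture_dir <- function(out_dir, n_classes = 2L, per_class = 10L,
                              image_size = 128L, background = "turf",
                              seed = 1L) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  count_cycle <- c(1L, 4L, 2L, 6L, 3L, 5L)
  classes <- sprintf("class_%02d", seq_len(n_classes))
  rows <- NULL
  i <- 0L
  for (k in seq_len(n_classes)) {
    n_leaves <- count_cycle[((k - 1L) %% length(count_cycle)) + 1L]
    for (j in seq_len(per_class)) {
      i <- i + 1L
      sp <- fixture_spec(image_size = image_size, n_leaves = n_leaves,
                         leaf_scale = image_size * 0.30 / sqrt(n_leaves),
                         background = background,
                         seed = seed * 100000L + i, class_label = classes[k])
      fx <- make_fixture(sp)
      rel <- sprintf("%s_img%04d.png", classes[k], j)
      write_rgb(fx$image, file.path(out_dir, "images", rel))
      write_mask(fx$mask, file.path(out_dir, "masks", rel))
      rows <- rbind(rows, data.frame(class = classes[k],
                                     path = file.path("images", rel),
                                     stringsAsFactors = FALSE))
    }
  }
  man <- manifest(rows$class, rows$path)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  invisible(man)
}

#' Segment every image in a directory
#'
#' Runs [segment_plant()] on each PNG/JPEG under `in_dir/images` (or
#' directly under `in_dir`), writing the binary mask and the masked RGB
#' image under `out_dir`. When `in_dir/masks` holds ground truth, a
#' per-image IoU is computed and summarized.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created).
#' @param p,mp,gray_source passed to [segment_plant()].
#' @return A summary list (also written to `out_dir/summary.json`):
#'   `n_images`, per-image `iou` (if ground truth found), `mean_iou`,
#'   `mean_foreground_fraction`.
#' @export
segment_directory <- function(in_dir, out_dir, p = enhance_params(),
                              mp = morphology_params(), gray_source = "exg") {
  img_dir <- if (dir.exists(file.path(in_dir, "images"))) {
    file.path(in_dir, "images")
  } else {
    in_dir
  }
  files <- list.files(img_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  if (!length(files)) stop_config("no images found under %s", img_dir)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masked"), recursive = TRUE, showWarnings = FALSE)
  gt_dir <- file.path(in_dir, "masks")
  ious <- numeric(0)
  fg <- numeric(length(files))
  for (i in seq_along(files)) {
    img <- read_rgb(file.path(img_dir, files[i]))
    seg <- segment_plant(img, p = p, mp = mp, gray_source = gray_source)
    write_mask(seg$mask, file.path(out_dir, "masks", files[i]))
    write_rgb(seg$image, file.path(out_dir, "masked", files[i]))
    fg[i] <- mean(seg$mask)
    gt_path <- file.path(gt_dir, files[i])
    if (file.exists(gt_path)) {
      ious <- c(ious, mask_iou(seg$mask, read_mask(gt_path)))
    }
  }
  summary <- list(n_images = length(files),
                  mean_foreground_fraction = mean(fg),
                  mean_iou = if (length(ious)) mean(ious) else NULL,
                  iou = if (length(ious)) ious else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}

load_manifest_images <- function(man, dir, input_size) {
  x <- array(0, c(input_size, input_size, 3L, nrow(man)))
  for (i in seq_len(nrow(man))) {
    img <- read_rgb(file.path(dir, man$path[i]))
    if (!all(dim(img)[1:2] == input_size)) {
      img <- resize_center_crop(img, resize_to = input_size,
                                crop_to = input_size)
    }
    x[, , , i] <- img
  }
  x
}

#' Run one pipeline command programmatically
#'
#' The engine behind the `weedseg` command line: executes the flow
#' data -> preprocess -> train -> predict on directories of images.
#'
#' @param command one of `"synth"`, `"segment"`, `"augment"`, `"split"`,
#'   `"train"`, `"eval"`.
#' @param config a configuration list as from [default_config()].
#' @param in_dir input directory (commands other than `synth`).
#' @param out_dir output/run directory.
#' @param seed integer seed overriding `config$seed`.
#' @param preprocess for `train`/`eval`: apply background segmentation to
#'   each image before feeding the classifier (the `--no-preprocess`
#'   ablation arm sets this FALSE).
#' @param weights_file for `eval`: RDS file of [save_weights()] output
#'   written by a previous `train` run.
#' @return A summary list; every command also writes `summary.json` and
#'   echoes the effective config to `config.yaml` under `out_dir`.
#' @export
run_pipeline <- function(command = c("synth", "segment", "augment", "split",
                                     "train", "eval"),
                         config = default_config(), in_dir = NULL,
                         out_dir = NULL, seed = NULL, preprocess = TRUE,
                         weights_file = NULL) {
  command <- match.arg(command)
  if (is.null(out_dir)) stop_config("`out_dir` is required")
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  p <- do.call(enhance_params, config$enhance)
  mp <- do.call(morphology_params, config$morphology)

  summary <- switch(
    command,
    synth = {
      man <- synth_fixture_dir(out_dir,
                               n_classes = config$model$num_classes,
                               per_class = 8L,
                               image_size = config$fixture$image_size,
                               background = config$fixture$background,
                               seed = seed)
      list(command = "synth", n_images = nrow(man))
    },
    segment = {
      if (is.null(in_dir)) stop_config("`in_dir` is required for segment")
      c(list(command = "segment"),
        segment_directory(in_dir, out_dir, p = p, mp = mp,
                          gray_source = config$segmentation$gray_source))
    },
    augment = {
      if (is.null(in_dir)) stop_config("`in_dir` is required for augment")
      man <- read_manifest(file.path(in_dir, "manifest.csv"))
      ext <- expand_dataset(man, seed = seed,
                            noise_sigma = config$dataset$noise_sigma,
                            image_dir = in_dir,
                            out_dir = file.path(out_dir, "images"))
      write_manifest(ext, file.path(out_dir, "manifest.csv"))
      write_manifest_summary(ext, file.path(out_dir, "class_summary.json"))
      list(command = "augment", n_raw = sum(ext$origin == "raw"),
           n_total = nrow(ext))
    },
    split = {
      if (is.null(in_dir)) stop_config("`in_dir` is required for split")
      man <- read_manifest(file.path(in_dir, "manifest.csv"))
      man <- split_dataset(man, ratio = config$dataset$split_ratio, seed = seed)
      write_manifest(man, file.path(out_dir, "manifest.csv"))
      list(command = "split", n_train = sum(man$split == "train"),
           n_test = sum(man$split == "test"))
    },
    train = {
      if (is.null(in_dir)) stop_config("`in_dir` is required for train")
      man <- read_manifest(file.path(in_dir, "manifest.csv"))
      if (!any(man$split == "train")) stop_config("manifest has no train split")
      cfg <- do.call(eca_dense_config, config$model)
      eca <- do.call(eca_config, config$eca)
      tc <- do.call(train_config, c(config$train[c("learning_rate",
                                                   "batch_size", "epochs")],
                                    list(seed = seed)))
      classes <- sort(unique(man$class))
      prep <- function(sub) {
        x <- load_manifest_images(sub, in_dir, cfg$input_size)
        if (preprocess) {
          for (i in seq_len(dim(x)[4L])) {
            x[, , , i] <- segment_plant(x[, , , i], p = p, mp = mp)$image
          }
        }
        list(x = x, y = match(sub$class, classes))
      }
      tr <- prep(man[man$split == "train", , drop = FALSE])
      va <- if (any(man$split == "test")) {
        prep(man[man$split == "test", , drop = FALSE])
      }
      model <- build_model(cfg, eca, seed = seed)
      fit <- train_model(model, tr, tc, valid = va)
      write.csv(fit$history, file.path(out_dir, "history.csv"),
                row.names = FALSE)
      saveRDS(list(weights = save_weights(fit$model), classes = classes,
                   model_config = cfg, eca_config = eca),
              file.path(out_dir, "weights.rds"))
      list(command = "train",
           final_train_acc = fit$history$train_acc[nrow(fit$history)],
           final_valid_acc = fit$history$valid_acc[nrow(fit$history)],
           epochs_run = nrow(fit$history))
    },
    eval = {
      if (is.null(in_dir) || is.null(weights_file)) {
        stop_config("`in_dir` and `weights_file` are required for eval")
      }
      ck <- readRDS(weights_file)
      model <- build_model(ck$model_config, ck$eca_config, seed = seed)
      load_weights(model, ck$weights)
      man <- read_manifest(file.path(in_dir, "manifest.csv"))
      sub <- man[man$split == "test", , drop = FALSE]
      if (!nrow(sub)) sub <- man
      x <- load_manifest_images(sub, in_dir, ck$model_config$input_size)
      if (preprocess) {
        for (i in seq_len(dim(x)[4L])) {
          x[, , , i] <- segment_plant(x[, , , i], p = p, mp = mp)$image
        }
      }
      res <- evaluate_model(model, list(x = x, y = match(sub$class, ck$classes)),
                            classes = ck$classes)
      list(command = "eval", accuracy = res$accuracy,
           per_class = as.list(res$per_class),
           confusion = apply(res$confusion, 1L, as.list),
           mean_inference_ms = res$mean_inference_ms)
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}
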