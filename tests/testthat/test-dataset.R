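test_that("doubling augmentation reproduces the published per-class counts", {
  man <- manifest_from_counts(seedling_class_counts())
  expect_equal(nrow(man), 5539L)
  ext <- expand_dataset(man, seed = 1)
  expect_equal(nrow(ext), 11078L)
  s <- manifest_summary(ext)
  expect_equal(s$extended, 2L * s$raw)
  expect_equal(s$extended[s$class == "common_chickweed"], 1426L)
  expect_equal(s$raw[s$class == "common_chickweed"], 713L)
})

test_that("expansion is deterministic per seed and rejects bad input", {
  man <- manifest(rep(c("a", "b"), c(3, 4)), sprintf("img%02d.png", 1:7))
  e1 <- expand_dataset(man, seed = 42)
  e2 <- expand_dataset(man, seed = 42)
  expect_identical(e1, e2)
  e3 <- expand_dataset(man, seed = 43)
  expect_false(identical(e1$aug_kind, e3$aug_kind))
  expect_true(all(e1$aug_kind[e1$origin == "augmented"] %in%
                    c("add_noise", "random_flip")))
  expect_error(expand_dataset(e1), "augmented entries")
  expect_error(manifest(character(0), character(0)), "at least one")
})

test_that("flips are involutions and zero-sigma noise is the identity", {
  set.seed(8)
  img <- array(runif(10 * 12 * 3), c(10, 12, 3))
  for (ax in c("horizontal", "vertical", "both")) {
    once <- augment_image(img, "random_flip", flip_axis = ax)
    expect_equal(augment_image(once, "random_flip", flip_axis = ax), img)
  }
  expect_equal(augment_image(img, "add_noise", noise_sigma = 0), img)
  n1 <- augment_image(img, "add_noise", seed = 5)
  n2 <- augment_image(img, "add_noise", seed = 5)
  expect_identical(n1, n2)
  expect_false(identical(n1, augment_image(img, "add_noise", seed = 6)))
  expect_equal(dim(n1), dim(img))
  expect_true(min(n1) >= 0 && max(n1) <= 1)
})

test_that("resize-center-crop takes the central window", {
  set.seed(3)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  out <- resize_center_crop(img)
  expect_equal(out, img[17:240, 17:240, ])
  flat <- flat_rgb(224, 224, c(0.2, 0.6, 0.3))
  out2 <- resize_center_crop(flat)
  expect_equal(dim(out2), c(224L, 224L, 3L))
  expect_equal(max(abs(sweep(out2, 3, c(0.2, 0.6, 0.3)))), 0, tolerance = 1e-7)
  small <- array(runif(20 * 30 * 3), c(20, 30, 3))
  expect_equal(dim(resize_center_crop(small)), c(224L, 224L, 3L))
})

test_that("the 0.8 split reproduces the published train/test sizes", {
  man <- expand_dataset(manifest_from_counts(), seed = 1)
  sp <- split_dataset(man, ratio = 0.8, seed = 2)
  expect_equal(sum(sp$split == "train"), 8862L)
  expect_equal(sum(sp$split == "test"), 2216L)
  expect_equal(sum(sp$split == "unassigned"), 0L)
})

test_that("splitting conserves entries, is deterministic, and validates ratio", {
  man <- manifest(rep(c("a", "b"), 5), sprintf("i%02d", 1:10))
  sp <- split_dataset(man, ratio = 0.5, seed = 7)
  expect_equal(sum(sp$split == "train"), 5L)
  expect_equal(sum(sp$split == "test"), 5L)
  expect_identical(split_dataset(man, 0.5, seed = 7), sp)
  expect_false(identical(split_dataset(man, 0.5, seed = 8)$split, sp$split))
  expect_error(split_dataset(man, ratio = 1.2), "between 0 and 1")
  st <- split_dataset(man, ratio = 0.5, seed = 7, stratify = TRUE)
  for (k in c("a", "b")) {
    expect_equal(sum(st$split == "train" & st$class == k), 2L)  # floor(0.5*5)
  }
})

test_that("manifests round-trip through CSV and summarize to JSON", {
  man <- split_dataset(expand_dataset(manifest(rep("a", 4), sprintf("i%d.png", 1:4)),
                                      seed = 1), 0.5, seed = 1)
  tf <- tempfile(fileext = ".csv")
  write_manifest(man, tf)
  back <- read_manifest(tf)
  expect_equal(as.data.frame(back), as.data.frame(man))
  tj <- tempfile(fileext = ".json")
  write_manifest_summary(man, tj)
  j <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(j$raw, 4L)
  expect_equal(j$extended, 8L)
})

test_that("materialized augmentation writes readable augmented images", {
  dir_in <- file.path(tempdir(), "aug_in")
  dir.create(dir_in, showWarnings = FALSE)
  cs <- make_classification_set(2, 2, seed = 4, image_size = 16, dir = dir_in)
  out <- file.path(tempdir(), "aug_out")
  ext <- expand_dataset(cs$manifest, seed = 9, image_dir = dir_in,
                        out_dir = out)
  aug <- ext[ext$origin == "augmented", ]
  expect_equal(nrow(aug), 4L)
  for (pth in aug$path) {
    img <- read_rgb(file.path(out, pth))
    expect_equal(dim(img), c(16L, 16L, 3L))
  }
})
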