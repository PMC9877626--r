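test_that("excess-green index matches hand-evaluated pixels", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(0.2, 0.2, 0.2)  # gray: 2g = r + b boundary
  img[1, 2, ] <- c(1, 0, 0)        # pure red: clipped to 0
  img[2, 1, ] <- c(0, 1, 0)        # pure green: raw 2.0 -> rescaled 1.0
  img[2, 2, ] <- c(0, 0, 0)        # zero-sum pixel -> defined 0
  e <- compute_exg(img)
  expect_equal(e[1, 1], 0)
  expect_equal(e[1, 2], 0)
  expect_equal(e[2, 1], 1)
  expect_equal(e[2, 2], 0)
  expect_equal(dim(e), dim(img)[1:2])
})

test_that("excess-green index is invariant to global brightness scaling", {
  set.seed(4)
  img <- array(runif(12 * 12 * 3, 0.1, 1), c(12, 12, 3))
  expect_equal(compute_exg(img * 0.5), compute_exg(img), tolerance = 1e-12)
})

test_that("excess-green rejects non-finite input", {
  img <- array(0.5, c(4, 4, 3))
  img[1, 1, 1] <- NA
  expect_error(compute_exg(img), "non-finite")
})

test_that("local variance matches hand evaluation and handles degenerate input", {
  expect_equal(local_variance(matrix(0.7, 5, 5)), matrix(0, 5, 5))
  g <- matrix(0, 3, 3); g[2, 2] <- 1
  expect_equal(local_variance(g)[2, 2], 8 / 81, tolerance = 1e-12)
  expect_error(local_variance(matrix(0, 2, 5)), "at least 3 x 3")
})

test_that("local variance equals the brute-force window oracle on random images", {
  set.seed(7)
  for (i in 1:10) {
    h <- sample(3:32, 1); w <- sample(3:32, 1)
    g <- matrix(runif(h * w), h, w)
    expect_equal(local_variance(g), local_variance_oracle(g),
                 tolerance = 1e-12)
  }
})

test_that("non-linear normalization fixes endpoints and boosts mid-range", {
  v <- matrix(c(0, 0.5, 1), 3, 1)
  V <- normalize_variance(v)
  expect_equal(V[1, 1], 0)
  expect_equal(V[2, 1], 3 / 3.5, tolerance = 1e-12)  # 6*0.5/(5*0.5+1)
  expect_equal(V[3, 1], 1)
})

test_that("normalization is monotone and sits above the diagonal", {
  u <- matrix(seq(0, 1, by = 0.001), ncol = 1)
  V <- normalize_variance(u)
  expect_true(all(diff(V[, 1]) > 0))
  expect_true(all(V >= u))
  # endpoint identity holds for any a > b
  for (ab in list(c(2, 1), c(10, 3), c(1.5, 1.49))) {
    p <- enhance_params(a = ab[1], b = ab[2])
    expect_equal(normalize_variance(matrix(1), p)[1, 1], 1)
  }
})

test_that("an all-zero variance map stays zero and a<=b is rejected", {
  expect_equal(normalize_variance(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(enhance_params(a = 5, b = 5), "exceed")
  expect_error(enhance_params(a = 4, b = 5), "exceed")
})

test_that("enhancement gain matches hand evaluation at the extremes", {
  # V = 0: gain 1/(1 - 0.99) = 100
  expect_equal(enhance(matrix(0.005), matrix(0))[1, 1], 0.5)
  # gain clipped at 1.0 gray level
  expect_equal(enhance(matrix(0.5), matrix(0))[1, 1], 1)
  # V = 1: gain 1/(e^50 - 0.99), essentially zero
  expect_lt(enhance(matrix(0.9), matrix(1))[1, 1], 1e-20)
  expect_error(enhance(matrix(0.5), matrix(0, 2, 2)), "shapes differ")
  expect_error(enhance_params(k = -1), "positive")
  expect_error(enhance_params(m = 1.2), "\\(0, 1\\)")
})

test_that("the enhancement gain crosses 1 at sqrt(log(1+m)/k)", {
  vstar <- enhancement_crossover(50, 0.99)
  expect_gte(vstar, 0.117)
  expect_lte(vstar, 0.118)
  p <- enhance_params()
  gain <- function(V) 1 / (exp(p$k * V^2) - p$m)
  expect_gt(gain(vstar - 1e-4), 1)
  expect_lt(gain(vstar + 1e-4), 1)
})

test_that("binarization separates two-level images and flags constants", {
  g <- matrix(rep(c(0, 1), each = 8), 4, 4)
  expect_equal(binarize(g), g == 1)
  expect_warning(m <- binarize(matrix(0.4, 6, 6)), "constant")
  expect_false(any(m))
  expect_equal(binarize(matrix(c(0.1, 0.9), 4, 4), method = "fixed",
                        threshold = 0.5),
               matrix(c(FALSE, TRUE), 4, 4))
})

test_that("binarization survives impulse noise on a two-level image", {
  set.seed(21)
  truth <- matrix(runif(64 * 64) < 0.4, 64, 64)
  g <- ifelse(truth, 0.8, 0.2)
  hit <- sample(length(g), round(0.1 * length(g)))
  g[hit] <- pmin(pmax(g[hit] + sample(c(-0.1, 0.1), length(hit), TRUE), 0), 1)
  mask <- binarize(g)
  expect_gte(mean(mask == truth), 0.99)
})

test_that("morphological cleanup removes specks and fills holes", {
  mask <- matrix(FALSE, 64, 64)
  mask[21:40, 21:40] <- TRUE          # 20x20 solid square
  truth <- mask
  mask[30:31, 30:31] <- FALSE         # 2x2 hole
  singles <- cbind(c(3, 10, 50, 60, 5), c(3, 55, 8, 60, 30))
  mask[singles] <- TRUE               # five isolated pixels
  mp <- morphology_params(selem_shape = "square", selem_radius = 2)
  cleaned <- morph_cleanup(mask, mp)
  expect_equal(cleaned, truth)
  # idempotence
  expect_equal(morph_cleanup(cleaned, mp), cleaned)
  disk <- morph_cleanup(mask, morphology_params())
  expect_equal(morph_cleanup(disk, morphology_params()), disk)
  # fixed points
  empty <- matrix(FALSE, 16, 16)
  expect_equal(morph_cleanup(empty), empty)
  full <- matrix(TRUE, 16, 16)
  expect_equal(morph_cleanup(full), full)
})

test_that("mask application keeps foreground and blacks out background", {
  set.seed(5)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(apply_mask(img, matrix(TRUE, 8, 8)), img)
  expect_equal(apply_mask(img, matrix(FALSE, 8, 8)), array(0, c(8, 8, 3)))
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  out <- apply_mask(img, chk)
  nz <- apply(out, c(1, 2), function(p) any(p > 0))
  expect_equal(nz, chk)
  expect_error(apply_mask(img, matrix(TRUE, 4, 4)), "shapes differ")
})

test_that("segmentation recovers leaves on turf and nothing on bare soil", {
  fx <- make_fixture(fixture_spec(image_size = 128, n_leaves = 2,
                                  leaf_scale = 24, seed = 7))
  seg <- segment_plant(fx$image)
  expect_gte(mask_iou(seg$mask, fx$mask), 0.8)
  expect_equal(dim(seg$mask), dim(fx$mask))
  expect_equal(dim(seg$image), dim(fx$image))
  soil <- make_fixture(fixture_spec(image_size = 128, n_leaves = 0,
                                    background = "soil", seed = 3))
  expect_lt(mean(segment_plant(soil$image)$mask), 0.01)
  # all-black image: degenerate, all-background
  seg0 <- segment_plant(array(0, c(16, 16, 3)))
  expect_false(any(seg0$mask))
  expect_equal(seg0$image, array(0, c(16, 16, 3)))
})

test_that("segmentation mask is stable under global brightness scaling", {
  fx <- make_fixture(fixture_spec(image_size = 96, n_leaves = 1,
                                  leaf_scale = 28, seed = 13))
  base <- segment_plant(fx$image)$mask
  for (s in c(0.5, 0.7, 1)) {
    scaled <- segment_plant(fx$image * s)$mask
    expect_lte(mean(scaled != base), 0.05)
  }
})

test_that("every preprocessing stage preserves image dimensions", {
  fx <- make_fixture(fixture_spec(image_size = 48, seed = 2))
  f <- compute_exg(fx$image)
  v <- local_variance(f)
  V <- normalize_variance(v)
  g <- enhance(f, V)
  m <- binarize(g)
  m2 <- morph_cleanup(m)
  out <- apply_mask(fx$image, m2)
  for (x in list(f, v, V, g, m, m2)) expect_equal(dim(x), c(48L, 48L))
  expect_equal(dim(out), dim(fx$image))
})

test_that("image and mask round-trip through PNG", {
  fx <- make_fixture(fixture_spec(image_size = 32, seed = 9))
  tf <- tempfile(fileext = ".png")
  write_rgb(fx$image, tf)
  back <- read_rgb(tf)
  expect_equal(dim(back), dim(fx$image))
  expect_lt(max(abs(back - fx$image)), 1 / 255)
  tm <- tempfile(fileext = ".png")
  write_mask(fx$mask, tm)
  expect_equal(read_mask(tm), fx$mask)
})
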