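test_that("a scaled model emits finite logits of the contracted shape", {
  cfg <- scaled_model_config(num_classes = 12L, input_size = 32L)
  m <- build_model(cfg, eca_config(), seed = 1)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  lg <- model_forward(m, x)
  expect_equal(dim(lg), c(2L, 12L))
  expect_true(all(is.finite(lg)))
  # single image without explicit batch dimension
  expect_equal(dim(model_forward(m, x[, , , 1])), c(1L, 12L))
})

test_that("the full-size architecture maps a 224x224 image to 12 logits", {
  m <- build_model(eca_dense_config(), eca_config(), seed = 1)
  lg <- model_forward(m, array(0.5, c(224, 224, 3)))
  expect_equal(dim(lg), c(1L, 12L))
  expect_true(all(is.finite(lg)))
})

test_that("disabling attention removes exactly the eca nodes from the graph", {
  with_g <- model_layer_types(build_model(scaled_model_config(use_eca = TRUE),
                                          seed = 1))
  without_g <- model_layer_types(build_model(scaled_model_config(use_eca = FALSE),
                                             seed = 1))
  expect_true("eca" %in% with_g)
  expect_false("eca" %in% without_g)
  expect_identical(with_g[with_g != "eca"], without_g)
})

test_that("training is reproducible and a zero learning rate learns nothing", {
  d <- two_class_set(per_class = 4L, image_size = 16L)
  cfg <- scaled_model_config(input_size = 16L)
  tc <- scaled_train_config(epochs = 2L)
  f1 <- train_model(build_model(cfg, seed = 2), d, tc)
  f2 <- train_model(build_model(cfg, seed = 2), d, tc)
  expect_equal(f1$history, f2$history)
  m0 <- build_model(cfg, seed = 2)
  w_before <- save_weights(m0)
  train_model(m0, d, train_config(learning_rate = 0, batch_size = 8,
                                  epochs = 2, seed = 1))
  expect_equal(save_weights(m0), w_before)
})

test_that("training rejects empty or inconsistent data", {
  m <- build_model(scaled_model_config(input_size = 16L), seed = 1)
  expect_error(train_model(m, list(x = NULL, y = NULL)), "must have")
  expect_error(train_model(m, list(x = array(0, c(16, 16, 3, 2)), y = 1L)),
               "inconsistent")
})

test_that("evaluation reports a coherent confusion matrix", {
  d <- two_class_set(per_class = 10L)
  m <- build_model(scaled_model_config(), seed = 3)
  fit <- train_model(m, d, scaled_train_config(), stop_at_train_acc = 1)
  res <- evaluate_model(fit$model, d, classes = d$classes)
  expect_equal(rowSums(res$confusion), c(class_01 = 10, class_02 = 10))
  expect_equal(sum(res$confusion), length(d$y))
  expect_equal(res$accuracy, mean(res$predictions == d$y))
  expect_equal(unname(res$per_class),
               unname(diag(res$confusion) / rowSums(res$confusion)))
  expect_true(res$mean_inference_ms >= 0)
  # when predictions agree with truth everywhere the confusion is diagonal
  perfect <- evaluate_model(fit$model, list(x = d$x, y = res$predictions),
                            classes = d$classes)
  expect_equal(perfect$accuracy, 1.0)
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))
})

test_that("weights survive a save/load round trip", {
  cfg <- scaled_model_config(input_size = 16L)
  m1 <- build_model(cfg, seed = 4)
  m2 <- build_model(cfg, seed = 5)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_false(isTRUE(all.equal(model_forward(m1, x), model_forward(m2, x))))
  load_weights(m2, save_weights(m1))
  expect_equal(model_forward(m2, x), model_forward(m1, x))
  expect_error(load_weights(m2, list()), "does not match")
})
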