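# The engine's correctness hinges on its gradients; check every trainable
# layer against central finite differences through the whole network.

test_that("analytic gradients match finite differences through the full stack", {
  set.seed(42)
  cfg <- eca_dense_config(block_sizes = c(1, 1, 1, 1), growth_rate = 3,
                          dropout = 0, input_size = 16, num_classes = 3,
                          stem_kernel = 3, decoder_channels = 4)
  m <- build_model(cfg, eca_config(), seed = 5)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1L, 3L)
  loss_at <- function() {
    weedseg:::softmax_xent(model_forward(m, x, train = TRUE), y)$loss
  }
  sx <- weedseg:::softmax_xent(model_forward(m, x, train = TRUE), y)
  weedseg:::model_backward(m, sx$dlogits)
  layers <- weedseg:::flatten_layers(m$layers)
  expect_gt(length(layers), 20)
  worst <- 0
  for (ly in layers) {
    for (nm in names(ly$par)) {
      p <- ly$par[[nm]]
      for (ii in sample(length(p), min(2, length(p)))) {
        eps <- 1e-5
        ly$par[[nm]][ii] <- p[ii] + eps; lp <- loss_at()
        ly$par[[nm]][ii] <- p[ii] - eps; lm <- loss_at()
        ly$par[[nm]][ii] <- p[ii]
        num <- (lp - lm) / (2 * eps)
        ana <- ly$grad[[nm]][ii]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("convolution matches a naive sliding-window oracle", {
  set.seed(6)
  cv <- weedseg:::layer_conv(2L, 3L, 3L, stride = 1L, pad = 1L)
  x <- array(rnorm(5 * 4 * 2 * 1), c(5, 4, 2, 1))
  y <- cv$forward(x)
  W <- array(cv$par$W, c(3, 3, 2, 3))  # (dh, dw, c_in, c_out)
  naive <- array(0, c(5, 4, 3, 1))
  for (co in 1:3) {
    for (i in 1:5) {
      for (j in 1:4) {
        acc <- cv$par$b[co]
        for (di in 1:3) {
          for (dj in 1:3) {
            si <- i + di - 2; sj <- j + dj - 2
            if (si >= 1 && si <= 5 && sj >= 1 && sj <= 4) {
              acc <- acc + sum(x[si, sj, , 1] * W[di, dj, , co])
            }
          }
        }
        naive[i, j, co, 1] <- acc
      }
    }
  }
  expect_equal(y, naive, tolerance = 1e-12)
})

test_that("pooling layers reduce spatial size as configured", {
  x <- array(seq_len(4 * 4 * 2 * 1) / 32, c(4, 4, 2, 1))
  avg <- weedseg:::layer_pool("avg", 2L, 2L)
  y <- avg$forward(x)
  expect_equal(dim(y), c(2L, 2L, 2L, 1L))
  expect_equal(y[1, 1, 1, 1], mean(x[1:2, 1:2, 1, 1]))
  mx <- weedseg:::layer_pool("max", 3L, 2L, pad = 1L)
  ym <- mx$forward(x)
  expect_equal(dim(ym), c(2L, 2L, 2L, 1L))
  expect_equal(ym[2, 2, 2, 1], max(x[3:4, 3:4, 2, 1]))
  # degenerate spatial size falls through unchanged
  one <- array(1, c(1, 1, 3, 2))
  expect_equal(avg$forward(one), one)
})

test_that("adam reduces the loss of a small separable problem", {
  set.seed(14)
  lin <- weedseg:::layer_linear(2L, 2L)
  x <- rbind(matrix(rnorm(40, -1, 0.3), 20, 2),
             matrix(rnorm(40, 1, 0.3), 20, 2))
  y <- rep(1:2, each = 20)
  losses <- numeric(50)
  for (t in 1:50) {
    sx <- weedseg:::softmax_xent(lin$forward(x), y)
    losses[t] <- sx$loss
    lin$backward(sx$dlogits)
    weedseg:::adam_step(list(lin), 0.05, t)
  }
  expect_lt(losses[50], losses[1] / 5)
})
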