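# Shared helpers: independent brute-force oracles and small fixtures.
# Oracles deliberately use naive double loops so they share no code path
# with the implementation they check.

# per-pixel 3x3 window variance with replicate padding, divisor 9
local_variance_oracle <- function(g) {
  h <- nrow(g); w <- ncol(g)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- numeric(9)
      t <- 0L
      for (di in -1:1) {
        for (dj in -1:1) {
          t <- t + 1L
          vals[t] <- g[min(max(i + di, 1L), h), min(max(j + dj, 1L), w)]
        }
      }
      out[i, j] <- mean((vals - mean(vals))^2)
    }
  }
  out
}

# naive 1-D cross-channel convolution with zero padding
eca_conv1d_oracle <- function(s, kern) {
  C <- length(s)
  k <- length(kern)
  p <- (k - 1L) %/% 2L
  z <- numeric(C)
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      src <- c + (j - p - 1L)
      if (src >= 1L && src <= C) z[c] <- z[c] + kern[j] * s[src]
    }
  }
  z
}

# flat RGB image of one colour
flat_rgb <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

scaled_model_config <- function(num_classes = 2L, input_size = 32L,
                                use_eca = TRUE) {
  eca_dense_config(block_sizes = c(1L, 1L, 1L, 1L), growth_rate = 4L,
                   dropout = 0.1, input_size = input_size,
                   num_classes = num_classes, use_eca = use_eca)
}

scaled_train_config <- function(epochs = 30L, seed = 3L) {
  train_config(learning_rate = 3e-3, batch_size = 8L, epochs = epochs,
               seed = seed)
}

two_class_set <- function(seed = 11L, per_class = 20L, image_size = 32L) {
  cs <- make_classification_set(n_classes = 2L, per_class = per_class,
                                seed = seed, image_size = image_size)
  list(x = stack_images(cs$images), y = cs$labels, classes = cs$classes)
}
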