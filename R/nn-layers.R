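# Minimal convolutional-network engine.
#
# Feature maps are numeric arrays with dim (H, W, C, N). Each layer is an
# environment exposing $forward(x, train) and $backward(dout), holding its
# trainable arrays in $par, the matching gradients in $grad and Adam state
# in $adam. Convolution uses im2col: patch gathering by one precomputed
# integer index matrix, a single matrix multiply, and a rowsum scatter-add
# for the input gradient. Gradients are verified against numeric
# differentiation in the test suite.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$grad <- list()
  e$adam <- NULL
  e$sub <- list()
  e
}

rowrep <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# index matrix mapping (output pixel, patch offset) -> linear index into the
# zero-padded input array of dim (Hp, Wp, C, N)
conv_index <- function(H, W, C, N, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oh <- rep(seq_len(Ho), times = Wo * N)
  ow <- rep(rep(seq_len(Wo), each = Ho), times = N)
  nn <- rep(seq_len(N), each = Ho * Wo)
  row_part <- (oh - 1L) * stride + 1L + ((ow - 1L) * stride) * Hp +
    (nn - 1L) * (Hp * Wp * C)
  dh <- rep(seq_len(k) - 1L, times = k * C)
  dw <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  col_part <- dh + dw * Hp + (cc - 1L) * (Hp * Wp)
  idx <- outer(row_part, col_part, `+`)
  storage.mode(idx) <- "integer"
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

pad_input <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ] <- x
  xp
}

scatter_add <- function(values, index, length_out) {
  g <- rowsum(as.vector(values), as.vector(index))
  out <- numeric(length_out)
  out[as.integer(rownames(g))] <- g[, 1L]
  out
}

layer_conv <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       first = FALSE, type = "conv") {
  e <- new_layer(type)
  e$c_in <- c_in; e$c_out <- c_out; e$k <- k; e$stride <- stride
  e$pad <- pad; e$first <- first
  fan_in <- k * k * c_in
  e$par$W <- matrix(rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
  e$par$b <- numeric(c_out)
  e$icache <- list()
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    key <- paste(d, collapse = "x")
    if (is.null(e$icache[[key]])) {
      e$icache[[key]] <- conv_index(d[1L], d[2L], d[3L], d[4L], e$k,
                                    e$stride, e$pad)
    }
    ic <- e$icache[[key]]
    xp <- pad_input(x, e$pad)
    patches <- xp[as.vector(ic$idx)]   # linear indexing, never coordinate-matrix
    dim(patches) <- dim(ic$idx)
    out <- patches %*% e$par$W
    out <- out + rowrep(e$par$b, nrow(out))
    e$cache <- list(patches = patches, ic = ic, d = d)
    y <- array(out, c(ic$Ho, ic$Wo, d[4L], e$c_out))
    aperm(y, c(1L, 2L, 4L, 3L))
  }
  e$backward <- function(dout) {
    cc <- e$cache
    dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), nrow(cc$patches), e$c_out)
    e$grad$W <- crossprod(cc$patches, dmat)
    e$grad$b <- colSums(dmat)
    if (e$first) return(NULL)
    dpatch <- tcrossprod(dmat, e$par$W)
    d <- cc$d; ic <- cc$ic
    dxp <- scatter_add(dpatch, ic$idx, ic$Hp * ic$Wp * d[3L] * d[4L])
    dim(dxp) <- c(ic$Hp, ic$Wp, d[3L], d[4L])
    p <- e$pad
    if (p > 0L) {
      dxp[p + seq_len(d[1L]), p + seq_len(d[2L]), , , drop = FALSE]
    } else {
      dxp
    }
  }
  e
}

layer_bn <- function(C, momentum = 0.9, eps = 1e-5) {
  e <- new_layer("bn")
  e$C <- C; e$momentum <- momentum; e$eps <- eps
  e$par$gamma <- rep(1, C)
  e$par$beta <- rep(0, C)
  e$run_mean <- rep(0, C)
  e$run_var <- rep(1, C)
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    xr <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = e$C)
    R <- nrow(xr)
    if (train) {
      mu <- colMeans(xr)
      va <- colMeans(xr * xr) - mu * mu
      e$run_mean <- e$momentum * e$run_mean + (1 - e$momentum) * mu
      e$run_var <- e$momentum * e$run_var + (1 - e$momentum) * va
    } else {
      mu <- e$run_mean
      va <- e$run_var
    }
    sd <- sqrt(va + e$eps)
    xhat <- (xr - rowrep(mu, R)) / rowrep(sd, R)
    yr <- xhat * rowrep(e$par$gamma, R) + rowrep(e$par$beta, R)
    e$cache <- list(xhat = xhat, sd = sd, d = d, train = train)
    aperm(array(yr, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  }
  e$backward <- function(dout) {
    cc <- e$cache
    d <- cc$d
    dy <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = e$C)
    R <- nrow(dy)
    e$grad$gamma <- colSums(dy * cc$xhat)
    e$grad$beta <- colSums(dy)
    dxhat <- dy * rowrep(e$par$gamma, R)
    if (cc$train) {
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cc$xhat)
      dxr <- (dxhat - rowrep(m1, R) - cc$xhat * rowrep(m2, R)) / rowrep(cc$sd, R)
    } else {
      dxr <- dxhat / rowrep(cc$sd, R)
    }
    aperm(array(dxr, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
  }
  e
}

layer_relu <- function() {
  e <- new_layer("relu")
  e$forward <- function(x, train = FALSE) {
    e$cache <- x > 0
    x * e$cache
  }
  e$backward <- function(dout) dout * e$cache
  e
}

layer_dropout <- function(rate) {
  e <- new_layer("dropout")
  e$rate <- rate
  e$forward <- function(x, train = FALSE) {
    if (!train || e$rate == 0) {
      e$cache <- NULL
      return(x)
    }
    keep <- 1 - e$rate
    e$cache <- array((runif(length(x)) < keep) / keep, dim(x))
    x * e$cache
  }
  e$backward <- function(dout) {
    if (is.null(e$cache)) dout else dout * e$cache
  }
  e
}

layer_pool <- function(kind = c("max", "avg"), k = 2L, stride = k,
                       pad = 0L) {
  kind <- match.arg(kind)
  e <- new_layer(paste0(kind, "pool"))
  e$k <- k; e$stride <- stride; e$pad <- pad; e$kind <- kind
  e$icache <- list()
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    if (d[1L] + 2L * e$pad < e$k || d[2L] + 2L * e$pad < e$k) {
      # degenerate spatial size: identity
      e$cache <- list(skip = TRUE)
      return(x)
    }
    key <- paste(d, collapse = "x")
    if (is.null(e$icache[[key]])) {
      e$icache[[key]] <- conv_index(d[1L], d[2L], 1L, d[3L] * d[4L], e$k,
                                    e$stride, e$pad)
    }
    ic <- e$icache[[key]]
    xr <- x
    dim(xr) <- c(d[1L], d[2L], 1L, d[3L] * d[4L])
    xp <- pad_input(xr, e$pad, fill = if (e$kind == "max") -Inf else 0)
    patches <- xp[as.vector(ic$idx)]
    dim(patches) <- dim(ic$idx)
    if (e$kind == "max") {
      amax <- max.col(patches, ties.method = "first")
      val <- patches[cbind(seq_len(nrow(patches)), amax)]
      pos <- ic$idx[cbind(seq_len(nrow(patches)), amax)]
      e$cache <- list(skip = FALSE, pos = pos, ic = ic, d = d)
    } else {
      val <- rowMeans(patches)
      e$cache <- list(skip = FALSE, ic = ic, d = d)
    }
    y <- array(val, c(ic$Ho, ic$Wo, d[3L] * d[4L]))
    dim(y) <- c(ic$Ho, ic$Wo, d[3L], d[4L])
    y
  }
  e$backward <- function(dout) {
    cc <- e$cache
    if (cc$skip) return(dout)
    d <- cc$d; ic <- cc$ic
    len <- ic$Hp * ic$Wp * d[3L] * d[4L]
    dv <- as.vector(dout)
    if (e$kind == "max") {
      dxp <- scatter_add(dv, cc$pos, len)
    } else {
      dsp <- matrix(dv / (e$k * e$k), length(dv), e$k * e$k)
      dxp <- scatter_add(dsp, ic$idx, len)
    }
    dim(dxp) <- c(ic$Hp, ic$Wp, d[3L], d[4L])
    p <- e$pad
    dx <- if (p > 0L) {
      dxp[p + seq_len(d[1L]), p + seq_len(d[2L]), , , drop = FALSE]
    } else {
      dxp
    }
    dim(dx) <- d
    dx
  }
  e
}

layer_gap <- function() {
  e <- new_layer("gap")
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    e$cache <- d
    cm <- colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L]))
    t(matrix(cm, d[3L], d[4L]))         # N x C
  }
  e$backward <- function(dout) {
    d <- e$cache
    dx <- rep(as.vector(t(dout)), each = d[1L] * d[2L]) / (d[1L] * d[2L])
    dim(dx) <- d
    dx
  }
  e
}

layer_linear <- function(c_in, c_out) {
  e <- new_layer("linear")
  e$par$W <- matrix(rnorm(c_in * c_out, 0, sqrt(2 / c_in)), c_in, c_out)
  e$par$b <- numeric(c_out)
  e$forward <- function(x, train = FALSE) {
    e$cache <- x
    x %*% e$par$W + rowrep(e$par$b, nrow(x))
  }
  e$backward <- function(dout) {
    e$grad$W <- crossprod(e$cache, dout)
    e$grad$b <- colSums(dout)
    tcrossprod(dout, e$par$W)
  }
  e
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# shift rows of a C x N matrix by `off` with zero padding
shift_rows <- function(s, off) {
  C <- nrow(s)
  out <- matrix(0, C, ncol(s))
  if (off == 0L) return(s)
  if (off > 0L) {
    out[seq_len(C - off), ] <- s[(off + 1L):C, , drop = FALSE]
  } else {
    out[(-off + 1L):C, ] <- s[seq_len(C + off), , drop = FALSE]
  }
  out
}

layer_eca <- function(C, gamma = 2, beta = 1) {
  e <- new_layer("eca")
  e$C <- C
  e$ksize <- eca_kernel_size(C, gamma, beta)
  e$par$kern <- rnorm(e$ksize, 0, 0.3)
  e$forward <- function(x, train = FALSE) {
    d <- dim(x)
    s <- matrix(colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])), d[3L], d[4L])
    p <- (e$ksize - 1L) %/% 2L
    z <- matrix(0, d[3L], d[4L])
    for (j in seq_len(e$ksize)) {
      z <- z + e$par$kern[j] * shift_rows(s, j - p - 1L)
    }
    w <- sigmoid(z)
    e$cache <- list(x = x, s = s, w = w, d = d)
    x * array(rep(as.vector(w), each = d[1L] * d[2L]), d)
  }
  e$backward <- function(dout) {
    cc <- e$cache
    d <- cc$d
    hw <- d[1L] * d[2L]
    wrep <- array(rep(as.vector(cc$w), each = hw), d)
    dx <- dout * wrep
    dw <- matrix(colSums(matrix(dout * cc$x, hw, d[3L] * d[4L])), d[3L], d[4L])
    dz <- dw * cc$w * (1 - cc$w)
    p <- (e$ksize - 1L) %/% 2L
    dkern <- numeric(e$ksize)
    ds <- matrix(0, d[3L], d[4L])
    for (j in seq_len(e$ksize)) {
      off <- j - p - 1L
      sh <- shift_rows(cc$s, off)
      dkern[j] <- sum(dz * sh)
      ds <- ds + e$par$kern[j] * shift_rows(dz, -off)
    }
    e$grad$kern <- dkern
    dx + array(rep(as.vector(ds / hw), each = hw), d)
  }
  e
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# Densely connected block: each layer applies BN-ReLU-Conv3x3 to the
# concatenation of all previous outputs and appends `growth` new channels;
# with `use_eca` an ECA reweighting follows each dense connection.
layer_dense_block <- function(c_in, n_layers, growth, use_eca = TRUE,
                              eca_gamma = 2, eca_beta = 1) {
  e <- new_layer(if (use_eca) "eca_dense_block" else "dense_block")
  e$c_in <- c_in; e$n_layers <- n_layers; e$growth <- growth
  e$c_out <- c_in + n_layers * growth
  e$bn <- list(); e$relu <- list(); e$conv <- list(); e$eca <- list()
  C <- c_in
  for (i in seq_len(n_layers)) {
    e$bn[[i]] <- layer_bn(C)
    e$relu[[i]] <- layer_relu()
    e$conv[[i]] <- layer_conv(C, growth, 3L)
    C <- C + growth
    if (use_eca) e$eca[[i]] <- layer_eca(C, eca_gamma, eca_beta)
  }
  e$use_eca <- use_eca
  e$sub <- c(e$bn, e$conv, if (use_eca) e$eca)
  e$forward <- function(x, train = FALSE) {
    for (i in seq_len(e$n_layers)) {
      h <- e$bn[[i]]$forward(x, train)
      h <- e$relu[[i]]$forward(h, train)
      nw <- e$conv[[i]]$forward(h, train)
      x <- concat_channels(x, nw)
      if (e$use_eca) x <- e$eca[[i]]$forward(x, train)
    }
    x
  }
  e$backward <- function(dout) {
    d <- dout
    for (i in rev(seq_len(e$n_layers))) {
      if (e$use_eca) d <- e$eca[[i]]$backward(d)
      cprev <- e$c_in + (i - 1L) * e$growth
      d_prev <- d[, , seq_len(cprev), , drop = FALSE]
      d_new <- d[, , cprev + seq_len(e$growth), , drop = FALSE]
      dh <- e$conv[[i]]$backward(d_new)
      dh <- e$relu[[i]]$backward(dh)
      d <- d_prev + e$bn[[i]]$backward(dh)
    }
    d
  }
  e
}

# Transition between dense blocks: BN-ReLU-Conv3x3 (channel compression)
# followed by 2x2 average pooling.
layer_transition <- function(c_in, compression = 0.5) {
  e <- new_layer("transition")
  e$c_out <- max(1L, as.integer(floor(c_in * compression)))
  e$bn1 <- layer_bn(c_in)
  e$relu1 <- layer_relu()
  e$conv1 <- layer_conv(c_in, e$c_out, 3L)
  e$pool1 <- layer_pool("avg", 2L, 2L)
  e$sub <- list(e$bn1, e$conv1)
  e$forward <- function(x, train = FALSE) {
    h <- e$bn1$forward(x, train)
    h <- e$relu1$forward(h, train)
    h <- e$conv1$forward(h, train)
    e$pool1$forward(h, train)
  }
  e$backward <- function(dout) {
    d <- e$pool1$backward(dout)
    d <- e$conv1$backward(d)
    d <- e$relu1$backward(d)
    e$bn1$backward(d)
  }
  e
}

# ---- parameter walking and Adam -------------------------------------------

flatten_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (length(ly$sub)) {
      out <- c(out, flatten_layers(ly$sub))
    }
    if (length(ly$par)) out <- c(out, list(ly))
  }
  out
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in flatten_layers(layers)) {
    if (is.null(ly$adam)) {
      ly$adam <- list(m = lapply(ly$par, function(p) p * 0),
                      v = lapply(ly$par, function(p) p * 0))
    }
    for (nm in names(ly$par)) {
      g <- ly$grad[[nm]]
      if (is.null(g)) next
      ly$adam$m[[nm]] <- beta1 * ly$adam$m[[nm]] + (1 - beta1) * g
      ly$adam$v[[nm]] <- beta2 * ly$adam$v[[nm]] + (1 - beta2) * g * g
      mhat <- ly$adam$m[[nm]] / (1 - beta1^t)
      vhat <- ly$adam$v[[nm]] / (1 - beta2^t)
      ly$par[[nm]] <- ly$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

softmax_xent <- function(logits, y) {
  # logits: N x K; y: integer labels in 1..K
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
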