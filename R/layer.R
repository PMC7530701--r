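#' Trainable multi-channel INRF layer
#'
#' A drop-in replacement for a 2D convolutional layer in which each
#' output channel computes, per input channel,
#' \deqn{y = k * x - \lambda \sum_d k_d\, \sigma\big(x(\cdot + d) -
#'       x(\cdot)\big),}
#' i.e. the receptive-field model with `g` a delta function and the
#' linear and nonlinear kernels tied to one learnable weight tensor
#' `k`.  The operator is linear in `k`, so its weight gradient is a
#' plain correlation with the per-offset features.  Boundary handling
#' is zero padding, the convention of the convolutional layers it
#' replaces; `lambda` is a fixed hyperparameter, not learned.
#'
#' @param in_channels,out_channels Positive channel counts.
#' @param kernel_size Odd spatial extent of the shared kernel.
#' @param lambda Fixed nonlinear-term weight.
#' @param sigma A [sigma_spec()]; defaults to the asymmetric power
#'   nonlinearity of the vision experiments.
#' @param seed Seed for the weight initialization (scaled uniform).
#' @return List of class `"inrf_layer_spec"` with the weight array
#'   `weights` of dimension `(kernel_size, kernel_size, in_channels,
#'   out_channels)`.
#' @export
inrf_layer_spec <- function(in_channels, out_channels, kernel_size = 3,
                            lambda = 1.1,
                            sigma = sigma_spec("asymmetric_power",
                                               p = 0.625, q = 0.775),
                            seed = 1L) {
  if (kernel_size %% 2 == 0) stop("invalid layer spec: kernel_size must be odd")
  stopifnot(in_channels >= 1, out_channels >= 1)
  fan_in <- kernel_size^2 * in_channels
  weights <- with_local_seed(seed, {
    array(stats::runif(kernel_size^2 * in_channels * out_channels,
                       -1, 1) / sqrt(fan_in),
          dim = c(kernel_size, kernel_size, in_channels, out_channels))
  })
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 kernel_size = kernel_size, lambda = lambda, sigma = sigma,
                 weights = weights),
            class = "inrf_layer_spec")
}

# coerce input to an (H, W, C_in, N) array
as_layer_input <- function(x, in_channels) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 4L || dim(x)[3] != in_channels) {
    stop("input must be (H, W, in_channels, N)")
  }
  x
}

# per-offset features F_d = x(.+d) - lambda * sigma(x(.+d) - x(.)),
# zero-padded; returned as an (H, W, C, N, K^2) array
layer_features <- function(x, spec) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  r <- (spec$kernel_size - 1L) %/% 2L
  xpad <- array(0, dim = c(H + 2L * r, W + 2L * r, C, N))
  xpad[(r + 1L):(r + H), (r + 1L):(r + W), , ] <- x
  K <- spec$kernel_size
  F <- array(0, dim = c(H, W, C, N, K * K))
  for (b in seq_len(K)) {
    for (a in seq_len(K)) {
      s <- xpad[(a):(a + H - 1L), (b):(b + W - 1L), , , drop = FALSE]
      F[, , , , (b - 1L) * K + a] <-
        s - spec$lambda * eval_sigma(spec$sigma, s - x)
    }
  }
  F
}

#' Forward pass of the INRF layer
#'
#' @param x Input batch: an `(H, W, in_channels, N)` array (a bare
#'   matrix is treated as one single-channel sample); spatial extent
#'   must be at least the kernel size.
#' @param spec An [inrf_layer_spec()].
#' @return Output batch `(H, W, out_channels, N)`.
#' @export
inrf_layer_forward <- function(x, spec) {
  x <- as_layer_input(x, spec$in_channels)
  d <- dim(x)
  if (d[1] < spec$kernel_size || d[2] < spec$kernel_size) {
    stop("spatial extent smaller than the kernel")
  }
  F <- layer_features(x, spec)
  layer_forward_from_features(F, spec)
}

layer_forward_from_features <- function(F, spec) {
  d <- dim(F); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; K2 <- d[5]
  out <- array(0, dim = c(H, W, spec$out_channels, N))
  wmat <- array(spec$weights, dim = c(K2, C, spec$out_channels))
  # dims were (K, K, C, O); flattening the two spatial dims preserves
  # column-major offset order used by layer_features
  for (o in seq_len(spec$out_channels)) {
    acc <- array(0, dim = c(H, W, N))
    for (ci in seq_len(C)) {
      for (t in seq_len(K2)) {
        wk <- wmat[t, ci, o]
        if (wk == 0) next
        acc <- acc + wk * array(F[, , ci, , t], dim = c(H, W, N))
      }
    }
    out[, , o, ] <- acc
  }
  out
}

# gradient of a scalar loss w.r.t. the weights, given dL/d(out)
layer_weight_grad <- function(F, spec, dout) {
  d <- dim(F); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; K2 <- d[5]
  K <- spec$kernel_size
  gw <- array(0, dim = c(K, K, C, spec$out_channels))
  for (o in seq_len(spec$out_channels)) {
    dd <- array(dout[, , o, ], dim = c(H, W, N))
    for (ci in seq_len(C)) {
      for (t in seq_len(K2)) {
        gw[((t - 1L) %% K) + 1L, ((t - 1L) %/% K) + 1L, ci, o] <-
          sum(dd * array(F[, , ci, , t], dim = c(H, W, N)))
      }
    }
  }
  gw
}

#' Synthetic two-class image set: blobs versus bars
#'
#' Seeded generator for the training demo: class 0 images contain a
#' soft circular blob at a random position, class 1 images an oriented
#' bar; both carry additive Gaussian pixel noise and live on `size x
#' size` grids in `[0, 1]`.
#'
#' @param n_per_class Images per class.
#' @param size Image side length.
#' @param noise_sd Pixel noise standard deviation.
#' @param seed Integer seed.
#' @return List with `x` (`(size, size, 1, 2 n)` array) and `y`
#'   (0/1 labels).
#' @export
make_blob_bar_dataset <- function(n_per_class = 200, size = 8,
                                  noise_sd = 0.08, seed = 1L) {
  with_local_seed(seed, {
    n <- 2L * n_per_class
    x <- array(0, dim = c(size, size, 1L, n))
    y <- rep(c(0L, 1L), each = n_per_class)
    ax <- seq_len(size)
    for (i in seq_len(n)) {
      if (y[i] == 0L) {
        cx <- stats::runif(1, 3, size - 2); cy <- stats::runif(1, 3, size - 2)
        img <- exp(-(outer((ax - cy)^2, (ax - cx)^2, `+`)) / (2 * 1.2^2))
      } else {
        theta <- stats::runif(1, 0, pi)
        off <- stats::runif(1, -1, 1)
        dist <- outer(ax - size / 2, ax - size / 2,
                      function(r, c) r * cos(theta) + c * sin(theta)) - off
        img <- exp(-dist^2 / (2 * 0.9^2))
      }
      x[, , 1L, i] <- pmin(pmax(img + stats::rnorm(size^2, 0, noise_sd), 0), 1)
    }
    list(x = x, y = y)
  })
}

#' Train a small INRF-layer classifier on synthetic data
#'
#' Desk-scale training demo: one INRF layer, global average pooling and
#' a logistic head, trained with Adam on the blobs-versus-bars set from
#' [make_blob_bar_dataset()].  All gradients are computed analytically
#' (the layer is linear in its weights).
#'
#' @param n_per_class Images per class.
#' @param epochs Full-batch training epochs.
#' @param out_channels Layer width.
#' @param lambda Layer nonlinear-term weight.
#' @param lr Adam learning rate.
#' @param seed Seed for data and initialization.
#' @return List with `error_trace` (training error per epoch),
#'   `final_train_error`, `loss_trace` and the trained `spec`/head.
#' @export
train_demo <- function(n_per_class = 200, epochs = 20, out_channels = 4,
                       lambda = 1.1, lr = 0.05, seed = 1L) {
  data <- make_blob_bar_dataset(n_per_class, seed = derive_seed(seed, 1))
  x <- data$x; y <- data$y
  spec <- inrf_layer_spec(1L, out_channels, kernel_size = 3L,
                          lambda = lambda, seed = derive_seed(seed, 2))
  F <- layer_features(x, spec) # input is fixed: features precomputable
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  # small random head so the layer weights receive gradient from epoch 1
  Whead <- with_local_seed(derive_seed(seed, 3),
                           stats::rnorm(out_channels, 0, 0.5))
  bhead <- 0
  params <- list(k = spec$weights, W = Whead, b = bhead)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  err_trace <- loss_trace <- numeric(epochs)
  bn_eps <- 1e-6
  for (ep in seq_len(epochs)) {
    spec$weights <- params$k
    out <- layer_forward_from_features(F, spec)
    feat <- apply(out, c(3, 4), mean) # (out_channels, N)
    # batch-normalize pooled features (as in the networks the layer
    # replaces a convolution in); removes the common-mode intensity
    # offset that otherwise dominates the logistic head
    mu <- rowMeans(feat)
    sdv <- sqrt(apply(feat, 1, stats::var) * (N - 1) / N + bn_eps)
    fhat <- (feat - mu) / sdv
    z <- as.numeric(crossprod(fhat, params$W)) + params$b
    p <- stats::plogis(z)
    loss <- -mean(y * log(pmax(p, 1e-12)) +
                    (1 - y) * log(pmax(1 - p, 1e-12)))
    err <- mean((p > 0.5) != (y == 1L))
    loss_trace[ep] <- loss; err_trace[ep] <- err
    dz <- (p - y) / N
    gW <- as.numeric(fhat %*% dz)
    gb <- sum(dz)
    dfhat <- outer(params$W, dz) # (out_channels, N)
    # batch-norm backward
    dfeat <- (dfhat - rowMeans(dfhat) -
                fhat * rowMeans(dfhat * fhat)) / sdv
    dout <- array(0, dim = dim(out))
    for (o in seq_len(out_channels)) {
      dout[, , o, ] <- rep(dfeat[o, ], each = H * W) / (H * W)
    }
    gk <- layer_weight_grad(F, spec, dout)
    grads <- list(k = gk, W = gW, b = gb)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^ep)
      vhat <- vel[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  spec$weights <- params$k
  list(error_trace = err_trace, loss_trace = loss_trace,
       final_train_error = err_trace[epochs], spec = spec,
       head = list(W = params$W, b = params$b))
}
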