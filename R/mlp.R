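## Minimal fully-connected regressor: ReLU mid-layers, linear scalar
## output, inverted dropout, Adam on mini-batch MSE. Implemented on BLAS
## matrix ops; deterministic for a fixed seed on fixed hardware.

#' Fit a multi-layer perceptron regressor
#'
#' Trains a fully-connected network with ReLU mid-layers and a linear
#' single-unit output by mini-batch stochastic gradient descent (Adam)
#' on mean-squared error. Inputs and the target are standardized
#' internally (training-set mean/SD, stored in the model and reapplied
#' at prediction). Dropout is the inverted variant, applied to
#' mid-layer activations during training only.
#'
#' @param x Numeric feature matrix, one row per sample.
#' @param y Numeric target vector.
#' @param layers Integer vector of mid-layer widths, e.g. `c(64, 64, 64)`
#'   for 3 mid-layers of 64 units.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size (clipped to `nrow(x)`).
#' @param learn_rate Adam step size.
#' @param seed Optional integer seed (initialization, shuffling, dropout).
#' @return An object of class `xq_mlp`.
#' @export
mlp_fit <- function(x, y, layers = c(64, 64, 64), dropout = 0,
                    epochs = 50, batch_size = 1000, learn_rate = 1e-3,
                    seed = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(layers >= 1), epochs >= 1,
            dropout >= 0, dropout < 1)
  n <- nrow(x)
  p <- ncol(x)
  batch_size <- min(batch_size, n)

  x_mu <- colMeans(x)
  x_sd <- pmax(apply(x, 2L, sd), 1e-12)
  y_mu <- mean(y)
  y_sd <- max(sd(y), 1e-12)
  xs <- sweep(sweep(x, 2L, x_mu), 2L, x_sd, "/")
  ys <- (y - y_mu) / y_sd

  dims <- c(p, layers, 1L)
  nl <- length(dims) - 1L

  .with_seed(seed, {
    W <- vector("list", nl)
    b <- vector("list", nl)
    for (l in seq_len(nl)) {
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L

    n_batch <- ceiling(n / batch_size)
    A <- vector("list", nl + 1L)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (bi in seq_len(n_batch)) {
        idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
        nb <- length(idx)
        A[[1L]] <- xs[idx, , drop = FALSE]
        drop_masks <- vector("list", nl - 1L)
        for (l in seq_len(nl)) {
          Z <- A[[l]] %*% W[[l]]
          Z <- sweep(Z, 2L, b[[l]], "+")
          if (l < nl) {
            Z[Z < 0] <- 0
            if (dropout > 0) {
              msk <- matrix((runif(length(Z)) >= dropout) / (1 - dropout),
                            nrow(Z), ncol(Z))
              Z <- Z * msk
              drop_masks[[l]] <- msk
            }
          }
          A[[l + 1L]] <- Z
        }
        delta <- 2 * (A[[nl + 1L]] - ys[idx]) / nb   # dLoss/dOut, column
        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (l in nl:1) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            if (dropout > 0) delta <- delta * drop_masks[[l - 1L]]
            delta[A[[l]] <= 0] <- 0
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          W[[l]] <- W[[l]] - learn_rate * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          b[[l]] <- b[[l]] - learn_rate * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }

    structure(
      list(W = W, b = b, dims = dims,
           x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd,
           config = list(layers = layers, dropout = dropout, epochs = epochs,
                         batch_size = batch_size, learn_rate = learn_rate,
                         seed = seed, optimizer = "adam", loss = "mse")),
      class = "xq_mlp"
    )
  })
}

#' @param object An `xq_mlp`.
#' @param newdata Feature matrix with the training column count.
#' @param ... Unused.
#' @return `predict()`: numeric vector of predictions in target units.
#' @rdname mlp_fit
#' @export
predict.xq_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$dims[1L])
    stop(sprintf("expected %d features, got %d", object$dims[1L], ncol(x)),
         call. = FALSE)
  out <- numeric(nrow(x))
  nl <- length(object$W)
  chunk <- 65536L
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    A <- sweep(sweep(x[idx, , drop = FALSE], 2L, object$x_mu), 2L,
               object$x_sd, "/")
    for (l in seq_len(nl)) {
      A <- sweep(A %*% object$W[[l]], 2L, object$b[[l]], "+")
      if (l < nl) A[A < 0] <- 0
    }
    out[idx] <- A[, 1L]
  }
  out * object$y_sd + object$y_mu
}

#' @param model An `xq_mlp` (or `xq_regressor`).
#' @return `n_weights()`: total count of trainable weights and biases.
#' @rdname mlp_fit
#' @export
n_weights <- function(model) {
  if (inherits(model, "xq_regressor")) model <- model$mlp
  stopifnot(inherits(model, "xq_mlp"))
  sum(vapply(model$W, length, 1L)) + sum(vapply(model$b, length, 1L))
}

#' @export
print.xq_mlp <- function(x, ...) {
  cat(sprintf("<xq_mlp> %s (%d weights), dropout %g, %d epochs, batch %d\n",
              paste(x$dims, collapse = "-"), n_weights(x),
              x$config$dropout, x$config$epochs, x$config$batch_size))
  invisible(x)
}
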