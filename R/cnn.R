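# 1-D convolutional classifier. The ordered feature vector (clonotype
# frequencies in vocabulary-rank order) is treated as a one-dimensional
# signal; stacked valid-mode convolution + ReLU layers feed a global pooling
# step, dropout, and a dense sigmoid readout.

.conv_patches <- function(signal, k) {
  # signal: L x C -> patches: (L - k + 1) x (k * C)
  L_out <- nrow(signal) - k + 1
  do.call(cbind, lapply(seq_len(k), function(o)
    signal[o:(o + L_out - 1), , drop = FALSE]))
}

.conv_forward <- function(signal, W, b, k) {
  P <- .conv_patches(signal, k)
  Z <- sweep(P %*% W, 2, b, "+")
  list(P = P, Z = Z, H = pmax(Z, 0))
}

# scatter patch gradient back to the input signal
.conv_backward_input <- function(dP, L, C, k) {
  dS <- matrix(0, L, C)
  L_out <- L - k + 1
  for (o in seq_len(k)) {
    cols <- ((o - 1) * C + 1):(o * C)
    rows <- o:(o + L_out - 1)
    dS[rows, ] <- dS[rows, ] + dP[, cols, drop = FALSE]
  }
  dS
}

#' Fit a 1-D convolutional network binary classifier
#'
#' @param X numeric matrix (samples x features); columns are read as an
#'   ordered 1-D signal over vocabulary rank.
#' @param y binary 0/1 labels.
#' @param conv_layers number of convolution + ReLU layers (1 or 2).
#' @param filters filters per convolution layer.
#' @param kernel_size convolution kernel width.
#' @param pooling `"max"` or `"mean"` global pooling over positions.
#' @param dropout dropout probability before the dense readout.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size,seed training controls.
#' @return object of class `tcrdx_cnn` for [nn_predict()].
#' @export
fit_cnn <- function(X, y, conv_layers = 1, filters = 8, kernel_size = 5,
                    pooling = c("max", "mean"), dropout = 0.2,
                    learning_rate = 1e-3, epochs = 30, batch_size = 32,
                    seed = 1) {
  pooling <- match.arg(pooling)
  stopifnot(conv_layers %in% c(1, 2))
  X <- as.matrix(X); y <- as.numeric(y)
  m <- ncol(X); k <- kernel_size
  stopifnot(m >= conv_layers * (k - 1) + 1)
  chans <- c(1, rep(filters, conv_layers))
  with_seed(seed, {
    params <- list()
    for (l in seq_len(conv_layers)) {
      params[[paste0("Wc", l)]] <- .glorot(k * chans[l], chans[l + 1])
      params[[paste0("bc", l)]] <- rep(0, chans[l + 1])
    }
    params$Wd <- .glorot(filters, 1)
    params$bd <- 0
    st <- .adam_init(params)
    for (ep in seq_len(epochs)) {
      for (batch in .minibatches(nrow(X), batch_size)) {
        grads <- lapply(params, function(p) p * 0)
        loss_grad_scale <- 1 / length(batch)
        for (i in batch) {
          sig <- matrix(X[i, ], ncol = 1)
          caches <- vector("list", conv_layers)
          s <- sig
          for (l in seq_len(conv_layers)) {
            cc <- .conv_forward(s, params[[paste0("Wc", l)]],
                                params[[paste0("bc", l)]], k)
            caches[[l]] <- c(cc, list(input = s))
            s <- cc$H
          }
          pool_idx <- if (pooling == "max") apply(s, 2, which.max) else NULL
          u <- if (pooling == "max") apply(s, 2, max) else colMeans(s)
          if (dropout > 0) {
            mask <- (stats::runif(length(u)) >= dropout) / (1 - dropout)
            u_d <- u * mask
          } else u_d <- u
          z <- sum(u_d * params$Wd) + params$bd
          p <- .sigmoid(z)
          dz <- (p - y[i]) * loss_grad_scale
          grads$Wd <- grads$Wd + dz * matrix(u_d, ncol = 1)
          grads$bd <- grads$bd + dz
          du <- dz * drop(params$Wd)
          if (dropout > 0) du <- du * mask
          # unpool
          dH <- matrix(0, nrow(s), ncol(s))
          if (pooling == "max") {
            dH[cbind(pool_idx, seq_len(ncol(s)))] <- du
          } else dH <- matrix(rep(du / nrow(s), each = nrow(s)),
                              nrow(s), ncol(s))
          for (l in rev(seq_len(conv_layers))) {
            cc <- caches[[l]]
            dZ <- dH * (cc$Z > 0)
            grads[[paste0("Wc", l)]] <- grads[[paste0("Wc", l)]] +
              t(cc$P) %*% dZ
            grads[[paste0("bc", l)]] <- grads[[paste0("bc", l)]] + colSums(dZ)
            if (l > 1) {
              dP <- dZ %*% t(params[[paste0("Wc", l)]])
              dH <- .conv_backward_input(dP, nrow(cc$input), ncol(cc$input), k)
            }
          }
        }
        upd <- .adam_step(params, grads, st, learning_rate)
        params <- upd$params; st <- upd$state
      }
    }
    structure(list(params = params, conv_layers = conv_layers,
                   kernel_size = k, pooling = pooling),
              class = "tcrdx_cnn")
  })
}

#' @export
nn_predict.tcrdx_cnn <- function(model, X) {
  X <- as.matrix(X)
  vapply(seq_len(nrow(X)), function(i) {
    s <- matrix(X[i, ], ncol = 1)
    for (l in seq_len(model$conv_layers)) {
      s <- .conv_forward(s, model$params[[paste0("Wc", l)]],
                         model$params[[paste0("bc", l)]],
                         model$kernel_size)$H
    }
    u <- if (model$pooling == "max") apply(s, 2, max) else colMeans(s)
    .sigmoid(sum(u * drop(model$params$Wd)) + model$params$bd)
  }, numeric(1))
}
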