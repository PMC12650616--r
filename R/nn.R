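# Minimal neural-network engine used by the MLP, CNN and Transformer
# classifier families: Glorot initialization, Adam, binary cross-entropy.
# Everything is plain matrix algebra with hand-derived gradients; all
# stochasticity (init, minibatch order, dropout) is seeded.

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# ---- multilayer perceptron -------------------------------------------------

#' Fit a multilayer perceptron binary classifier
#'
#' Fully connected ReLU network with inverted dropout, sigmoid output and
#' binary cross-entropy loss, trained by minibatch Adam. Inputs are expected
#' standardized (the model wrapper handles that).
#'
#' @param X numeric matrix (samples x features).
#' @param y binary 0/1 labels.
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param dropout dropout probability on hidden activations.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed seed for init, batching and dropout.
#' @return object of class `tcrdx_mlp` with `predict_proba` applicable via
#'   [nn_predict()].
#' @export
fit_mlp <- function(X, y, hidden_sizes = c(32), dropout = 0.2,
                    learning_rate = 1e-3, epochs = 30, batch_size = 32,
                    seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  sizes <- c(ncol(X), hidden_sizes, 1L)
  with_seed(seed, {
    params <- list()
    for (l in seq_len(length(sizes) - 1)) {
      params[[paste0("W", l)]] <- .glorot(sizes[l], sizes[l + 1])
      params[[paste0("b", l)]] <- rep(0, sizes[l + 1])
    }
    st <- .adam_init(params)
    n_layers <- length(sizes) - 1
    for (ep in seq_len(epochs)) {
      for (batch in .minibatches(nrow(X), batch_size)) {
        Xb <- X[batch, , drop = FALSE]; yb <- y[batch]
        acts <- list(Xb); masks <- list()
        H <- Xb
        for (l in seq_len(n_layers - 1)) {
          Z <- sweep(H %*% params[[paste0("W", l)]], 2,
                     params[[paste0("b", l)]], "+")
          H <- pmax(Z, 0)
          if (dropout > 0) {
            mask <- matrix(stats::runif(length(H)) >= dropout,
                           nrow(H), ncol(H)) / (1 - dropout)
            H <- H * mask
            masks[[l]] <- mask
          }
          acts[[l + 1]] <- H
        }
        z <- drop(H %*% params[[paste0("W", n_layers)]]) +
             params[[paste0("b", n_layers)]]
        p <- .sigmoid(z)
        dz <- matrix((p - yb) / length(yb), ncol = 1)
        grads <- list()
        grads[[paste0("W", n_layers)]] <- t(acts[[n_layers]]) %*% dz
        grads[[paste0("b", n_layers)]] <- sum(dz)
        dH <- dz %*% t(params[[paste0("W", n_layers)]])
        for (l in rev(seq_len(n_layers - 1))) {
          if (dropout > 0) dH <- dH * masks[[l]]
          dZ <- dH * (acts[[l + 1]] > 0)
          grads[[paste0("W", l)]] <- t(acts[[l]]) %*% dZ
          grads[[paste0("b", l)]] <- colSums(dZ)
          if (l > 1) dH <- dZ %*% t(params[[paste0("W", l)]])
        }
        upd <- .adam_step(params, grads, st, learning_rate)
        params <- upd$params; st <- upd$state
      }
    }
    structure(list(params = params, n_layers = n_layers), class = "tcrdx_mlp")
  })
}

#' Predict class-1 probabilities from a fitted network
#'
#' Deterministic evaluation-mode forward pass (no dropout) for any of the
#' package's network classifiers.
#'
#' @param model a `tcrdx_mlp`, `tcrdx_cnn` or `tcrdx_transformer`.
#' @param X numeric matrix (samples x features).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
nn_predict <- function(model, X) UseMethod("nn_predict")

#' @export
nn_predict.tcrdx_mlp <- function(model, X) {
  H <- as.matrix(X)
  for (l in seq_len(model$n_layers - 1)) {
    H <- pmax(sweep(H %*% model$params[[paste0("W", l)]], 2,
                    model$params[[paste0("b", l)]], "+"), 0)
  }
  z <- drop(H %*% model$params[[paste0("W", model$n_layers)]]) +
       model$params[[paste0("b", model$n_layers)]]
  .sigmoid(z)
}
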