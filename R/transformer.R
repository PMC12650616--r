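# Self-attention (Transformer encoder) classifier over clonotype features.
#
# Tokenization: each of the m selected clonotypes is one token. Token j's
# input representation is a learned identity embedding E[j, ] plus the
# sample's (standardized) frequency for clonotype j passed through a learned
# value-projection vector:  T_j = E[j, ] + x_j * w_val.  The token sequence
# runs through num_layers post-norm encoder layers (multi-head scaled
# dot-product self-attention + position-wise ReLU feed-forward, residual
# connections, layer normalization), is mean-pooled, and a dense sigmoid
# readout yields the class-1 probability.

.LN_EPS <- 1e-5

.layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  r1 <- rowMeans(dxhat)
  r2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - r1 - cache$xhat * r2) * cache$inv
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

.softmax_rows <- function(S) {
  S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S)
  E / rowSums(E)
}

#' Initialize a Transformer encoder classifier
#'
#' @param m number of input features (tokens); fixed at build time.
#' @param d_model embedding width; must be divisible by `nhead`.
#' @param nhead number of attention heads.
#' @param num_layers number of encoder layers.
#' @param dropout dropout probability (applied after attention and
#'   feed-forward sublayers during training only).
#' @param seed initialization seed.
#' @return an untrained `tcrdx_transformer`.
#' @export
transformer_init <- function(m, d_model = 8, nhead = 2, num_layers = 1,
                             dropout = 0.1, seed = 1) {
  if (d_model %% nhead != 0)
    stop("d_model (", d_model, ") must be divisible by nhead (", nhead, ")",
         call. = FALSE)
  dff <- 4 * d_model
  with_seed(seed, {
    params <- list(E = .glorot(m, d_model) * 0.5,
                   w_val = stats::rnorm(d_model, 0, 0.5),
                   w_out = stats::rnorm(d_model, 0, 0.1), b_out = 0)
    for (l in seq_len(num_layers)) {
      pre <- paste0("L", l, "_")
      params[[paste0(pre, "Wq")]] <- .glorot(d_model, d_model)
      params[[paste0(pre, "Wk")]] <- .glorot(d_model, d_model)
      params[[paste0(pre, "Wv")]] <- .glorot(d_model, d_model)
      params[[paste0(pre, "Wo")]] <- .glorot(d_model, d_model)
      params[[paste0(pre, "g1")]] <- rep(1, d_model)
      params[[paste0(pre, "b1")]] <- rep(0, d_model)
      params[[paste0(pre, "W1")]] <- .glorot(d_model, dff)
      params[[paste0(pre, "bf1")]] <- rep(0, dff)
      params[[paste0(pre, "W2")]] <- .glorot(dff, d_model)
      params[[paste0(pre, "bf2")]] <- rep(0, d_model)
      params[[paste0(pre, "g2")]] <- rep(1, d_model)
      params[[paste0(pre, "b2")]] <- rep(0, d_model)
    }
    structure(list(params = params, m = m, d_model = d_model, nhead = nhead,
                   num_layers = num_layers, dropout = dropout),
              class = "tcrdx_transformer")
  })
}

# forward pass for one sample; returns caches when training
.tf_forward_one <- function(model, x, training = FALSE, keep_cache = FALSE) {
  p <- model$params
  d <- model$d_model; nh <- model$nhead; dh <- d / nh
  drop_p <- if (training) model$dropout else 0
  Xt <- p$E + outer(x, p$w_val)
  caches <- vector("list", model$num_layers)
  for (l in seq_len(model$num_layers)) {
    pre <- paste0("L", l, "_")
    Q <- Xt %*% p[[paste0(pre, "Wq")]]
    K <- Xt %*% p[[paste0(pre, "Wk")]]
    V <- Xt %*% p[[paste0(pre, "Wv")]]
    heads <- vector("list", nh)
    Concat <- matrix(0, model$m, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      A <- .softmax_rows(S)
      Oh <- A %*% V[, cols, drop = FALSE]
      Concat[, cols] <- Oh
      if (keep_cache) heads[[h]] <- list(A = A)
    }
    O <- Concat %*% p[[paste0(pre, "Wo")]]
    if (drop_p > 0) {
      D1 <- matrix(stats::runif(length(O)) >= drop_p, nrow(O), ncol(O)) /
        (1 - drop_p)
      O <- O * D1
    } else D1 <- NULL
    R1 <- Xt + O
    ln1 <- .layernorm_fwd(R1, p[[paste0(pre, "g1")]], p[[paste0(pre, "b1")]])
    N1 <- ln1$out
    Z1 <- sweep(N1 %*% p[[paste0(pre, "W1")]], 2, p[[paste0(pre, "bf1")]], "+")
    F1 <- pmax(Z1, 0)
    F2 <- sweep(F1 %*% p[[paste0(pre, "W2")]], 2, p[[paste0(pre, "bf2")]], "+")
    if (drop_p > 0) {
      D2 <- matrix(stats::runif(length(F2)) >= drop_p, nrow(F2), ncol(F2)) /
        (1 - drop_p)
      F2 <- F2 * D2
    } else D2 <- NULL
    R2 <- N1 + F2
    ln2 <- .layernorm_fwd(R2, p[[paste0(pre, "g2")]], p[[paste0(pre, "b2")]])
    if (keep_cache)
      caches[[l]] <- list(Xt = Xt, Q = Q, K = K, V = V, Concat = Concat,
                          heads = heads, D1 = D1, ln1 = ln1, N1 = N1,
                          Z1 = Z1, F1 = F1, D2 = D2, ln2 = ln2)
    Xt <- ln2$out
  }
  u <- colMeans(Xt)
  z <- sum(u * p$w_out) + p$b_out
  list(prob = .sigmoid(z), u = u, caches = caches, final = Xt)
}

# backward pass for one sample; returns gradient list aligned with params
.tf_backward_one <- function(model, x, fwd, y, scale) {
  p <- model$params
  d <- model$d_model; nh <- model$nhead; dh <- d / nh; m <- model$m
  grads <- list()
  dz <- (fwd$prob - y) * scale
  grads$w_out <- dz * fwd$u
  grads$b_out <- dz
  du <- dz * p$w_out
  dXt <- matrix(rep(du / m, each = m), m, d)
  for (l in rev(seq_len(model$num_layers))) {
    pre <- paste0("L", l, "_")
    cc <- fwd$caches[[l]]
    ln2b <- .layernorm_bwd(dXt, cc$ln2, p[[paste0(pre, "g2")]])
    grads[[paste0(pre, "g2")]] <- ln2b$dg
    grads[[paste0(pre, "b2")]] <- ln2b$db
    dR2 <- ln2b$dX
    dN1 <- dR2
    dF2 <- if (!is.null(cc$D2)) dR2 * cc$D2 else dR2
    grads[[paste0(pre, "W2")]] <- t(cc$F1) %*% dF2
    grads[[paste0(pre, "bf2")]] <- colSums(dF2)
    dF1 <- dF2 %*% t(p[[paste0(pre, "W2")]])
    dZ1 <- dF1 * (cc$Z1 > 0)
    grads[[paste0(pre, "W1")]] <- t(cc$N1) %*% dZ1
    grads[[paste0(pre, "bf1")]] <- colSums(dZ1)
    dN1 <- dN1 + dZ1 %*% t(p[[paste0(pre, "W1")]])
    ln1b <- .layernorm_bwd(dN1, cc$ln1, p[[paste0(pre, "g1")]])
    grads[[paste0(pre, "g1")]] <- ln1b$dg
    grads[[paste0(pre, "b1")]] <- ln1b$db
    dR1 <- ln1b$dX
    dXt_res <- dR1
    dO <- if (!is.null(cc$D1)) dR1 * cc$D1 else dR1
    grads[[paste0(pre, "Wo")]] <- t(cc$Concat) %*% dO
    dConcat <- dO %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, m, d); dK <- matrix(0, m, d); dV <- matrix(0, m, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- cc$heads[[h]]$A
      dOh <- dConcat[, cols, drop = FALSE]
      dA <- dOh %*% t(cc$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dOh
      dS <- (dA - rowSums(dA * A)) * A / sqrt(dh)
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- t(dS) %*% cc$Q[, cols, drop = FALSE]
    }
    grads[[paste0(pre, "Wq")]] <- t(cc$Xt) %*% dQ
    grads[[paste0(pre, "Wk")]] <- t(cc$Xt) %*% dK
    grads[[paste0(pre, "Wv")]] <- t(cc$Xt) %*% dV
    dXt <- dXt_res + dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
  }
  grads$E <- dXt
  grads$w_val <- drop(t(dXt) %*% x)
  grads
}

#' Transformer forward pass on a batch of feature vectors
#'
#' Evaluation-mode (no dropout) scoring of each row of `X`; rows are scored
#' independently, so batch order and composition cannot affect a sample's
#' score.
#'
#' @param model a `tcrdx_transformer` (trained or freshly initialized).
#' @param X numeric matrix (samples x features); feature count must equal
#'   the model's `m`.
#' @return numeric vector of class-1 probabilities.
#' @export
transformer_forward <- function(model, X) {
  stopifnot(inherits(model, "tcrdx_transformer"))
  X <- as.matrix(X)
  if (ncol(X) != model$m)
    stop("feature count (", ncol(X), ") does not match model tokens (",
         model$m, ")", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite values in input", call. = FALSE)
  vapply(seq_len(nrow(X)),
         function(i) .tf_forward_one(model, X[i, ])$prob, numeric(1))
}

#' @export
nn_predict.tcrdx_transformer <- function(model, X) transformer_forward(model, X)

#' Train a Transformer encoder classifier
#'
#' @param X numeric matrix (samples x features), standardized upstream.
#' @param y binary 0/1 labels.
#' @param d_model,nhead,num_layers,dropout architecture; see
#'   [transformer_init()].
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size,seed training controls.
#' @return a trained `tcrdx_transformer`.
#' @export
fit_transformer <- function(X, y, d_model = 8, nhead = 2, num_layers = 1,
                            dropout = 0.1, learning_rate = 5e-3,
                            epochs = 30, batch_size = 32, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  model <- transformer_init(ncol(X), d_model, nhead, num_layers, dropout,
                            seed = derive_seed(seed, "init"))
  st <- .adam_init(model$params)
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      for (batch in .minibatches(nrow(X), batch_size)) {
        grads <- NULL
        scale <- 1 / length(batch)
        for (i in batch) {
          fwd <- .tf_forward_one(model, X[i, ], training = TRUE,
                                 keep_cache = TRUE)
          g <- .tf_backward_one(model, X[i, ], fwd, y[i], scale)
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads[names(g)], g)
        }
        grads <- grads[names(model$params)]
        upd <- .adam_step(model$params, grads, st, learning_rate)
        model$params <- upd$params; st <- upd$state
      }
    }
  })
  model
}
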