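# Minimal neural-network primitives: dense layers, layer/batch normalization,
# masked multi-head self-attention, Adam. Forward passes return caches that
# the matching *_backward functions consume; gradients are verified against
# finite differences in the test suite.

rand_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

# two-layer scalar MLP: Linear -> tanh -> Linear  (value and time embedders)
mlp2_forward <- function(x, W1, b1, W2, b2) {
  # x: n-vector of scalars; W1: 1 x d; W2: d x d
  Z <- outer(x, W1[1, ]) + matrix(b1, length(x), length(b1), byrow = TRUE)
  A <- tanh(Z)
  Y <- A %*% W2 + matrix(b2, length(x), length(b2), byrow = TRUE)
  list(Y = Y, cache = list(x = x, A = A, W1 = W1, W2 = W2))
}

mlp2_backward <- function(dY, cache) {
  A <- cache$A
  dW2 <- crossprod(A, dY)
  db2 <- colSums(dY)
  dA <- dY %*% t(cache$W2)
  dZ <- dA * (1 - A^2)
  dW1 <- matrix(colSums(dZ * cache$x), 1)
  db1 <- colSums(dZ)
  dx <- as.numeric(dZ %*% t(cache$W1))
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

linear_forward <- function(X, W, b) {
  list(Y = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE),
       cache = list(X = X, W = W))
}

linear_backward <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  inv <- 1 / sqrt(v + eps)
  Xn <- Xc * inv
  Y <- sweep(Xn, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, cache = list(Xn = Xn, inv = inv, g = g))
}

ln_backward <- function(dY, cache) {
  Xn <- cache$Xn; inv <- cache$inv; d <- ncol(dY)
  dg <- colSums(dY * Xn)
  db <- colSums(dY)
  dXn <- sweep(dY, 2, cache$g, `*`)
  # per-row: dX = inv/d * (d*dXn - sum(dXn) - Xn * sum(dXn*Xn))
  s1 <- rowSums(dXn)
  s2 <- rowSums(dXn * Xn)
  dX <- (dXn * d - s1 - Xn * s2) * (inv / d)
  list(dX = dX, dg = dg, db = db)
}

bn_forward <- function(X, g, b, state, training = TRUE, momentum = 0.1,
                       eps = 1e-5) {
  if (training && nrow(X) > 1) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var  <- (1 - momentum) * state$var +
      momentum * v * nrow(X) / max(1, nrow(X) - 1)
  } else {
    mu <- state$mean; v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  Xn <- sweep(sweep(X, 2, mu), 2, inv, `*`)
  Y <- sweep(sweep(Xn, 2, g, `*`), 2, b, `+`)
  list(Y = Y, state = state,
       cache = list(Xn = Xn, inv = inv, g = g, training = training && nrow(X) > 1))
}

bn_backward <- function(dY, cache) {
  Xn <- cache$Xn; n <- nrow(dY)
  dg <- colSums(dY * Xn)
  db <- colSums(dY)
  dXn <- sweep(dY, 2, cache$g, `*`)
  if (cache$training) {
    s1 <- colSums(dXn); s2 <- colSums(dXn * Xn)
    dX <- sweep(dXn * n, 2, s1) - sweep(Xn, 2, s2, `*`)
    dX <- sweep(dX, 2, cache$inv / n, `*`)
  } else {
    dX <- sweep(dXn, 2, cache$inv, `*`)
  }
  list(dX = dX, dg = dg, db = db)
}

# masked multi-head self-attention over a flat token matrix X (T x d) whose
# rows belong to windows given by win_id. Tokens attend only within their own
# window; per-window blocks are small (tens of tokens), so looping windows
# with small dense ops beats materializing the T x T score matrix. No
# positional encoding: token order within a window carries no information.
attn_forward <- function(X, win_id, p, heads) {
  d <- ncol(X); dh <- d / heads
  Q <- X %*% p$Wq + matrix(p$bq, nrow(X), d, byrow = TRUE)
  K <- X %*% p$Wk + matrix(p$bk, nrow(X), d, byrow = TRUE)
  V <- X %*% p$Wv + matrix(p$bv, nrow(X), d, byrow = TRUE)
  Z <- matrix(0, nrow(X), d)
  runs <- split(seq_len(nrow(X)), win_id)
  caches <- vector("list", length(runs) * heads)
  ci <- 0L
  for (r in runs) {
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      q <- Q[r, cols, drop = FALSE]; k <- K[r, cols, drop = FALSE]
      v <- V[r, cols, drop = FALSE]
      S <- tcrossprod(q, k) / sqrt(dh)
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      Z[r, cols] <- A %*% v
      ci <- ci + 1L
      caches[[ci]] <- list(r = r, cols = cols, A = A, q = q, k = k, v = v)
    }
  }
  out <- linear_forward(Z, p$Wo, p$bo)
  list(Y = out$Y, cache = list(X = X, heads = heads, dh = dh, p = p,
                               att = caches, lin = out$cache))
}

attn_backward <- function(dY, cache) {
  p <- cache$p; dh <- cache$dh
  lb <- linear_backward(dY, cache$lin)
  dZ <- lb$dX
  dQ <- matrix(0, nrow(dZ), ncol(dZ))
  dK <- dQ; dV <- dQ
  for (cc in cache$att) {
    r <- cc$r; cols <- cc$cols; A <- cc$A
    dZh <- dZ[r, cols, drop = FALSE]
    dA <- tcrossprod(dZh, cc$v)             # dZh %*% t(v)
    dV[r, cols] <- dV[r, cols] + crossprod(A, dZh)
    dS <- A * (dA - rowSums(dA * A))        # softmax backward, row-wise
    dS <- dS / sqrt(dh)
    dQ[r, cols] <- dQ[r, cols] + dS %*% cc$k
    dK[r, cols] <- dK[r, cols] + crossprod(dS, cc$q)
  }
  X <- cache$X
  list(dX = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = crossprod(X, dQ), dbq = colSums(dQ),
       dWk = crossprod(X, dK), dbk = colSums(dK),
       dWv = crossprod(X, dV), dbv = colSums(dV),
       dWo = lb$dW, dbo = lb$db)
}

# one post-norm transformer encoder layer
encoder_layer_forward <- function(X, win_id, p, heads) {
  at <- attn_forward(X, win_id, p, heads)
  r1 <- X + at$Y
  l1 <- ln_forward(r1, p$ln1_g, p$ln1_b)
  f1 <- linear_forward(l1$Y, p$ffW1, p$ffb1)
  H <- pmax(f1$Y, 0)
  f2 <- linear_forward(H, p$ffW2, p$ffb2)
  r2 <- l1$Y + f2$Y
  l2 <- ln_forward(r2, p$ln2_g, p$ln2_b)
  list(Y = l2$Y, cache = list(at = at$cache, l1 = l1$cache, f1 = f1$cache,
                              H = H, f2 = f2$cache, l2 = l2$cache))
}

encoder_layer_backward <- function(dY, cache) {
  g <- list()
  b2 <- ln_backward(dY, cache$l2)
  g$ln2_g <- b2$dg; g$ln2_b <- b2$db
  dr2 <- b2$dX
  f2b <- linear_backward(dr2, cache$f2)
  g$ffW2 <- f2b$dW; g$ffb2 <- f2b$db
  dH <- f2b$dX * (cache$H > 0)
  f1b <- linear_backward(dH, cache$f1)
  g$ffW1 <- f1b$dW; g$ffb1 <- f1b$db
  dl1 <- dr2 + f1b$dX
  b1 <- ln_backward(dl1, cache$l1)
  g$ln1_g <- b1$dg; g$ln1_b <- b1$db
  dr1 <- b1$dX
  ab <- attn_backward(dr1, cache$at)
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
    g[[nm]] <- ab[[paste0("d", nm)]]
  list(dX = dr1 + ab$dX, grads = g)
}

# masked mean pooling: average token rows per window
pool_forward <- function(X, win_id, n_windows) {
  counts <- as.numeric(table(factor(win_id, levels = seq_len(n_windows))))
  if (any(counts == 0)) stop("window with zero tokens cannot be pooled")
  P <- rowsum(X, group = win_id, reorder = TRUE) / counts
  list(Y = P, cache = list(win_id = win_id, counts = counts))
}

pool_backward <- function(dP, cache) {
  dP[cache$win_id, , drop = FALSE] / cache$counts[cache$win_id]
}

# Adam optimizer over a flat named list of parameter matrices/vectors
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(params[[nm]]) || is.null(grads[[nm]])) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Multi-horizon binary cross-entropy loss
#'
#' Mean over all horizons (and rows, when given matrices) of
#' `-[y log p + (1 - y) log(1 - p)]`, with probabilities clamped to
#' `[eps, 1 - eps]` for numerical safety.
#'
#' @param probs Numeric vector or matrix of predicted probabilities.
#' @param labels 0/1 vector or matrix of the same shape.
#' @param eps Clamp width.
#' @return Scalar loss.
#' @export
bce_multihorizon_loss <- function(probs, labels, eps = 1e-7) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  mean(-(labels * log(p) + (1 - labels) * log(1 - p)))
}
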