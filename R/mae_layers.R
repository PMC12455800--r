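
# Neural-network primitives for the masked autoencoder: linear, layer norm,
# batch norm, SELU/GELU/ReLU, multi-head self-attention, and (transposed)
# convolution via a shared im2col geometry. Every forward has a matching
# analytic backward; correctness is pinned by finite-difference tests on a
# tiny configuration.
#
# Feature-map layout for the convolutional decoder: a stack of N maps with C
# channels and H x W pixels is a (C*H*W) x N matrix with the channel index
# fastest, then row, then column. With C = 1 this coincides with column-major
# image flattening.

SELU_ALPHA <- 1.6732632423543772
SELU_LAMBDA <- 1.0507009873554805

selu_fwd <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(pmin(x, 0)) - 1))
}
selu_bwd <- function(x, dy) {
  dy * SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(pmin(x, 0)))
}

# sigmoid-approximation GELU (x * sigmoid(1.702 x)); cheap and smooth
gelu_fwd <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_bwd <- function(x, dy) {
  s <- 1 / (1 + exp(-1.702 * x))
  dy * (s + 1.702 * x * s * (1 - s))
}

relu_fwd <- function(x) pmax(x, 0)

# column-broadcast add/multiply without sweep() (which aperm-copies twice)
addc <- function(X, b) X + rep(b, each = nrow(X))
mulc <- function(X, g) X * rep(g, each = nrow(X))

lin_fwd <- function(X, W, b) addc(X %*% W, b)
# returns list(dX, dW, db)
lin_bwd <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

LN_EPS <- 1e-5

ln_fwd <- function(X, g, b) {
  m <- rowMeans(X)
  xc <- X - m
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  Y <- addc(mulc(xhat, g), b)
  list(Y = Y, xhat = xhat, inv = inv)
}
ln_bwd <- function(cache, g, dY) {
  dxhat <- mulc(dY, g)
  xhat <- cache$xhat
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

BN_EPS <- 1e-5

bn_fwd <- function(X, g, b, rm, rv, train, momentum = 0.1) {
  if (train) {
    m <- colMeans(X)
    v <- colMeans(sweep(X, 2, m)^2)
    rm <- (1 - momentum) * rm + momentum * m
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    m <- rm; v <- rv
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- mulc(addc(X, -m), inv)
  Y <- addc(mulc(xhat, g), b)
  list(Y = Y, xhat = xhat, inv = inv, rm = rm, rv = rv, train = train)
}
bn_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dxhat <- mulc(dY, g)
  if (cache$train) {
    dX <- mulc(dxhat - matrix(colMeans(dxhat), n, ncol(dY), byrow = TRUE) -
                 xhat * matrix(colMeans(dxhat * xhat), n, ncol(dY), byrow = TRUE),
               cache$inv)
  } else {
    dX <- mulc(dxhat, cache$inv)
  }
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# ---- attention -------------------------------------------------------------

# X: (N*V) x t token matrix, image n owning rows ((n-1)V+1):(nV).
attn_fwd <- function(X, w, prefix, n_heads, V, need_grad) {
  t_dim <- ncol(X)
  dh <- t_dim %/% n_heads
  N <- nrow(X) %/% V
  Q <- lin_fwd(X, w[[paste0(prefix, "Wq")]], w[[paste0(prefix, "bq")]])
  K <- lin_fwd(X, w[[paste0(prefix, "Wk")]], w[[paste0(prefix, "bk")]])
  Vv <- lin_fwd(X, w[[paste0(prefix, "Wv")]], w[[paste0(prefix, "bv")]])
  O <- matrix(0, nrow(X), t_dim)
  A_all <- if (need_grad) array(0, c(V, V, n_heads, N)) else NULL
  scl <- 1 / sqrt(dh)
  for (n in seq_len(N)) {
    rows <- ((n - 1) * V + 1):(n * V)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * scl
      S <- S - S[cbind(seq_len(V), max.col(S, ties.method = "first"))]
      A <- exp(S); A <- A / rowSums(A)
      O[rows, cols] <- A %*% Vv[rows, cols, drop = FALSE]
      if (need_grad) A_all[, , h, n] <- A
    }
  }
  Y <- lin_fwd(O, w[[paste0(prefix, "Wo")]], w[[paste0(prefix, "bo")]])
  list(Y = Y, Q = Q, K = K, V = Vv, O = O, A = A_all)
}

attn_bwd <- function(cache, X, w, prefix, n_heads, V, dY, grads) {
  t_dim <- ncol(X)
  dh <- t_dim %/% n_heads
  N <- nrow(X) %/% V
  scl <- 1 / sqrt(dh)
  go <- lin_bwd(cache$O, w[[paste0(prefix, "Wo")]], dY)
  grads[[paste0(prefix, "Wo")]] <- go$dW
  grads[[paste0(prefix, "bo")]] <- go$db
  dO <- go$dX
  dQ <- matrix(0, nrow(X), t_dim)
  dK <- matrix(0, nrow(X), t_dim)
  dV <- matrix(0, nrow(X), t_dim)
  for (n in seq_len(N)) {
    rows <- ((n - 1) * V + 1):(n * V)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- cache$A[, , h, n]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(A * dA))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * scl
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * scl
    }
  }
  gq <- lin_bwd(X, w[[paste0(prefix, "Wq")]], dQ)
  gk <- lin_bwd(X, w[[paste0(prefix, "Wk")]], dK)
  gv <- lin_bwd(X, w[[paste0(prefix, "Wv")]], dV)
  grads[[paste0(prefix, "Wq")]] <- gq$dW; grads[[paste0(prefix, "bq")]] <- gq$db
  grads[[paste0(prefix, "Wk")]] <- gk$dW; grads[[paste0(prefix, "bk")]] <- gk$db
  grads[[paste0(prefix, "Wv")]] <- gv$dW; grads[[paste0(prefix, "bv")]] <- gv$db
  list(dX = gq$dX + gk$dX + gv$dX, grads = grads)
}

# ---- (transposed) convolution ---------------------------------------------

.conv_geom_cache <- new.env(parent = emptyenv())

# Geometry of a k x k, stride-s, pad-p convolution from (Ci, Hi, Wi) down to
# (Ho, Wo). Used forwards for conv and backwards ("adjoint") for tconv.
conv_geom <- function(Hi, Wi, Ci, k, stride, pad) {
  key <- paste(Hi, Wi, Ci, k, stride, pad, sep = "_")
  if (!is.null(.conv_geom_cache[[key]])) return(.conv_geom_cache[[key]])
  Hp <- Hi + 2 * pad; Wp <- Wi + 2 * pad
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  stopifnot((Hp - k) %% stride == 0, (Wp - k) %% stride == 0)
  pad_idx <- function(c, h, w) c + Ci * ((h - 1) + Hp * (w - 1))
  # rows of the padded layout corresponding to real pixels, in feature layout
  ew <- rep(seq_len(Wi), each = Ci * Hi)
  eh <- rep(rep(seq_len(Hi), each = Ci), times = Wi)
  ec <- rep(seq_len(Ci), times = Hi * Wi)
  inner <- pad_idx(ec, eh + pad, ew + pad)
  # im2col index matrix: (Ci*k*k) x (Ho*Wo)
  dw <- rep(seq_len(k), each = Ci * k)
  dhh <- rep(rep(seq_len(k), each = Ci), times = k)
  dc <- rep(seq_len(Ci), times = k * k)
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ci * k * k, Ho * Wo)
  for (l in seq_len(Ho * Wo)) {
    h0 <- (oh[l] - 1) * stride
    w0 <- (ow[l] - 1) * stride
    idx[, l] <- pad_idx(dc, h0 + dhh, w0 + dw)
  }
  g <- list(Hi = Hi, Wi = Wi, Ci = Ci, k = k, stride = stride, pad = pad,
            Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, inner = inner,
            idx = as.vector(idx), n_rows = Ci * k * k, L = Ho * Wo,
            n_pad = Ci * Hp * Wp)
  .conv_geom_cache[[key]] <- g
  g
}

im2col <- function(Xf, g) {
  N <- ncol(Xf)
  P <- matrix(0, g$n_pad, N)
  P[g$inner, ] <- Xf
  A <- P[g$idx, , drop = FALSE]
  dim(A) <- c(g$n_rows, g$L * N)
  A
}

col2im <- function(A, g, N) {
  dim(A) <- c(g$n_rows * g$L, N)
  rs <- rowsum(A, group = g$idx, reorder = TRUE)
  P <- matrix(0, g$n_pad, N)
  P[as.integer(rownames(rs)), ] <- rs
  P[g$inner, , drop = FALSE]
}

# Transposed convolution small -> big. S: (Cs*Hs*Ws) x N, weight Wm:
# Cs x (Cb*k*k); the geometry g describes the conv big -> small.
tconv_fwd <- function(S, Wm, b, g, need_grad) {
  N <- ncol(S)
  Smat <- S
  dim(Smat) <- c(nrow(Wm), g$L * N)
  cols <- crossprod(Wm, Smat)             # (Cb*k*k) x (L*N)
  B <- col2im(cols, g, N)                 # (Cb*Hb*Wb) x N
  bfull <- b[(seq_len(nrow(B)) - 1L) %% g$Ci + 1L]
  B <- B + bfull
  list(Y = B, Smat = if (need_grad) Smat else NULL)
}

tconv_bwd <- function(dB, S_mat, Wm, g) {
  N <- ncol(dB)
  A <- im2col(dB, g)                      # (Cb*k*k) x (L*N)
  dS <- Wm %*% A                          # Cs x (L*N)
  dim(dS) <- c(nrow(Wm) * g$L, N)
  dWm <- tcrossprod(S_mat, A)             # Cs x (Cb*k*k)
  db_full <- rowSums(dB)
  db <- rowsum(db_full, group = (seq_along(db_full) - 1L) %% g$Ci + 1L)
  list(dX = dS, dW = dWm, db = as.vector(db))
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- positional encoding ---------------------------------------------------

# Fixed 2-D sinusoidal encoding over the patch grid; first half of the token
# dimension encodes the patch row, second half the column.
sincos_position_encoding <- function(n_rows, n_cols, t_dim) {
  stopifnot(t_dim %% 4 == 0)
  half <- t_dim %/% 2
  enc1d <- function(pos, d) {
    i <- seq_len(d %/% 2) - 1
    freq <- 1 / 10000^(2 * i / d)
    ang <- outer(pos, freq)
    cbind(sin(ang), cos(ang))
  }
  pr <- rep(seq_len(n_rows), each = n_cols)   # row-major patch order
  pc <- rep(seq_len(n_cols), times = n_rows)
  cbind(enc1d(pr, half), enc1d(pc, half))
}
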