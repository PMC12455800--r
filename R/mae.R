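
# Adapted masked autoencoder for gray-scale gene images: patchify, mask a
# high fraction (default 80%) of patches, encode the visible patches with a
# light vision-transformer (pre-norm blocks), mean-pool visible tokens,
# project through a linear + batch-norm + SELU head into the embedding
# space, and reconstruct the full image with a convolutional decoder driven
# directly by the gene embedding. The reconstruction loss is the summed
# squared error over images.

#' Masked autoencoder configuration
#'
#' @param patch_size Patch side length (images must be divisible by it).
#' @param mask_ratio Fraction of patches masked during training, in `[0, 1)`.
#' @param encoder_blocks Number of transformer blocks.
#' @param attention_heads Attention heads (must divide `token_dim`).
#' @param token_dim Token width (must be divisible by 4 for the fixed 2-D
#'   sinusoidal positional encoding).
#' @param embed_dim Embedding dimension D of the gene representations.
#' @param mlp_ratio Width multiplier of the block MLPs.
#' @param decoder_channels Channels at the decoder base grid and after the
#'   first two of the three transposed-convolution upsampling blocks.
#' @param seed Seed for weight initialization.
#' @return A list of class `mae_config`.
#' @export
mae_config <- function(patch_size = 4, mask_ratio = 0.8, encoder_blocks = 4,
                       attention_heads = 4, token_dim = 128, embed_dim = 64,
                       mlp_ratio = 2, decoder_channels = c(32, 16, 8),
                       seed = 1) {
  if (mask_ratio < 0 || mask_ratio >= 1) stopf("mask_ratio must be in [0, 1)")
  if (token_dim %% attention_heads != 0) stopf("token_dim must be divisible by attention_heads")
  if (token_dim %% 4 != 0) stopf("token_dim must be divisible by 4")
  if (embed_dim < 2) stopf("embed_dim must be at least 2")
  if (length(decoder_channels) != 3) stopf("decoder_channels must have length 3")
  structure(list(patch_size = patch_size, mask_ratio = mask_ratio,
                 encoder_blocks = encoder_blocks,
                 attention_heads = attention_heads, token_dim = token_dim,
                 embed_dim = embed_dim, mlp_ratio = mlp_ratio,
                 decoder_channels = decoder_channels, seed = seed),
            class = "mae_config")
}

#' Split an image into flattened non-overlapping patches
#'
#' Patches are ordered row-major over the patch grid; each patch is
#' flattened row-major. `unpatchify()` inverts the operation exactly.
#'
#' @param image H x W matrix.
#' @param patch_size Patch side length dividing both dimensions.
#' @return `(H/p * W/p)` x `p^2` matrix of patches.
#' @export
patchify <- function(image, patch_size) {
  H <- nrow(image); W <- ncol(image); p <- patch_size
  if (H %% p != 0 || W %% p != 0)
    stopf("image %d x %d not divisible by patch size %d", H, W, p)
  nr <- H %/% p; nc <- W %/% p
  out <- matrix(0, nr * nc, p * p)
  for (pr in seq_len(nr)) for (pc in seq_len(nc)) {
    blk <- image[((pr - 1) * p + 1):(pr * p), ((pc - 1) * p + 1):(pc * p)]
    out[(pr - 1) * nc + pc, ] <- as.vector(t(blk))   # row-major within patch
  }
  out
}

#' @rdname patchify
#' @param patches Matrix produced by [patchify()].
#' @param height,width Original image dimensions.
#' @export
unpatchify <- function(patches, height, width, patch_size) {
  p <- patch_size
  nr <- height %/% p; nc <- width %/% p
  img <- matrix(0, height, width)
  for (pr in seq_len(nr)) for (pc in seq_len(nc)) {
    blk <- matrix(patches[(pr - 1) * nc + pc, ], p, p, byrow = TRUE)
    img[((pr - 1) * p + 1):(pr * p), ((pc - 1) * p + 1):(pc * p)] <- blk
  }
  img
}

#' Sample a random patch mask
#'
#' Exactly `floor(mask_ratio * n_patches)` patches are masked, chosen
#' uniformly without replacement; deterministic given the seed.
#'
#' @param n_patches Number of patches.
#' @param mask_ratio Fraction masked, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = masked (discarded).
#' @export
sample_mask <- function(n_patches, mask_ratio, seed = 1) {
  n_mask <- floor(mask_ratio * n_patches)
  m <- rep(FALSE, n_patches)
  if (n_mask > 0)
    m[with_seed(seed, sample.int(n_patches, n_mask))] <- TRUE
  m
}

# index matrix mapping patch-row-major flattened patches into the
# column-major image vector
patch_index_matrix <- function(H, W, p) {
  nr <- H %/% p; nc <- W %/% p
  P <- nr * nc
  M <- matrix(0L, p * p, P)
  for (pr in seq_len(nr)) for (pc in seq_len(nc)) {
    pid <- (pr - 1) * nc + pc
    a <- rep(seq_len(p), each = p)       # row within patch (row-major flat)
    b <- rep(seq_len(p), times = p)
    i <- (pr - 1) * p + a
    j <- (pc - 1) * p + b
    M[, pid] <- i + H * (j - 1L)
  }
  M
}

#' Initialize masked-autoencoder weights
#'
#' @param cfg An [mae_config()].
#' @param height,width Image dimensions the model is bound to.
#' @return A list of class `mae_weights` holding trainable parameters,
#'   fixed buffers (positional encoding, batch-norm running statistics) and
#'   the configuration.
#' @export
mae_init <- function(cfg, height, width) {
  p <- cfg$patch_size
  if (height %% p != 0 || width %% p != 0)
    stopf("image dims must be divisible by the patch size")
  if (height %% 8 != 0 || width %% 8 != 0)
    stopf("image dims must be divisible by 8 (three 2x decoder upsamplings)")
  t_dim <- cfg$token_dim; D <- cfg$embed_dim
  nr <- height %/% p; nc <- width %/% p; P <- nr * nc
  ch <- cfg$decoder_channels
  h0 <- height %/% 8; w0 <- width %/% 8

  with_seed(cfg$seed, {
    rn <- function(nr_, nc_) matrix(stats::rnorm(nr_ * nc_, 0, 0.02), nr_, nc_)
    params <- list(pw = rn(p * p, t_dim), pb = numeric(t_dim))
    for (b in seq_len(cfg$encoder_blocks)) {
      pre <- paste0("b", b, "_")
      params[[paste0(pre, "ln1g")]] <- rep(1, t_dim)
      params[[paste0(pre, "ln1b")]] <- numeric(t_dim)
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        params[[paste0(pre, nm)]] <- rn(t_dim, t_dim)
      for (nm in c("bq", "bk", "bv", "bo"))
        params[[paste0(pre, nm)]] <- numeric(t_dim)
      params[[paste0(pre, "ln2g")]] <- rep(1, t_dim)
      params[[paste0(pre, "ln2b")]] <- numeric(t_dim)
      params[[paste0(pre, "W1")]] <- rn(t_dim, cfg$mlp_ratio * t_dim)
      params[[paste0(pre, "b1")]] <- numeric(cfg$mlp_ratio * t_dim)
      params[[paste0(pre, "W2")]] <- rn(cfg$mlp_ratio * t_dim, t_dim)
      params[[paste0(pre, "b2")]] <- numeric(t_dim)
    }
    params$hW <- rn(t_dim, D); params$hb <- numeric(D)
    params$bng <- rep(1, D); params$bnb <- numeric(D)
    params$dW0 <- rn(D, ch[1] * h0 * w0); params$db0 <- numeric(ch[1] * h0 * w0)
    chain <- c(ch, 1L)
    for (l in 1:3) {
      params[[paste0("t", l, "W")]] <- rn(chain[l], chain[l + 1] * 16)
      params[[paste0("t", l, "b")]] <- numeric(chain[l + 1])
    }
    structure(list(
      cfg = cfg, height = height, width = width, n_patches = P,
      params = params,
      buffers = list(pos = sincos_position_encoding(nr, nc, t_dim),
                     bn_rm = numeric(D), bn_rv = rep(1, D)),
      patch_idx = patch_index_matrix(height, width, p)
    ), class = "mae_weights")
  })
}

# decoder geometries (conv big -> small) for the three upsampling stages
decoder_geoms <- function(w) {
  ch <- c(w$cfg$decoder_channels, 1L)
  H <- w$height; W <- w$width
  list(conv_geom(H %/% 4, W %/% 4, ch[2], 4, 2, 1),
       conv_geom(H %/% 2, W %/% 2, ch[3], 4, 2, 1),
       conv_geom(H, W, ch[4], 4, 2, 1))
}

# Full forward pass.
# imgs: N x (H*W) column-major flattened images. vis_mat: V x N matrix of
# visible patch indices (same count V per image). Returns Z (N x D), Xhat
# (N x H*W) when need_recon, plus caches when need_grad.
mae_forward <- function(imgs, w, vis_mat, train = FALSE, need_grad = FALSE,
                        need_recon = TRUE) {
  cfg <- w$cfg
  N <- nrow(imgs); P <- w$n_patches
  V <- nrow(vis_mat)
  t_dim <- cfg$token_dim

  A <- imgs[, as.vector(w$patch_idx), drop = FALSE]   # N x (p^2 * P)
  B <- array(t(A), c(cfg$patch_size^2, P, N))
  Xp <- aperm(B, c(2, 3, 1))
  dim(Xp) <- c(P * N, cfg$patch_size^2)
  rows_sel <- as.vector(vis_mat + P * rep(0:(N - 1), each = V))
  X0 <- Xp[rows_sel, , drop = FALSE]
  X <- lin_fwd(X0, w$params$pw, w$params$pb) +
    w$buffers$pos[as.vector(vis_mat), , drop = FALSE]

  cache <- list(X0 = X0, rows_sel = rows_sel, vis_mat = vis_mat, blocks = list())
  for (b in seq_len(cfg$encoder_blocks)) {
    pre <- paste0("b", b, "_")
    l1 <- ln_fwd(X, w$params[[paste0(pre, "ln1g")]], w$params[[paste0(pre, "ln1b")]])
    at <- attn_fwd(l1$Y, w$params, pre, cfg$attention_heads, V, need_grad)
    X1 <- X + at$Y
    l2 <- ln_fwd(X1, w$params[[paste0(pre, "ln2g")]], w$params[[paste0(pre, "ln2b")]])
    U <- lin_fwd(l2$Y, w$params[[paste0(pre, "W1")]], w$params[[paste0(pre, "b1")]])
    G <- gelu_fwd(U)
    M <- lin_fwd(G, w$params[[paste0(pre, "W2")]], w$params[[paste0(pre, "b2")]])
    X2 <- X1 + M
    if (need_grad)
      cache$blocks[[b]] <- list(Xin = X, l1 = l1, at = at, X1 = X1, l2 = l2,
                                U = U, G = G)
    X <- X2
  }

  grp <- rep(seq_len(N), each = V)
  pooled <- rowsum(X, grp, reorder = FALSE) / V
  Hd <- lin_fwd(pooled, w$params$hW, w$params$hb)
  bn <- bn_fwd(Hd, w$params$bng, w$params$bnb, w$buffers$bn_rm,
               w$buffers$bn_rv, train)
  Z <- selu_fwd(bn$Y)

  out <- list(Z = Z, bn_rm = bn$rm, bn_rv = bn$rv)
  if (need_grad) {
    cache$Xtop <- X; cache$pooled <- pooled; cache$Hd <- Hd; cache$bn <- bn
    cache$bnY <- bn$Y; cache$V <- V; cache$N <- N
  }

  if (need_recon) {
    geoms <- decoder_geoms(w)
    S0 <- lin_fwd(Z, w$params$dW0, w$params$db0)
    F0 <- t(S0)
    R0 <- relu_fwd(F0)
    t1 <- tconv_fwd(R0, w$params$t1W, w$params$t1b, geoms[[1]], need_grad)
    R1 <- relu_fwd(t1$Y)
    t2 <- tconv_fwd(R1, w$params$t2W, w$params$t2b, geoms[[2]], need_grad)
    R2 <- relu_fwd(t2$Y)
    t3 <- tconv_fwd(R2, w$params$t3W, w$params$t3b, geoms[[3]], need_grad)
    out$Xhat <- t(t3$Y)
    if (need_grad)
      cache$dec <- list(S0 = S0, F0 = F0, R0 = R0, t1 = t1, R1 = R1,
                        t2 = t2, R2 = R2, t3 = t3, geoms = geoms)
  }
  if (need_grad) out$cache <- cache
  out
}

# Backward pass: dZ_ext is the gradient arriving at the embeddings from any
# mixture-side losses; dXhat the gradient at the reconstruction (or NULL).
mae_backward <- function(fw, w, dZ_ext = NULL, dXhat = NULL) {
  cfg <- w$cfg
  cache <- fw$cache
  N <- cache$N; V <- cache$V
  grads <- list()
  D <- cfg$embed_dim

  dZ <- if (is.null(dZ_ext)) matrix(0, N, D) else dZ_ext
  if (!is.null(dXhat)) {
    dec <- cache$dec
    dT3 <- t(dXhat)
    g3 <- tconv_bwd(dT3, dec$t3$Smat, w$params$t3W, dec$geoms[[3]])
    grads$t3W <- g3$dW; grads$t3b <- g3$db
    dR2 <- g3$dX * (dec$t2$Y > 0)
    g2 <- tconv_bwd(dR2, dec$t2$Smat, w$params$t2W, dec$geoms[[2]])
    grads$t2W <- g2$dW; grads$t2b <- g2$db
    dR1 <- g2$dX * (dec$t1$Y > 0)
    g1 <- tconv_bwd(dR1, dec$t1$Smat, w$params$t1W, dec$geoms[[1]])
    grads$t1W <- g1$dW; grads$t1b <- g1$db
    dF0 <- g1$dX * (dec$F0 > 0)
    dS0 <- t(dF0)
    g0 <- lin_bwd(fw$Z, w$params$dW0, dS0)
    grads$dW0 <- g0$dW; grads$db0 <- g0$db
    dZ <- dZ + g0$dX
  }

  dbnY <- selu_bwd(cache$bnY, dZ)
  gb <- bn_bwd(cache$bn, w$params$bng, dbnY)
  grads$bng <- gb$dg; grads$bnb <- gb$db
  gh <- lin_bwd(cache$pooled, w$params$hW, gb$dX)
  grads$hW <- gh$dW; grads$hb <- gh$db
  dX <- gh$dX[rep(seq_len(N), each = V), , drop = FALSE] / V

  for (b in rev(seq_len(cfg$encoder_blocks))) {
    pre <- paste0("b", b, "_")
    bc <- cache$blocks[[b]]
    # X2 = X1 + M
    gm2 <- lin_bwd(bc$G, w$params[[paste0(pre, "W2")]], dX)
    grads[[paste0(pre, "W2")]] <- gm2$dW; grads[[paste0(pre, "b2")]] <- gm2$db
    dU <- gelu_bwd(bc$U, gm2$dX)
    gm1 <- lin_bwd(bc$l2$Y, w$params[[paste0(pre, "W1")]], dU)
    grads[[paste0(pre, "W1")]] <- gm1$dW; grads[[paste0(pre, "b1")]] <- gm1$db
    gl2 <- ln_bwd(bc$l2, w$params[[paste0(pre, "ln2g")]], gm1$dX)
    grads[[paste0(pre, "ln2g")]] <- gl2$dg; grads[[paste0(pre, "ln2b")]] <- gl2$db
    dX1 <- dX + gl2$dX
    # X1 = Xin + attn(LN1(Xin))
    ab <- attn_bwd(bc$at, bc$l1$Y, w$params, pre, cfg$attention_heads, V,
                   dX1, grads)
    grads <- ab$grads
    gl1 <- ln_bwd(bc$l1, w$params[[paste0(pre, "ln1g")]], ab$dX)
    grads[[paste0(pre, "ln1g")]] <- gl1$dg; grads[[paste0(pre, "ln1b")]] <- gl1$db
    dX <- dX1 + gl1$dX
  }

  gp <- lin_bwd(cache$X0, w$params$pw, dX)
  grads$pw <- gp$dW; grads$pb <- gp$db
  grads
}

stack_images_flat <- function(stack) {
  d <- dim(stack$images)
  matrix(stack$images, nrow = d[1])
}

#' Encode gene images into embeddings
#'
#' Runs the encoder in evaluation mode (batch-norm running statistics). With
#' `mask_ratio = 0` the map is deterministic; a positive ratio samples an
#' independent mask per image from `seed`.
#'
#' @param stack A `gene_image_stack` (or plain N x H x W array).
#' @param weights An `mae_weights` object.
#' @param mask_ratio Fraction of patches to drop; embedding extraction for
#'   downstream analyses uses 0.
#' @param seed Seed for mask sampling.
#' @return List with `Z` (N x D matrix, rownames = gene ids) and `masks`
#'   (N x P logical matrix, TRUE = masked).
#' @export
mae_encode <- function(stack, weights, mask_ratio = 0, seed = 1) {
  imgs <- if (inherits(stack, "gene_image_stack")) stack_images_flat(stack)
          else matrix(stack, nrow = dim(stack)[1])
  if (ncol(imgs) != weights$height * weights$width)
    stopf("image dimensions do not match the model (%d x %d)",
          weights$height, weights$width)
  N <- nrow(imgs); P <- weights$n_patches
  n_mask <- floor(mask_ratio * P)
  V <- P - n_mask
  masks <- matrix(FALSE, N, P)
  if (n_mask > 0) {
    vis_mat <- with_seed(seed, {
      vapply(seq_len(N), function(i) {
        m <- sample.int(P, n_mask)
        masks[i, m] <<- TRUE
        sort(setdiff(seq_len(P), m))
      }, integer(V))
    })
  } else {
    vis_mat <- matrix(seq_len(P), P, N)
  }
  fw <- mae_forward(imgs, weights, vis_mat, train = FALSE, need_grad = FALSE,
                    need_recon = FALSE)
  Z <- fw$Z
  if (inherits(stack, "gene_image_stack")) rownames(Z) <- stack$gene_ids
  list(Z = Z, masks = masks)
}

#' Reconstruct images through the autoencoder
#'
#' Encodes each image from its visible patches and decodes the embedding
#' back to a full image.
#'
#' @inheritParams mae_encode
#' @param masks N x P logical matrix (TRUE = masked), e.g. from
#'   [mae_encode()]; NULL means no masking.
#' @return N x H x W array of reconstructions.
#' @export
mae_reconstruct <- function(stack, weights, masks = NULL) {
  imgs <- if (inherits(stack, "gene_image_stack")) stack_images_flat(stack)
          else matrix(stack, nrow = dim(stack)[1])
  N <- nrow(imgs); P <- weights$n_patches
  if (is.null(masks)) masks <- matrix(FALSE, N, P)
  if (!is.matrix(masks) || nrow(masks) != N || ncol(masks) != P)
    stopf("masks must be an N x P logical matrix aligned with the stack")
  nv <- P - rowSums(masks)
  if (length(unique(nv)) != 1)
    stopf("all masks must leave the same number of visible patches")
  vis_mat <- vapply(seq_len(N), function(i) which(!masks[i, ]), integer(nv[1]))
  if (!is.matrix(vis_mat)) vis_mat <- matrix(vis_mat, nrow = nv[1])
  fw <- mae_forward(imgs, weights, vis_mat, train = FALSE, need_grad = FALSE,
                    need_recon = TRUE)
  array(fw$Xhat, c(N, weights$height, weights$width))
}

#' Reconstruction loss
#'
#' Summed squared error over all images, `sum_i ||x_i - xhat_i||^2`,
#' equivalently the trace of `(X - Xhat)(X - Xhat)^T` with row-flattened
#' images. The sum (not mean) convention is kept throughout training.
#'
#' @param X,Xhat Image stacks/arrays/matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, Xhat) {
  if (inherits(X, "gene_image_stack")) X <- X$images
  if (inherits(Xhat, "gene_image_stack")) Xhat <- Xhat$images
  if (!identical(dim(X), dim(Xhat)))
    stopf("shape mismatch between X (%s) and Xhat (%s)",
          paste(dim(X), collapse = "x"), paste(dim(Xhat), collapse = "x"))
  sum((X - Xhat)^2)
}

# one pretraining step on a fixed set of rows; returns loss and new weights
mae_train_step <- function(imgs, w, opt_state, rows, mask_ratio, lr, step_seed) {
  P <- w$n_patches
  n_mask <- floor(mask_ratio * P)
  V <- P - n_mask
  vis_mat <- with_seed(step_seed, {
    vapply(seq_along(rows), function(i) sort(sample.int(P, P)[seq_len(V)]),
           integer(V))
  })
  if (!is.matrix(vis_mat)) vis_mat <- matrix(vis_mat, nrow = V)
  sub <- imgs[rows, , drop = FALSE]
  fw <- mae_forward(sub, w, vis_mat, train = TRUE, need_grad = TRUE,
                    need_recon = TRUE)
  loss <- sum((sub - fw$Xhat)^2)
  dXhat <- 2 * (fw$Xhat - sub)
  grads <- mae_backward(fw, w, dZ_ext = NULL, dXhat = dXhat)
  st <- adam_step(w$params, grads, opt_state, lr)
  w$params <- st$params
  w$buffers$bn_rm <- fw$bn_rm
  w$buffers$bn_rv <- fw$bn_rv
  list(w = w, opt_state = st$state, loss = loss)
}

#' Reconstruction-only pretraining
#'
#' Masked-reconstruction warm-up of the autoencoder with Adam; used before
#' the joint mixture training and as a standalone smoke test.
#'
#' @inheritParams mae_encode
#' @param steps Number of gradient steps.
#' @param batch_size Images per step (the whole stack if larger).
#' @param lr Adam learning rate.
#' @param mask_ratio Masking ratio; defaults to the model's configuration.
#' @return List with updated `weights`, Adam `opt_state` and the `loss`
#'   trace.
#' @export
mae_pretrain <- function(stack, weights, steps = 100, batch_size = 128,
                         lr = 1e-3, mask_ratio = NULL, seed = 1,
                         opt_state = NULL) {
  imgs <- if (inherits(stack, "gene_image_stack")) stack_images_flat(stack)
          else matrix(stack, nrow = dim(stack)[1])
  mask_ratio <- mask_ratio %||% weights$cfg$mask_ratio
  N <- nrow(imgs)
  bs <- min(batch_size, N)
  opt <- opt_state %||% adam_init(weights$params)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    rows <- if (bs == N) seq_len(N)
            else with_seed(seed + 7919L * s, sample.int(N, bs))
    st <- mae_train_step(imgs, weights, opt, rows, mask_ratio, lr,
                         step_seed = seed + 104729L + s)
    weights <- st$w; opt <- st$opt_state
    losses[s] <- st$loss
  }
  list(weights = weights, opt_state = opt, loss = losses)
}

#' Save / load autoencoder weights
#'
#' Single-file checkpoint with the configuration embedded; the round trip
#' preserves every parameter bit-exactly.
#'
#' @param weights An `mae_weights` object.
#' @param path Checkpoint file path.
#' @export
save_mae <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_mae
#' @export
load_mae <- function(path) readRDS(path)
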