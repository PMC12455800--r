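make_tiny_stack <- function(n = 6, H = 8, W = 8, seed = 3) {
  imgs <- withr::with_seed(seed, array(runif(n * H * W), c(n, H, W)))
  structure(list(images = imgs, valid_mask = matrix(TRUE, H, W),
                 gene_ids = sprintf("g%d", seq_len(n)),
                 scaling = cbind(min = rep(0, n), max = rep(1, n)),
                 pixel_map = NULL),
            class = "gene_image_stack")
}

test_that("patchify produces row-major patches and inverts exactly", {
  img <- matrix(runif(32 * 32), 32, 32)
  p <- patchify(img, 4)
  expect_equal(dim(p), c(64, 16))
  expect_equal(unpatchify(p, 32, 32, 4), img)

  # first patch is the top-left 4x4 block, flattened row-major
  expect_equal(p[1, ], as.vector(t(img[1:4, 1:4])))

  # degenerate: one patch equal to the flattened image
  small <- matrix(1:16, 4, 4)
  p1 <- patchify(small, 4)
  expect_equal(dim(p1), c(1, 16))
  expect_equal(unpatchify(p1, 4, 4, 4), small)

  expect_error(patchify(matrix(0, 6, 6), 4), "divisible")
})

test_that("mask sampling is exact, uniform-without-replacement and seeded", {
  m <- sample_mask(64, 0.8, seed = 4)
  expect_equal(sum(m), 51)          # floor(0.8 * 64)
  expect_equal(sum(!m), 13)
  expect_equal(sample_mask(64, 0, seed = 4), rep(FALSE, 64))
  expect_identical(m, sample_mask(64, 0.8, seed = 4))
  expect_false(identical(m, sample_mask(64, 0.8, seed = 5)))
  for (ratio in c(0.1, 0.33, 0.5, 0.75)) {
    for (P in c(16, 63, 100))
      expect_equal(sum(sample_mask(P, ratio, seed = 1)), floor(ratio * P))
  }
})

test_that("encoding is deterministic, shape-correct and per-image", {
  st <- make_tiny_stack(n = 6)
  st$images[4, , ] <- st$images[2, , ]          # duplicate image
  w <- mae_init(tiny_mae_cfg(), 8, 8)
  e1 <- mae_encode(st, w, mask_ratio = 0)
  e2 <- mae_encode(st, w, mask_ratio = 0)
  expect_equal(dim(e1$Z), c(6, 4))
  expect_identical(e1$Z, e2$Z)
  expect_equal(e1$Z[4, ], e1$Z[2, ], tolerance = 1e-12)

  # permuting input images permutes embeddings identically
  perm <- c(3, 1, 6, 2, 5, 4)
  stp <- st; stp$images <- st$images[perm, , ]; stp$gene_ids <- st$gene_ids[perm]
  ep <- mae_encode(stp, w, mask_ratio = 0)
  expect_equal(unname(ep$Z), unname(e1$Z[perm, ]), tolerance = 1e-12)

  # default configuration yields 64-dimensional embeddings
  w64 <- mae_init(mae_config(), 32, 32)
  st32 <- make_tiny_stack(n = 2, H = 32, W = 32)
  expect_equal(ncol(mae_encode(st32, w64, 0)$Z), 64)
})

test_that("reconstruction matches shapes and the loss its algebra", {
  st <- make_tiny_stack(n = 4)
  w <- mae_init(tiny_mae_cfg(), 8, 8)
  enc <- mae_encode(st, w, mask_ratio = 0.5, seed = 2)
  xh <- mae_reconstruct(st, w, enc$masks)
  expect_equal(dim(xh), dim(st$images))

  expect_equal(reconstruction_loss(st$images, st$images), 0)
  X <- array(diag(2), c(1, 2, 2))
  expect_equal(reconstruction_loss(X, X * 0), 2)   # sum of squares of I_2

  A <- matrix(rnorm(40), 4, 10); B <- matrix(rnorm(40), 4, 10)
  tr_form <- sum(diag((A - B) %*% t(A - B)))
  expect_equal(reconstruction_loss(A, B), tr_form, tolerance = 1e-12)
  expect_error(reconstruction_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("serialization round-trips weights bit-exactly", {
  st <- make_tiny_stack()
  w <- mae_init(tiny_mae_cfg(), 8, 8)
  f <- tempfile(fileext = ".rds")
  save_mae(w, f)
  w2 <- load_mae(f)
  expect_identical(w2$params, w$params)
  expect_identical(mae_encode(st, w2, 0)$Z, mae_encode(st, w, 0)$Z)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(11)
  H <- 8; W <- 8
  w <- mae_init(tiny_mae_cfg(seed = 5), H, W)
  # jitter all parameters so no pre-activation sits on a ReLU/SELU kink,
  # where finite differences are invalid
  w$params <- lapply(w$params, function(p) p + rnorm(length(p), 0, 0.15))
  imgs <- matrix(runif(3 * H * W), 3, H * W)
  vis_mat <- matrix(c(1L, 3L, 2L, 4L, 1L, 2L), nrow = 2)  # 2 visible of 4
  G <- matrix(rnorm(3 * 4), 3, 4)    # routes gradient through dZ too

  loss_fn <- function(params) {
    ww <- w; ww$params <- params
    fw <- stgem:::mae_forward(imgs, ww, vis_mat, train = TRUE,
                              need_grad = FALSE, need_recon = TRUE)
    sum((imgs - fw$Xhat)^2) + sum(fw$Z * G)
  }
  fw <- stgem:::mae_forward(imgs, w, vis_mat, train = TRUE, need_grad = TRUE,
                            need_recon = TRUE)
  grads <- stgem:::mae_backward(fw, w, dZ_ext = G,
                                dXhat = 2 * (fw$Xhat - imgs))

  h <- 1e-5
  for (nm in names(w$params)) {
    g_ana <- grads[[nm]]
    expect_false(is.null(g_ana), label = paste("gradient present for", nm))
    idx <- withr::with_seed(nchar(nm) + 1,
                            sample(length(w$params[[nm]]),
                                   min(4, length(w$params[[nm]]))))
    for (i in idx) {
      pp <- w$params; pp[[nm]][i] <- pp[[nm]][i] + h; up <- loss_fn(pp)
      pp <- w$params; pp[[nm]][i] <- pp[[nm]][i] - h; dn <- loss_fn(pp)
      g_num <- (up - dn) / (2 * h)
      expect_equal(g_ana[i], g_num, tolerance = 5e-4,
                   label = sprintf("d/d %s[%d] analytic", nm, i))
    }
  }
})

test_that("reconstruction training reduces the loss on a fixed batch", {
  st <- make_tiny_stack(n = 32, H = 16, W = 16, seed = 9)
  # smooth images so there is structure to learn
  for (i in 1:32) {
    st$images[i, , ] <- outer(sin(seq(0, pi, length = 16) * (i %% 4 + 1)),
                              cos(seq(0, pi, length = 16) * (i %% 3 + 1)))^2
  }
  cfg <- mae_config(patch_size = 4, mask_ratio = 0.5, encoder_blocks = 1,
                    attention_heads = 2, token_dim = 16, embed_dim = 8,
                    decoder_channels = c(8, 6, 4), seed = 2)
  w <- mae_init(cfg, 16, 16)
  out <- mae_pretrain(st, w, steps = 200, batch_size = 32, lr = 1e-2, seed = 1)
  expect_lt(out$loss[200], 0.5 * out$loss[1])
  expect_true(all(is.finite(out$loss)))
})
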