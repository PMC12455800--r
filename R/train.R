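
# Joint training: alternate (II) MAP-EM refresh of the Student's-t mixture
# on the current embeddings with (III) gradient refinement of the
# autoencoder and the differentiable mixture parameters, first through the
# epoch-level loss L1 on the full data, then through the batch-level loss
# L2 = L_c + lambda1 * L_r + lambda2 * L_lap. Training stops when the
# fraction of genes changing hard assignment falls below a threshold or the
# epoch budget is exhausted.

#' Training configuration
#'
#' @param K Number of mixture components; default `ceiling(N / 30)`, the
#'   typical gene count of a curated pathway per cluster.
#' @param eta1,eta2,eta3 Weights of the Laplacian, size and reconstruction
#'   terms in the epoch loss; `eta1` decays geometrically by `decay` per
#'   epoch.
#' @param lambda1,lambda2 Weights of the reconstruction and Laplacian terms
#'   in the batch loss; `lambda2` follows `eta1`'s decay schedule.
#' @param upsilon Cluster-size exemption threshold; default `1/K`.
#' @param batch_size Genes per batch in the refinement phase.
#' @param max_epochs Epoch budget.
#' @param assignment_change_tol Stop when the changed-assignment fraction
#'   drops below this.
#' @param lr_mae,lr_smm Adam learning rates for autoencoder and mixture
#'   parameters during the joint phase. The joint rate is deliberately
#'   smaller than the warm-up rate: the refinement losses reshape an
#'   already-formed embedding geometry and larger steps make the mixture
#'   chase a moving target.
#' @param lr_warmup Adam learning rate for the reconstruction warm-up.
#' @param warmup_epochs Reconstruction-only passes over the data before the
#'   joint loop.
#' @param warmup_steps Absolute number of warm-up gradient steps; overrides
#'   `warmup_epochs` when set. The embeddings must already summarize the
#'   spatial maps before mixture fitting starts, so short warm-ups only make
#'   sense with pretrained weights.
#' @param decay Geometric decay factor for `eta1` and `lambda2`.
#' @param em_iter_init,em_iter_refresh EM sweeps for the first fit and the
#'   per-epoch refreshes.
#' @param l1_passes Full-data gradient passes on L1 per epoch.
#' @param cauchy_mode Fix all degrees of freedom at 1.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `stgem_config`.
#' @export
stgem_config <- function(K = NULL, eta1 = 0.5, eta2 = 0.1, eta3 = 0.1,
                         lambda1 = 0.3, lambda2 = 0.1, upsilon = NULL,
                         batch_size = 128, max_epochs = 50,
                         assignment_change_tol = 0.001, lr_mae = 2e-4,
                         lr_smm = 1e-4, lr_warmup = 1e-3,
                         warmup_epochs = 5, warmup_steps = NULL,
                         decay = 0.9,
                         em_iter_init = 50, em_iter_refresh = 10,
                         l1_passes = 1, cauchy_mode = FALSE, seed = 1) {
  if (any(c(eta1, eta2, eta3, lambda1, lambda2) < 0))
    stopf("loss weights must be non-negative")
  if (!is.null(upsilon) && (upsilon <= 0 || upsilon > 1))
    stopf("upsilon must lie in (0, 1]")
  structure(as.list(environment()), class = "stgem_config")
}

smm_logits <- function(theta) log(pmax(theta$pi, 1e-300))

#' Reduced desk-scale configuration
#'
#' A compact training setup for 32 x 32 rasters on commodity CPUs:
#' 32-dimensional embeddings, a 2-block encoder with patch size 8 (16
#' tokens per image), a 300-step reconstruction warm-up and a gentle joint
#' learning rate. The embedding must already reconstruct the maps before
#' the mixture sees it, and how fast that happens varies with the tissue
#' layout; datasets with many small domains profit from patch size 4 and a
#' longer warm-up. Used by the package's simulation studies; real Visium-scale
#' runs should move to the full [mae_config()] defaults.
#'
#' @param K Mixture components.
#' @param seed Master seed.
#' @param max_epochs Epoch budget of the joint phase.
#' @return List with elements `cfg` ([stgem_config()]) and `mae_cfg`
#'   ([mae_config()]); pass both to [fit_stgem()] with `height = width = 32`.
#' @export
stgem_reduced_preset <- function(K = 6, seed = 1, max_epochs = 12) {
  list(
    cfg = stgem_config(K = K, max_epochs = max_epochs, warmup_steps = 300,
                       batch_size = 128, lr_mae = 1e-4, seed = seed),
    mae_cfg = mae_config(patch_size = 8, encoder_blocks = 2,
                         attention_heads = 4, token_dim = 48, embed_dim = 32,
                         decoder_channels = c(32, 16, 8))
  )
}

#' Fit the full gene-embedding model
#'
#' Pipeline: rasterize the preprocessed dataset, warm up the masked
#' autoencoder on reconstruction alone, then per epoch (II) refresh the
#' MAP Student's-t mixture on the current embeddings and (III) refine the
#' autoencoder with the epoch loss L1 followed by batch-level passes of
#' `L2 = L_c + lambda1 L_r + lambda2 L_lap`, updating the autoencoder and
#' the differentiable mixture parameters (means, weight logits, log degrees
#' of freedom) jointly. Deterministic given the configuration seed.
#'
#' @param ds A preprocessed [spatial_dataset()].
#' @param cfg An [stgem_config()].
#' @param mae_cfg An [mae_config()].
#' @param height,width Raster dimensions.
#' @param verbose Emit one log line per epoch.
#' @return A list of class `stgem_model`: autoencoder weights, mixture
#'   parameters and priors, embeddings `Z`, latent statistics, the image
#'   stack geometry, the seeding graph and a per-epoch `history` data frame
#'   whose recorded components recombine exactly into the recorded totals.
#' @export
fit_stgem <- function(ds, cfg = stgem_config(), mae_cfg = mae_config(),
                      height = 48, width = 48, verbose = FALSE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!isTRUE(ds$normalized)) stopf("fit_stgem() expects a preprocessed dataset")
  N <- ncol(ds$counts)
  K <- cfg$K %||% ceiling(N / 30)
  if (N < 2 * K) stopf("need at least 2K genes (N=%d, K=%d)", N, K)
  upsilon <- cfg$upsilon %||% (1 / K)

  stack <- rasterize(ds, height, width, patch_size = mae_cfg$patch_size)
  imgs <- stack_images_flat(stack)
  seedg <- seed_similarity(ds, k_neighbors = min(10, N - 1))

  mae_cfg$seed <- cfg$seed
  w <- mae_init(mae_cfg, height, width)
  opt <- adam_init(w$params)

  # reconstruction-only warm-up
  steps_per_epoch <- max(1, ceiling(N / cfg$batch_size))
  n_warmup <- cfg$warmup_steps %||% (cfg$warmup_epochs * steps_per_epoch)
  if (n_warmup > 0) {
    pre <- mae_pretrain(stack, w, steps = n_warmup,
                        batch_size = cfg$batch_size, lr = cfg$lr_warmup,
                        seed = cfg$seed + 11L, opt_state = opt)
    w <- pre$weights; opt <- pre$opt_state
  }

  enc <- mae_encode(stack, w, mask_ratio = 0)
  Z <- enc$Z
  priors <- smm_priors(Z)
  fit <- fit_smm_map(Z, K, priors, max_iter = cfg$em_iter_init,
                     seed = cfg$seed + 23L, cauchy_mode = cfg$cauchy_mode)
  theta <- fit$theta

  smm_params <- list(mu = theta$mu, logit = smm_logits(theta),
                     logv = log(theta$v))
  opt_smm <- adam_init(smm_params)

  hard_prev <- fit$stats$hard
  history <- list()
  stop_reason <- "max_epochs"
  stop_epoch <- cfg$max_epochs
  eta1_t <- cfg$eta1
  lambda2_t <- cfg$lambda2
  P_full <- w$n_patches
  V_mask <- P_full - floor(mae_cfg$mask_ratio * P_full)

  for (epoch in seq_len(cfg$max_epochs)) {
    # ---- module II: refresh the mixture on current embeddings ----
    enc <- mae_encode(stack, w, mask_ratio = 0)
    Z <- enc$Z
    fit <- fit_smm_map(Z, K, priors, max_iter = cfg$em_iter_refresh,
                       seed = cfg$seed + 23L, theta0 = theta,
                       cauchy_mode = cfg$cauchy_mode)
    theta <- fit$theta
    smm_params <- list(mu = theta$mu, logit = smm_logits(theta),
                       logv = log(theta$v))

    st0 <- fit$stats
    Q_norm <- st0$r
    P_target <- target_distribution(Q_norm)   # fixed for the whole epoch

    # ---- module III, step 1: epoch loss L1, full data ----
    l1_rec <- NULL
    for (pass in seq_len(cfg$l1_passes)) {
      vis_all <- matrix(seq_len(P_full), P_full, N)
      fw <- mae_forward(imgs, w, vis_all, train = TRUE, need_grad = TRUE,
                        need_recon = TRUE)
      parts <- density_grad_parts(fw$Z, theta)
      l1 <- epoch_loss_L1(fw$Z, theta, seedg, imgs, fw$Xhat,
                          eta1 = eta1_t, eta2 = cfg$eta2, eta3 = cfg$eta3,
                          upsilon = upsilon)
      dZ <- -loglik_grad_z(parts, theta) +
        eta1_t * laplacian_grad(fw$Z, seedg) -
        cfg$eta2 * density_chain(size_grad_logq(parts$st, upsilon),
                                 parts, theta)$dZ
      dXhat <- cfg$eta3 * 2 * (fw$Xhat - imgs)
      grads <- mae_backward(fw, w, dZ_ext = dZ, dXhat = dXhat)
      stp <- adam_step(w$params, grads, opt, cfg$lr_mae)
      w$params <- stp$params; opt <- stp$state
      w$buffers$bn_rm <- fw$bn_rm; w$buffers$bn_rv <- fw$bn_rv
      if (pass == 1) l1_rec <- l1
    }

    # ---- module III, step 2: batch loss L2 ----
    perm <- with_seed(cfg$seed + 1000L + epoch, sample.int(N))
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    l2_acc <- c(total = 0, L_c = 0, L_r = 0, L_lap = 0)
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      nb <- length(rows)
      if (nb < 2) next
      vis_mat <- with_seed(cfg$seed + 3571L * epoch + bi, {
        m <- vapply(seq_len(nb),
                    function(i) sort(sample.int(P_full, P_full)[seq_len(V_mask)]),
                    integer(V_mask))
        if (!is.matrix(m)) matrix(m, nrow = V_mask) else m
      })
      sub <- imgs[rows, , drop = FALSE]
      fw <- mae_forward(sub, w, vis_mat, train = TRUE, need_grad = TRUE,
                        need_recon = TRUE)
      parts <- density_grad_parts(fw$Z, theta)
      Qb <- parts$st$r
      Pb <- P_target[rows, , drop = FALSE]
      L_c <- kl_clustering_loss(Pb, pmax(Qb, 1e-300))
      L_r <- sum((sub - fw$Xhat)^2)
      sg <- seed_subgraph(seedg, rows)
      L_lap <- laplacian_loss(fw$Z, sg)
      l2_acc <- l2_acc + c(L_c + cfg$lambda1 * L_r + lambda2_t * L_lap,
                           L_c, L_r, L_lap)

      chain <- density_chain(kl_grad_logq(Pb, Qb), parts, theta)
      dZ <- chain$dZ + lambda2_t * laplacian_grad(fw$Z, sg)
      dXhat <- cfg$lambda1 * 2 * (fw$Xhat - sub)
      grads <- mae_backward(fw, w, dZ_ext = dZ, dXhat = dXhat)
      stp <- adam_step(w$params, grads, opt, cfg$lr_mae)
      w$params <- stp$params; opt <- stp$state
      w$buffers$bn_rm <- fw$bn_rm; w$buffers$bn_rv <- fw$bn_rv

      sg2 <- adam_step(smm_params,
                       list(mu = chain$dmu, logit = chain$dlogit,
                            logv = chain$dlogv),
                       opt_smm, cfg$lr_smm)
      smm_params <- sg2$params; opt_smm <- sg2$state
      theta$mu <- smm_params$mu
      theta$pi <- exp(smm_params$logit - max(smm_params$logit))
      theta$pi <- theta$pi / sum(theta$pi)
      theta$v <- if (cfg$cauchy_mode) rep(1, K)
                 else clamp(exp(smm_params$logv), V_BOUNDS[1], V_BOUNDS[2])
      smm_params$logv <- log(theta$v)
    }

    # ---- epoch bookkeeping ----
    enc <- mae_encode(stack, w, mask_ratio = 0)
    Z <- enc$Z
    st <- smm_e_step(Z, theta)
    if (!all(is.finite(unlist(l1_rec[c("total")]))) || !all(is.finite(Z)))
      stopf("training diverged (non-finite loss) at epoch %d", epoch)
    change <- mean(st$hard != hard_prev)
    hard_prev <- st$hard
    history[[epoch]] <- data.frame(
      epoch = epoch, L1_total = l1_rec$total, L_ll = l1_rec$L_ll,
      L_lap = l1_rec$L_lap, L_size = l1_rec$L_size, L_r = l1_rec$L_r,
      eta1 = eta1_t, eta2 = cfg$eta2, eta3 = cfg$eta3,
      L2_total = l2_acc[["total"]], L2_c = l2_acc[["L_c"]],
      L2_r = l2_acc[["L_r"]], L2_lap = l2_acc[["L_lap"]],
      lambda1 = cfg$lambda1, lambda2 = lambda2_t,
      assignment_change = change,
      mean_max_resp = mean(apply(st$r, 1, max))
    )
    if (verbose)
      message(sprintf("epoch %2d | L1 %.2f | L2 %.2f | change %.4f | maxresp %.3f",
                      epoch, l1_rec$total, l2_acc[["total"]], change,
                      mean(apply(st$r, 1, max))))
    eta1_t <- eta1_t * cfg$decay
    lambda2_t <- lambda2_t * cfg$decay
    if (change < cfg$assignment_change_tol) {
      stop_reason <- "converged"; stop_epoch <- epoch
      break
    }
  }

  st <- smm_e_step(Z, theta)
  structure(list(
    mae = w, mae_cfg = mae_cfg, cfg = cfg, theta = theta, priors = priors,
    Z = Z, stats = st, stack = stack, seed_sim = seedg,
    gene_ids = ds$gene_ids, K = K,
    history = do.call(rbind, history),
    stop_reason = stop_reason, stop_epoch = stop_epoch
  ), class = "stgem_model")
}

#' @export
print.stgem_model <- function(x, ...) {
  cat(sprintf("<stgem_model> %d genes, D=%d, K=%d | stopped: %s at epoch %d\n",
              nrow(x$Z), ncol(x$Z), x$K, x$stop_reason, x$stop_epoch))
  invisible(x)
}

#' Save / load a trained model
#'
#' @param model An `stgem_model`.
#' @param path File path for the single-file checkpoint.
#' @export
save_stgem <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_stgem
#' @export
load_stgem <- function(path) readRDS(path)

#' Export embeddings as TSV
#'
#' @param Z Embedding matrix with gene ids as rownames (e.g. `model$Z`).
#' @param path Output TSV path.
#' @export
write_embeddings <- function(Z, path) {
  df <- data.frame(gene_id = rownames(Z), Z, check.names = FALSE)
  colnames(df) <- c("gene_id", paste0("d", seq_len(ncol(Z))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export hard assignments as TSV
#'
#' @param model An `stgem_model`.
#' @param path Output TSV path.
#' @export
write_assignments <- function(model, path) {
  df <- data.frame(gene_id = model$gene_ids, cluster = model$stats$hard,
                   max_responsibility = apply(model$stats$r, 1, max))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
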