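
# Cross-sample embedding alignment: a three-layer feedforward network with
# SELU activations maps embeddings of one dataset onto another, trained by
# mean absolute error on anchor genes whose biological role is stable
# across samples (housekeeping genes, in practice).

san_forward <- function(Z, p, need_grad = FALSE) {
  A1 <- lin_fwd(Z, p$W1, p$b1); H1 <- selu_fwd(A1)
  A2 <- lin_fwd(H1, p$W2, p$b2); H2 <- selu_fwd(A2)
  Y <- lin_fwd(H2, p$W3, p$b3)
  if (need_grad) list(Y = Y, A1 = A1, H1 = H1, A2 = A2, H2 = H2) else list(Y = Y)
}

san_backward <- function(fw, Z, p, dY) {
  g3 <- lin_bwd(fw$H2, p$W3, dY)
  dH2 <- selu_bwd(fw$A2, g3$dX)
  g2 <- lin_bwd(fw$H1, p$W2, dH2)
  dH1 <- selu_bwd(fw$A1, g2$dX)
  g1 <- lin_bwd(Z, p$W1, dH1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, W3 = g3$dW, b3 = g3$db)
}

#' Fit the embedding alignment network
#'
#' Trains `F`: a D -> 2D -> 2D -> D feedforward network with SELU
#' activations minimizing the mean absolute error `mean |F(z_a) - z_b|`
#' over anchor gene pairs. A held-out anchor fraction monitors validation
#' loss with early stopping on plateau.
#'
#' @param sgr_a,sgr_b Embedding matrices with gene-id rownames.
#' @param anchor_ids Genes (in both matrices) to train on; at least 20.
#' @param epochs Maximum training epochs (full-batch Adam).
#' @param lr Learning rate.
#' @param val_frac Anchor fraction held out for validation.
#' @param patience Epochs without validation improvement before stopping.
#' @param hidden_mult Hidden width as a multiple of D.
#' @param seed Integer seed.
#' @return List of class `san_model`: `params`, `anchors`, `loss`
#'   (train trace), `val_loss`.
#' @export
san_fit <- function(sgr_a, sgr_b, anchor_ids, epochs = 200, lr = 1e-2,
                    val_frac = 0.1, patience = 20, hidden_mult = 2, seed = 1) {
  anchor_ids <- intersect(anchor_ids, intersect(rownames(sgr_a), rownames(sgr_b)))
  if (length(anchor_ids) < 20) stopf("need at least 20 anchors present in both matrices")
  Za <- sgr_a[anchor_ids, , drop = FALSE]
  Zb <- sgr_b[anchor_ids, , drop = FALSE]
  D <- ncol(Za); Hd <- hidden_mult * D
  n <- nrow(Za)
  nv <- max(2, floor(val_frac * n))

  with_seed(seed, {
    vi <- sample.int(n, nv)
    rn <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(1 / a)), a, b)
    p <- list(W1 = rn(D, Hd), b1 = numeric(Hd), W2 = rn(Hd, Hd),
              b2 = numeric(Hd), W3 = rn(Hd, D), b3 = numeric(D))
    # bias the last layer toward the identity start
    p$W1[cbind(seq_len(D), seq_len(D))] <- p$W1[cbind(seq_len(D), seq_len(D))] + 0.5

    tr <- setdiff(seq_len(n), vi)
    opt <- adam_init(p)
    trace <- numeric(0); vtrace <- numeric(0)
    best <- Inf; best_p <- p; stall <- 0
    for (e in seq_len(epochs)) {
      fw <- san_forward(Za[tr, , drop = FALSE], p, need_grad = TRUE)
      R <- fw$Y - Zb[tr, , drop = FALSE]
      loss <- mean(abs(R))
      dY <- sign(R) / length(R)
      g <- san_backward(fw, Za[tr, , drop = FALSE], p, dY)
      st <- adam_step(p, g, opt, lr)
      p <- st$params; opt <- st$state
      vl <- mean(abs(san_forward(Za[vi, , drop = FALSE], p)$Y -
                       Zb[vi, , drop = FALSE]))
      trace <- c(trace, loss); vtrace <- c(vtrace, vl)
      if (vl < best - 1e-7) { best <- vl; best_p <- p; stall <- 0 }
      else stall <- stall + 1
      if (stall >= patience) break
    }
    structure(list(params = best_p, anchors = anchor_ids, loss = trace,
                   val_loss = vtrace), class = "san_model")
  })
}

#' Align embeddings through a trained network
#'
#' Applies `F` to rows of `sgr_a`; when the matching rows exist in `sgr_b`,
#' reports the per-gene scaled cosine dissimilarity of the aligned pairs.
#'
#' @param model A [san_fit()] model.
#' @param sgr_a Embeddings to map (gene-id rownames).
#' @param sgr_b Optional reference embeddings for dissimilarity reporting.
#' @return List with `aligned` (matrix) and `dissimilarity` (data.frame or
#'   NULL).
#' @export
san_align <- function(model, sgr_a, sgr_b = NULL) {
  aligned <- san_forward(sgr_a, model$params)$Y
  rownames(aligned) <- rownames(sgr_a)
  dis <- NULL
  if (!is.null(sgr_b)) {
    common <- intersect(rownames(sgr_a), rownames(sgr_b))
    if (length(common) > 0) {
      d <- scaled_cosine_dissim_rows(aligned[common, , drop = FALSE],
                                     sgr_b[common, , drop = FALSE])
      dis <- data.frame(gene_id = common, dissimilarity = d)
    }
  }
  list(aligned = aligned, dissimilarity = dis)
}
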