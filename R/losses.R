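
# Losses for the joint training loop: the seeding similarity graph and its
# normalized Laplacian penalty, the cluster-size entropy penalty, the
# epoch-level composite loss, and the deep-embedded-clustering target
# distribution with its KL refinement loss. Analytic gradients with respect
# to the embeddings (and the differentiable mixture parameters) live here
# too, so the trainer only ever routes a single dL/dZ into the encoder.

#' Seeding gene-gene similarity graph
#'
#' Cosine similarity between per-gene log-normalized spot-expression
#' vectors, sparsified to the top `k_neighbors` entries per row, symmetrized
#' by the elementwise maximum, negatives clipped to zero and unit diagonal.
#' This graph informs the early phase of training through the Laplacian
#' penalty, before the learned embeddings take over.
#'
#' @param ds A preprocessed [spatial_dataset()].
#' @param k_neighbors Neighbours kept per gene.
#' @return List of class `seed_similarity`: sparse `S`, degree vector
#'   `degrees`, and `k_neighbors`.
#' @export
seed_similarity <- function(ds, k_neighbors = 10) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!isTRUE(ds$normalized)) stopf("seed_similarity() expects a preprocessed dataset")
  N <- ncol(ds$counts)
  if (N < k_neighbors + 1) stopf("need more genes (%d) than k_neighbors + 1", N)
  C <- cosine_cols(ds$counts)
  keep <- matrix(FALSE, N, N)
  for (i in seq_len(N)) {
    o <- order(C[i, ], decreasing = TRUE)
    keep[i, o[seq_len(k_neighbors + 1)]] <- TRUE   # self + k neighbours
  }
  S <- C
  S[!(keep | t(keep))] <- 0
  S <- pmax(S, t(S))
  S[S < 0] <- 0
  diag(S) <- 1
  S <- as_sparse(S)
  structure(list(S = S, degrees = Matrix::rowSums(S),
                 k_neighbors = k_neighbors), class = "seed_similarity")
}

# symmetric normalized Laplacian applied to Z: (I - D^{-1/2} S D^{-1/2}) Z
laplacian_apply <- function(Z, S, degrees) {
  dm <- 1 / sqrt(degrees)
  Z - dm * as.matrix(S %*% (dm * Z))
}

#' Laplacian smoothness penalty
#'
#' `Tr(Z' (I - D^{-1/2} S D^{-1/2}) Z)`: small when genes similar in the
#' seeding graph have similar embeddings. Non-negative for any embedding
#' because the normalized Laplacian is positive semi-definite.
#'
#' @param Z N x D embedding matrix.
#' @param seed A [seed_similarity()] (or any list with `S`, `degrees`).
#' @return Scalar penalty.
#' @export
laplacian_loss <- function(Z, seed) {
  if (any(seed$degrees <= 0)) stopf("zero-degree node in the similarity graph")
  if (nrow(Z) != nrow(seed$S)) stopf("embedding rows do not match the graph")
  sum(Z * laplacian_apply(Z, seed$S, seed$degrees))
}

laplacian_grad <- function(Z, seed) 2 * laplacian_apply(Z, seed$S, seed$degrees)

# seed graph restricted to a batch, degrees recomputed (diagonal is 1 so
# every batch node keeps a positive degree)
seed_subgraph <- function(seed, rows) {
  S <- seed$S[rows, rows, drop = FALSE]
  list(S = S, degrees = Matrix::rowSums(S))
}

#' Cluster-size penalty
#'
#' Entropy-style penalty `sum_k -J_k log J_k` over cluster mass fractions
#' `J_k` (row-normalized assignment mass / N), with clusters whose share
#' already exceeds the exemption threshold `upsilon` contributing zero.
#' Entering the epoch loss with a negative weight, it pushes probability
#' mass toward empty and tiny clusters without touching healthy ones.
#'
#' @param stats An `smm_stats` (uses row-normalized responsibilities).
#' @param upsilon Exemption threshold in `(0, 1]`.
#' @return List with `loss` and the `J` vector of cluster fractions.
#' @export
size_loss <- function(stats, upsilon) {
  if (upsilon <= 0 || upsilon > 1) stopf("upsilon must lie in (0, 1]")
  J <- colSums(stats$r) / nrow(stats$r)
  Jeff <- ifelse(J > upsilon, 1, pmax(J, 1e-12))
  list(loss = sum(-Jeff * log(Jeff)), J = J)
}

#' Sharpened auxiliary target distribution
#'
#' Squares the normalized assignment probabilities, reweights by inverse
#' cluster mass and renormalizes each row: high-confidence assignments are
#' boosted, large clusters are discounted. One-hot rows are a fixed point;
#' a fully uniform matrix stays uniform.
#'
#' @param Q_norm N x K matrix of row-normalized assignment probabilities.
#' @return N x K target matrix `P` with unit row sums.
#' @export
target_distribution <- function(Q_norm) {
  f <- colSums(Q_norm)
  if (any(f <= 0)) stopf("cluster with zero total mass")
  W <- sweep(Q_norm^2, 2, f, "/")
  W / rowSums(W)
}

#' KL clustering refinement loss
#'
#' `KL(P || Q) = sum_ik p log(p/q)` with the convention `0 log(0/q) = 0`.
#' Zero iff `P = Q`; infinite mass on an impossible assignment is an error.
#'
#' @param P Target matrix from [target_distribution()].
#' @param Q_norm Current row-normalized assignment probabilities.
#' @return Non-negative scalar.
#' @export
kl_clustering_loss <- function(P, Q_norm) {
  if (!identical(dim(P), dim(Q_norm))) stopf("P and Q must have equal shape")
  if (any(Q_norm == 0 & P > 0)) stopf("infinite KL: target mass on zero-probability assignment")
  pos <- P > 0
  sum(P[pos] * (log(P[pos]) - log(Q_norm[pos])))
}

# ---- gradients through the mixture density --------------------------------

# Per-component quantities reused by every density-based gradient:
# g_{i,k} = d log q_{i,k} / d z_i = -zeta_{i,k} Sigma_k^{-1} (z_i - mu_k).
# Returns stats plus the list of Sigma^{-1}(z - mu) matrices.
density_grad_parts <- function(Z, theta) {
  st <- smm_e_step(Z, theta)
  K <- theta$K
  SinvZc <- vector("list", K)
  for (k in seq_len(K)) {
    L <- chol(theta$Sigma[[k]])
    Zc <- t(Z) - theta$mu[k, ]
    SinvZc[[k]] <- t(backsolve(L, backsolve(L, Zc, transpose = TRUE)))
  }
  list(st = st, SinvZc = SinvZc)
}

# dZ of the log-likelihood sum_i log sum_k q_{i,k}: sum_k r_{i,k} g_{i,k}
loglik_grad_z <- function(parts, theta) {
  acc <- 0
  for (k in seq_len(theta$K))
    acc <- acc - (parts$st$r[, k] * parts$st$zeta[, k]) * parts$SinvZc[[k]]
  acc
}

# Generic chain rule: given dL/d log q (N x K), return dL/dZ plus gradients
# for mu, pi logits and log v.
density_chain <- function(dlogq, parts, theta) {
  st <- parts$st
  K <- theta$K; D <- ncol(st$r) * 0 + length(theta$mu[1, ])
  dZ <- 0
  dmu <- matrix(0, K, D)
  for (k in seq_len(K)) {
    gk <- -st$zeta[, k] * parts$SinvZc[[k]]
    dZ <- dZ + dlogq[, k] * gk
    dmu[k, ] <- -colSums(dlogq[, k] * gk)
  }
  # pi enters log q additively through log pi_k; softmax-parameterized
  s <- colSums(dlogq)
  dlogit <- s - sum(s) * theta$pi
  # v enters through the t density; analytic d log Phi / d v
  dlogv <- numeric(K)
  if (!theta$cauchy_mode) {
    for (k in seq_len(K)) {
      v <- theta$v[k]; del <- st$mahalanobis[, k]
      dv <- 0.5 * (digamma((v + D) / 2) - digamma(v / 2) - D / v -
                     log1p(del / v) + (v + D) * del / (v * (v + del)))
      dlogv[k] <- sum(dlogq[, k] * dv) * v
    }
  }
  list(dZ = dZ, dmu = dmu, dlogit = dlogit, dlogv = dlogv)
}

# dL/d log q for the KL refinement loss with fixed targets P:
# row-normalization of q gives dL/dlogq = Q_norm_rowmass * ... = (q_norm - p).
kl_grad_logq <- function(P, Q_norm) Q_norm - P

# dL/d log q for the size penalty (as it appears in L1 with weight -eta2).
size_grad_logq <- function(st, upsilon) {
  N <- nrow(st$r)
  J <- colSums(st$r) / N
  fprime <- ifelse(J > upsilon, 0, -(log(pmax(J, 1e-12)) + 1))
  # dJ_c/dlogq_{i,k} = r_{i,k} (1{c=k} - r_{i,c}) / N
  A <- st$r * matrix(fprime, N, length(J), byrow = TRUE)
  (A - st$r * rowSums(A)) / N
}

#' Epoch-level composite loss
#'
#' `L1 = -L_ll + eta1 * L_lap - eta2 * L_size + eta3 * L_r`: negative
#' mixture log likelihood, Laplacian agreement with the seeding graph
#' (weight decaying across epochs), the cluster-size term, and the
#' reconstruction fidelity. Components are returned alongside the total so
#' every recorded value can be re-assembled exactly.
#'
#' @param Z Embeddings (N x D).
#' @param theta `smm_parameters` freshly fitted this epoch.
#' @param seed A [seed_similarity()].
#' @param X,Xhat Flattened images and reconstructions (N x H*W).
#' @param eta1,eta2,eta3 Component weights (`eta1` already decayed).
#' @param upsilon Size-exemption threshold.
#' @return List of class `loss_breakdown`.
#' @export
epoch_loss_L1 <- function(Z, theta, seed, X, Xhat, eta1 = 0.5, eta2 = 0.1,
                          eta3 = 0.1, upsilon = 1 / theta$K) {
  st <- smm_e_step(Z, theta)
  L_ll <- st$loglik
  L_lap <- laplacian_loss(Z, seed)
  sz <- size_loss(st, upsilon)
  L_r <- reconstruction_loss(X, Xhat)
  total <- -L_ll + eta1 * L_lap - eta2 * sz$loss + eta3 * L_r
  structure(list(total = total, L_ll = L_ll, L_lap = L_lap,
                 L_size = sz$loss, L_r = L_r, J = sz$J,
                 eta1 = eta1, eta2 = eta2, eta3 = eta3),
            class = "loss_breakdown")
}
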