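make_seed_graph <- function(S) {
  list(S = Matrix::Matrix(as.matrix(S), sparse = TRUE), degrees = Matrix::rowSums(S))
}

test_that("seeding similarity graph has the contracted structure", {
  ds <- preprocess(make_raw_dataset(n_side = 8, n_genes = 30), min_spots = 1)
  sg <- seed_similarity(ds, k_neighbors = 5)
  S <- as.matrix(sg$S)
  expect_equal(S, t(S))
  expect_true(all(Matrix::diag(sg$S) == 1))
  expect_true(all(sg$degrees > 0))
  expect_true(all(S >= 0))

  # identical expression vectors -> similarity 1; orthogonal -> 0
  m <- as.matrix(ds$counts)
  m[, 2] <- m[, 1]
  m[, 3] <- 0; m[1:20, 3] <- 1
  m[, 4] <- 0; m[21:40, 4] <- 1
  ds2 <- ds; ds2$counts <- Matrix::Matrix(m, sparse = TRUE)
  sg2 <- seed_similarity(ds2, k_neighbors = 5)
  expect_equal(sg2$S[1, 2], 1, tolerance = 1e-12)
  expect_equal(sg2$S[3, 4], 0)

  expect_error(seed_similarity(ds, k_neighbors = 30), "k_neighbors")
})

test_that("Laplacian penalty vanishes on identity graphs and is PSD", {
  Z <- matrix(rnorm(40), 10, 4)
  expect_equal(laplacian_loss(Z, make_seed_graph(Matrix::Diagonal(10))), 0,
               tolerance = 1e-12)

  # a fully-similar pair with identical embeddings contributes nothing
  S <- matrix(c(1, 1, 1, 1), 2)
  Z2 <- matrix(rnorm(3), 1, 3)[rep(1, 2), , drop = FALSE]
  expect_equal(laplacian_loss(Z2, make_seed_graph(S)), 0, tolerance = 1e-12)

  for (i in 1:20) {
    A <- matrix(runif(25), 5); A <- (A + t(A)) / 2; diag(A) <- 1
    Zr <- matrix(rnorm(15), 5, 3)
    expect_gte(laplacian_loss(Zr, make_seed_graph(A)), -1e-12)
  }

  bad <- make_seed_graph(Matrix::Diagonal(10))
  bad$degrees[3] <- 0
  expect_error(laplacian_loss(Z, bad), "zero-degree")
})

fake_stats <- function(r) structure(list(r = r), class = "smm_stats")

test_that("size penalty honors the exemption clause and hand values", {
  # all clusters above the threshold -> zero
  r <- matrix(1 / 3, 9, 3)
  out <- size_loss(fake_stats(r), upsilon = 0.2)
  expect_equal(out$loss, 0)
  expect_equal(out$J, rep(1 / 3, 3))

  # J = (0.5, 0.5), upsilon = 0.6 -> -2 * 0.5 * log 0.5 = log 2
  r2 <- cbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  expect_equal(size_loss(fake_stats(r2), 0.6)$loss, log(2), tolerance = 1e-12)

  # an empty cluster contributes a finite (clamped) value
  r3 <- cbind(rep(1, 4), rep(0, 4))
  expect_true(is.finite(size_loss(fake_stats(r3), 1)$loss))
  expect_error(size_loss(fake_stats(r), 0), "upsilon")
})

test_that("target sharpening fixes one-hot rows and preserves uniformity", {
  onehot <- diag(4)[c(1, 2, 2, 3, 4), ]
  expect_equal(target_distribution(onehot), onehot, tolerance = 1e-12)

  unif <- matrix(1 / 5, 8, 5)
  expect_equal(target_distribution(unif), unif, tolerance = 1e-12)

  # with equal column masses, sharpening cannot increase row entropy
  q <- matrix(runif(40), 8, 5); q <- q / rowSums(q)
  qe <- sweep(q, 2, colSums(q) / mean(colSums(q)), "/")
  qe <- qe / rowSums(qe)   # now approx equal column masses
  p <- target_distribution(qe)
  H <- function(x) -rowSums(ifelse(x > 0, x * log(x), 0))
  expect_true(all(H(p) <= H(qe) + 1e-8))

  expect_equal(rowSums(target_distribution(q)), rep(1, 8), tolerance = 1e-12)
  qz <- q; qz[, 2] <- 0
  expect_error(target_distribution(qz / rowSums(qz)), "zero total mass")
})

test_that("KL refinement loss is a proper divergence", {
  q <- matrix(runif(30), 6, 5); q <- q / rowSums(q)
  expect_equal(kl_clustering_loss(q, q), 0, tolerance = 1e-12)

  P <- matrix(c(1, 0), 1); Q <- matrix(c(0.5, 0.5), 1)
  expect_equal(kl_clustering_loss(P, Q), log(2), tolerance = 1e-12)

  for (i in 1:20) {
    p <- matrix(runif(12), 3, 4); p <- p / rowSums(p)
    q2 <- matrix(runif(12), 3, 4); q2 <- q2 / rowSums(q2)
    expect_gte(kl_clustering_loss(p, q2), 0)
  }
  expect_error(kl_clustering_loss(matrix(c(1, 0), 1), matrix(c(0, 1), 1)),
               "infinite")
})

test_that("epoch loss recombines exactly and matches the density oracle", {
  set.seed(12)
  Z <- matrix(rnorm(60), 20, 3)
  th <- smm_init(Z, 3, seed = 1)
  sg <- make_seed_graph(Matrix::Diagonal(20))
  X <- matrix(runif(20 * 16), 20, 16)
  Xh <- X + matrix(rnorm(20 * 16, 0, 0.1), 20, 16)

  lb <- epoch_loss_L1(Z, th, sg, X, Xh, eta1 = 0.4, eta2 = 0.2, eta3 = 0.3,
                      upsilon = 0.5)
  expect_equal(lb$total,
               -lb$L_ll + 0.4 * lb$L_lap - 0.2 * lb$L_size + 0.3 * lb$L_r,
               tolerance = 1e-10)

  # zero weights: minimizing L1 is exactly maximizing the log likelihood
  lb0 <- epoch_loss_L1(Z, th, sg, X, Xh, eta1 = 0, eta2 = 0, eta3 = 0)
  expect_equal(lb0$total, -lb0$L_ll, tolerance = 1e-12)

  # independent mixture-density oracle for L_ll via t_logpdf
  dens <- sapply(1:3, function(k)
    th$pi[k] * exp(t_logpdf(Z, th$mu[k, ], th$Sigma[[k]], th$v[k])))
  expect_equal(lb$L_ll, sum(log(rowSums(dens))), tolerance = 1e-8)
})

test_that("analytic embedding/mixture gradients match finite differences", {
  set.seed(13)
  N <- 12; D <- 3; K <- 3
  Z <- matrix(rnorm(N * D), N, D)
  th <- smm_init(Z, K, seed = 2)
  P <- matrix(runif(N * K), N, K); P <- P / rowSums(P)

  kl_of <- function(Zx, thx) {
    st <- smm_e_step(Zx, thx)
    kl_clustering_loss(P, st$r)
  }
  parts <- stgem:::density_grad_parts(Z, th)
  ch <- stgem:::density_chain(stgem:::kl_grad_logq(P, parts$st$r), parts, th)

  h <- 1e-6
  for (i in c(1, 17, 30)) {
    Zp <- Z; Zp[i] <- Zp[i] + h
    Zn <- Z; Zn[i] <- Zn[i] - h
    expect_equal(ch$dZ[i], (kl_of(Zp, th) - kl_of(Zn, th)) / (2 * h),
                 tolerance = 1e-5)
  }
  for (k in 1:K) for (j in 1:D) {
    tp <- th; tp$mu[k, j] <- tp$mu[k, j] + h
    tn <- th; tn$mu[k, j] <- tn$mu[k, j] - h
    expect_equal(ch$dmu[k, j], (kl_of(Z, tp) - kl_of(Z, tn)) / (2 * h),
                 tolerance = 1e-5)
  }
  # log-v gradient
  for (k in 1:K) {
    tp <- th; tp$v[k] <- exp(log(tp$v[k]) + h)
    tn <- th; tn$v[k] <- exp(log(tn$v[k]) - h)
    expect_equal(ch$dlogv[k], (kl_of(Z, tp) - kl_of(Z, tn)) / (2 * h),
                 tolerance = 1e-4)
  }
  # pi logits (softmax-parameterized)
  lg <- log(th$pi)
  for (k in 1:K) {
    tp <- th; lp <- lg; lp[k] <- lp[k] + h; tp$pi <- exp(lp) / sum(exp(lp))
    tn <- th; ln_ <- lg; ln_[k] <- ln_[k] - h; tn$pi <- exp(ln_) / sum(exp(ln_))
    expect_equal(ch$dlogit[k], (kl_of(Z, tp) - kl_of(Z, tn)) / (2 * h),
                 tolerance = 1e-5)
  }

  # size-loss gradient through the responsibilities
  ups <- 0.4
  sz_of <- function(Zx) size_loss(smm_e_step(Zx, th), ups)$loss
  dZs <- stgem:::density_chain(stgem:::size_grad_logq(parts$st, ups),
                               parts, th)$dZ
  for (i in c(2, 20)) {
    Zp <- Z; Zp[i] <- Zp[i] + h
    Zn <- Z; Zn[i] <- Zn[i] - h
    expect_equal(dZs[i], (sz_of(Zp) - sz_of(Zn)) / (2 * h), tolerance = 1e-5)
  }

  # log-likelihood gradient
  ll_of <- function(Zx) smm_e_step(Zx, th)$loglik
  dZl <- stgem:::loglik_grad_z(parts, th)
  for (i in c(5, 25)) {
    Zp <- Z; Zp[i] <- Zp[i] + h
    Zn <- Z; Zn[i] <- Zn[i] - h
    expect_equal(dZl[i], (ll_of(Zp) - ll_of(Zn)) / (2 * h), tolerance = 1e-5)
  }
})
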