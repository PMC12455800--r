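
# MAP-regularized Student's-t mixture model over gene embeddings.
#
# The t distribution is handled through its Gaussian scale-mixture form:
# ingredient zeta ~ Gamma(v/2, v/2) with z | zeta ~ N(mu, Sigma/zeta). The
# E-step therefore yields two expected sufficient statistics per gene and
# component: the responsibility and the posterior mean of zeta,
# (v + D) / (v + mahalanobis^2). The M-step maximizes the expected complete
# posterior under a symmetric Dirichlet prior on the weights and a
# normal-inverse-Wishart prior on each (mu_k, Sigma_k); degrees of freedom
# are improved (not maximized globally) by a bounded 1-D search, a valid
# generalized-EM step.

V_BOUNDS <- c(0.1, 200)

#' Prior specification for the MAP mixture fit
#'
#' Weakly informative conjugate priors: symmetric Dirichlet on the weights,
#' normal-inverse-Wishart on each component's mean and covariance. Defaults
#' center the NIW on the data with a small scatter, enough to keep every
#' covariance positive definite without materially biasing large components.
#'
#' @param Z Embedding matrix (rows = genes), used for data-driven defaults.
#' @param alpha0 Dirichlet concentration (>= 1).
#' @param kappa0 Prior mean strength.
#' @param rho0 NIW degrees of freedom (> D - 1); default `D + 2`.
#' @param m0 Prior mean; default the data mean.
#' @param S0 Prior scatter; default `0.01 * D * diag(diag(cov(Z)))`.
#' @return A list of class `smm_priors`.
#' @export
smm_priors <- function(Z, alpha0 = 1.01, kappa0 = 0.01, rho0 = NULL,
                       m0 = NULL, S0 = NULL) {
  D <- ncol(Z)
  if (is.null(rho0)) rho0 <- D + 2
  if (is.null(m0)) m0 <- colMeans(Z)
  if (is.null(S0)) {
    dv <- apply(Z, 2, stats::var)
    dv[dv <= 0] <- 1e-6
    S0 <- diag(0.01 * D * dv, D)
  }
  if (alpha0 < 1) stopf("alpha0 must be >= 1")
  if (kappa0 <= 0) stopf("kappa0 must be > 0")
  if (rho0 <= D - 1) stopf("rho0 must exceed D - 1")
  structure(list(alpha0 = alpha0, m0 = m0, kappa0 = kappa0, S0 = S0,
                 rho0 = rho0), class = "smm_priors")
}

#' Multivariate Student's-t log density
#'
#' Cholesky-based evaluation, numerically stable for very large Mahalanobis
#' distances and very large degrees of freedom (Gaussian limit).
#'
#' @param z A D-vector or an N x D matrix of points.
#' @param mu Location D-vector.
#' @param Sigma D x D positive-definite scale matrix.
#' @param v Degrees of freedom (> 0); `v = 1` is multivariate Cauchy.
#' @return Log density (vector if `z` is a matrix).
#' @export
t_logpdf <- function(z, mu, Sigma, v) {
  if (v <= 0) stopf("degrees of freedom must be positive")
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  D <- ncol(z)
  Sigma <- as.matrix(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e)
    stopf("scale matrix is not positive definite"))
  delta <- mahalanobis_sq(z, mu, L)
  t_logpdf_delta(delta, D, L, v)
}

# squared Mahalanobis distances given the upper Cholesky factor of Sigma
mahalanobis_sq <- function(Z, mu, L) {
  U <- backsolve(L, t(Z) - mu, transpose = TRUE)
  colSums(U^2)
}

t_logpdf_delta <- function(delta, D, L, v) {
  logdet <- 2 * sum(log(diag(L)))
  lgamma((v + D) / 2) - lgamma(v / 2) - (D / 2) * log(v * pi) -
    logdet / 2 - ((v + D) / 2) * log1p(delta / v)
}

#' Initialize mixture parameters
#'
#' k-means++ hard clustering of the embeddings seeds the means; within-cluster
#' covariances (plus a small ridge) seed the scales; cluster proportions seed
#' the weights; degrees of freedom start at `v_init`.
#'
#' @param Z N x D embedding matrix.
#' @param K Number of components.
#' @param init `"kmeans"` or `"random"` (random rows as means).
#' @param seed Integer seed.
#' @param v_init Initial degrees of freedom.
#' @param cauchy_mode Fix all degrees of freedom at 1.
#' @return A list of class `smm_parameters` with fields `K, pi, mu, Sigma, v,
#'   cauchy_mode` (`Sigma` a list of D x D matrices).
#' @export
smm_init <- function(Z, K, init = c("kmeans", "random"), seed = 1,
                     v_init = 10, cauchy_mode = FALSE) {
  init <- match.arg(init)
  N <- nrow(Z); D <- ncol(Z)
  if (K > N) stopf("K (%d) exceeds the number of points (%d)", K, N)
  with_seed(seed, {
    if (init == "kmeans" && K > 1) {
      centers <- kmeanspp_centers(Z, K)
      km <- suppressWarnings(stats::kmeans(Z, centers = centers, iter.max = 50))
      lab <- km$cluster
      mu <- km$centers
    } else if (K == 1) {
      lab <- rep(1L, N)
      mu <- matrix(colMeans(Z), 1)
    } else {
      idx <- sample.int(N, K)
      mu <- Z[idx, , drop = FALSE]
      d2 <- vapply(seq_len(K), function(k) rowSums(sweep(Z, 2, mu[k, ])^2),
                   numeric(N))
      lab <- max.col(-d2, ties.method = "first")
    }
    Sigma <- lapply(seq_len(K), function(k) {
      Zk <- Z[lab == k, , drop = FALSE]
      S <- if (nrow(Zk) > 1) stats::cov(Zk) else diag(1, D)
      S + diag(1e-4, D)
    })
    pi_k <- tabulate(lab, K) / N
    pi_k <- pmax(pi_k, 1e-6); pi_k <- pi_k / sum(pi_k)
    structure(list(K = K, pi = pi_k, mu = mu, Sigma = Sigma,
                   v = rep(if (cauchy_mode) 1 else v_init, K),
                   cauchy_mode = cauchy_mode),
              class = "smm_parameters")
  })
}

kmeanspp_centers <- function(Z, K) {
  N <- nrow(Z)
  centers <- matrix(0, K, ncol(Z))
  centers[1, ] <- Z[sample.int(N, 1), ]
  d2 <- rowSums(sweep(Z, 2, centers[1, ])^2)
  for (k in 2:K) {
    p <- d2 / sum(d2)
    centers[k, ] <- Z[sample.int(N, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(Z, 2, centers[k, ])^2))
  }
  centers
}

#' E-step: expected sufficient statistics
#'
#' Computes the unnormalized component densities `q_raw` (weight x t density),
#' responsibilities by log-sum-exp row normalization, the expected
#' scale-mixture weights `(v + D) / (v + mahalanobis^2)`, and hard
#' assignments.
#'
#' @param Z N x D embedding matrix.
#' @param theta An `smm_parameters` object.
#' @return A list of class `smm_stats`: `log_q`, `q_raw`, `r`, `zeta`,
#'   `mahalanobis`, `hard`, `loglik`.
#' @export
smm_e_step <- function(Z, theta) {
  if (!all(is.finite(Z))) {
    bad <- which(!stats::complete.cases(Z) | rowSums(!is.finite(Z)) > 0)[1]
    stopf("non-finite embedding in row %d", bad)
  }
  N <- nrow(Z); D <- ncol(Z); K <- theta$K
  log_q <- matrix(0, N, K)
  delta <- matrix(0, N, K)
  for (k in seq_len(K)) {
    L <- chol(theta$Sigma[[k]])
    delta[, k] <- mahalanobis_sq(Z, theta$mu[k, ], L)
    log_q[, k] <- log(theta$pi[k]) + t_logpdf_delta(delta[, k], D, L, theta$v[k])
  }
  lse <- log_sum_exp_rows(log_q)
  r <- exp(log_q - lse)
  zeta <- sweep(delta, 2, theta$v, "+")
  zeta <- sweep(1 / zeta, 2, theta$v + D, "*")
  structure(list(log_q = log_q, q_raw = exp(log_q), r = r, zeta = zeta,
                 mahalanobis = delta,
                 hard = max.col(r, ties.method = "first"),
                 loglik = sum(lse)), class = "smm_stats")
}

# Expected complete-data contribution of v for component k (terms depending
# on v only), given previous-iteration statistics; used by the GEM update.
v_objective <- function(v, r_k, zeta_k, elog_zeta_k) {
  sum(r_k * ((v / 2) * log(v / 2) - lgamma(v / 2) +
             (v / 2) * (elog_zeta_k - zeta_k)))
}

#' MAP M-step
#'
#' Conjugate closed-form updates of weights, means and scales under the
#' Dirichlet/NIW priors with scale-mixture-weighted data, plus a bounded 1-D
#' generalized-EM improvement of each component's degrees of freedom
#' (skipped in Cauchy mode). A component whose responsibility mass collapses
#' is re-seeded at the least-claimed point.
#'
#' @param Z N x D embedding matrix.
#' @param stats An `smm_stats` from [smm_e_step()] under `theta_prev`.
#' @param priors An [smm_priors()] object.
#' @param theta_prev Parameters that produced `stats`.
#' @return Updated `smm_parameters`.
#' @export
smm_m_step <- function(Z, stats, priors, theta_prev) {
  N <- nrow(Z); D <- ncol(Z); K <- theta_prev$K
  r <- stats$r; zeta <- stats$zeta
  theta <- theta_prev

  nk <- colSums(r)
  dead <- which(nk < 1e-8)
  for (k in dead) {
    i <- which.min(apply(r, 1, max))
    message(sprintf("re-seeding degenerate component %d at point %d", k, i))
    theta$mu[k, ] <- Z[i, ]
    theta$Sigma[[k]] <- priors$S0 / (priors$rho0 + D + 2) + diag(1e-3, D)
    r[, k] <- pmax(r[, k], 1e-6)
    r <- r / rowSums(r)
    nk <- colSums(r)
  }

  pi_new <- (nk + priors$alpha0 - 1)
  pi_new <- pi_new / sum(pi_new)

  w <- r * zeta
  sw <- colSums(w)
  mu_new <- theta$mu
  Sigma_new <- theta$Sigma
  v_new <- theta$v
  for (k in seq_len(K)) {
    wk <- w[, k]
    mu_k <- (priors$kappa0 * priors$m0 + colSums(Z * wk)) / (priors$kappa0 + sw[k])
    Zc <- sweep(Z, 2, mu_k)
    Sw <- crossprod(Zc * sqrt(wk))
    dmu <- mu_k - priors$m0
    Sigma_k <- (priors$S0 + Sw + priors$kappa0 * tcrossprod(dmu)) /
      (priors$rho0 + D + 2 + nk[k])
    Sigma_k <- (Sigma_k + t(Sigma_k)) / 2
    mu_new[k, ] <- mu_k
    Sigma_new[[k]] <- Sigma_k
    if (!theta$cauchy_mode) {
      elog <- digamma((theta_prev$v[k] + D) / 2) -
        log((theta_prev$v[k] + stats$mahalanobis[, k]) / 2)
      opt <- stats::optimize(v_objective, interval = V_BOUNDS, maximum = TRUE,
                             r_k = r[, k], zeta_k = zeta[, k], elog_zeta_k = elog,
                             tol = 1e-4)
      # GEM: accept only if it improves the expected complete-data term
      if (opt$objective >= v_objective(theta_prev$v[k], r[, k], zeta[, k], elog))
        v_new[k] <- opt$maximum
    }
  }
  theta$pi <- pi_new
  theta$mu <- mu_new
  theta$Sigma <- Sigma_new
  theta$v <- if (theta$cauchy_mode) rep(1, K) else v_new
  theta
}

ldirichlet <- function(p, alpha0) {
  K <- length(p)
  lgamma(K * alpha0) - K * lgamma(alpha0) + sum((alpha0 - 1) * log(pmax(p, 1e-300)))
}

lmvgamma <- function(D, a) (D * (D - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))

lniw <- function(mu, Sigma, priors) {
  D <- length(mu)
  L <- chol(Sigma)
  logdet <- 2 * sum(log(diag(L)))
  Sinv_dmu <- backsolve(L, backsolve(L, mu - priors$m0, transpose = TRUE))
  l_norm <- -D / 2 * log(2 * pi) + D / 2 * log(priors$kappa0) - logdet / 2 -
    priors$kappa0 / 2 * sum((mu - priors$m0) * Sinv_dmu)
  S0L <- chol(priors$S0)
  logdetS0 <- 2 * sum(log(diag(S0L)))
  tr <- sum(diag(backsolve(L, backsolve(L, priors$S0, transpose = TRUE))))
  l_iw <- (priors$rho0 / 2) * logdetS0 - (priors$rho0 * D / 2) * log(2) -
    lmvgamma(D, priors$rho0 / 2) - ((priors$rho0 + D + 1) / 2) * logdet - tr / 2
  l_norm + l_iw
}

#' Penalized (posterior) objective of the mixture
#'
#' Observed-data log likelihood plus log prior densities; the quantity the
#' MAP-EM sweep never decreases (up to the generalized degrees-of-freedom
#' step, which only improves its own term).
#'
#' @inheritParams smm_e_step
#' @param priors An [smm_priors()].
#' @return A scalar.
#' @export
smm_objective <- function(Z, theta, priors) {
  st <- smm_e_step(Z, theta)
  st$loglik + ldirichlet(theta$pi, priors$alpha0) +
    sum(vapply(seq_len(theta$K), function(k)
      lniw(theta$mu[k, ], theta$Sigma[[k]], priors), numeric(1)))
}

#' Fit the MAP-regularized Student's-t mixture by EM
#'
#' Alternates [smm_e_step()] and [smm_m_step()] until the relative change of
#' the penalized objective drops below `tol` or `max_iter` sweeps elapse.
#' Deterministic given `seed`.
#'
#' @inheritParams smm_init
#' @param priors An [smm_priors()]; defaults from the data.
#' @param max_iter Maximum EM sweeps.
#' @param tol Relative objective-change tolerance.
#' @param theta0 Optional warm-start parameters (skips initialization).
#' @return List of class `smm_fit`: `theta`, `stats`, `objective` (trace),
#'   `iterations`, `converged`.
#' @export
fit_smm_map <- function(Z, K, priors = NULL, init = c("kmeans", "random"),
                        max_iter = 100, tol = 1e-6, seed = 1,
                        cauchy_mode = FALSE, v_init = 10, theta0 = NULL) {
  Z <- as.matrix(Z)
  if (K < 1) stopf("K must be at least 1")
  if (K > nrow(Z)) stopf("K (%d) exceeds N (%d)", K, nrow(Z))
  if (is.null(priors)) priors <- smm_priors(Z)
  theta <- theta0 %||% smm_init(Z, K, match.arg(init), seed = seed,
                                v_init = v_init, cauchy_mode = cauchy_mode)
  trace <- numeric(0)
  obj_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- smm_e_step(Z, theta)
    theta <- smm_m_step(Z, st, priors, theta)
    obj <- smm_objective(Z, theta, priors)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) < tol * (abs(obj_prev) + 1e-12)) {
      converged <- TRUE
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  st <- smm_e_step(Z, theta)
  structure(list(theta = theta, stats = st, objective = trace,
                 iterations = length(trace), converged = converged),
            class = "smm_fit")
}

#' @export
print.smm_fit <- function(x, ...) {
  cat(sprintf("<smm_fit> K=%d, %d EM sweeps, objective %.4f (%s)\n",
              x$theta$K, x$iterations, utils::tail(x$objective, 1),
              if (x$converged) "converged" else "max_iter"))
  invisible(x)
}
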