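test_that("t log density matches closed forms and the scale-mixture quadrature", {
  # Cauchy (v = 1, D = 1) at the mode: density 1/pi
  expect_equal(exp(t_logpdf(0, 0, matrix(1), 1)), 1 / pi, tolerance = 1e-12)

  # large v converges to the Gaussian density
  mu <- c(0.3, -0.2)
  S <- matrix(c(1.3, 0.4, 0.4, 0.9), 2)
  for (z1 in c(-2, 0, 1.5)) for (z2 in c(-1, 0.5)) {
    z <- c(z1, z2)
    lg <- -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * mahalanobis(matrix(z, 1), mu, S)
    expect_equal(t_logpdf(z, mu, S, 1e6), as.numeric(lg), tolerance = 1e-4)
  }

  # numerical quadrature of the Gamma scale mixture
  for (v in c(2, 5, 30)) {
    # D = 1
    f1 <- function(zeta, z) dnorm(z, 0, sqrt(2 / zeta)) *
      dgamma(zeta, v / 2, rate = v / 2)
    for (z in c(-1.5, 0.2, 3)) {
      q <- integrate(f1, 0, Inf, z = z, rel.tol = 1e-10)$value
      expect_equal(exp(t_logpdf(z, 0, matrix(2), v)), q, tolerance = 1e-6)
    }
    # D = 2
    f2 <- function(zeta, z) {
      vapply(zeta, function(s) {
        Sc <- S / s
        exp(-log(2 * pi) - 0.5 * log(det(Sc)) -
              0.5 * mahalanobis(matrix(z, 1), mu, Sc)) *
          dgamma(s, v / 2, rate = v / 2)
      }, numeric(1))
    }
    z <- c(0.8, -0.5)
    q <- integrate(f2, 0, Inf, z = z, rel.tol = 1e-10)$value
    expect_equal(exp(t_logpdf(z, mu, S, v)), q, tolerance = 1e-6)
  }

  expect_error(t_logpdf(0, 0, matrix(-1), 3), "positive definite")
})

test_that("E-step statistics behave at closed-form points", {
  set.seed(1)
  Z <- matrix(rnorm(60), 20, 3)
  th1 <- smm_init(Z, 1, seed = 1)
  st1 <- smm_e_step(Z, th1)
  expect_equal(unname(st1$r[, 1]), rep(1, 20))

  th <- smm_init(Z, 3, seed = 1)
  st <- smm_e_step(Z, th)
  expect_lt(max(abs(rowSums(st$r) - 1)), 1e-10)
  expect_true(all(st$zeta > 0))
  expect_true(all(st$hard %in% 1:3))

  # z at a component mean: zeta = (v + D) / v
  zt <- matrix(th$mu[2, ], 1)
  st2 <- smm_e_step(zt, th)
  expect_equal(st2$zeta[1, 2], (th$v[2] + 3) / th$v[2], tolerance = 1e-12)

  Zbad <- Z; Zbad[7, 2] <- NaN
  expect_error(smm_e_step(Zbad, th), "row 7")
})

test_that("MAP M-step reduces to maximum likelihood under flat priors", {
  set.seed(2)
  Z <- matrix(rnorm(200), 50, 4)
  D <- 4
  flat <- structure(list(alpha0 = 1, m0 = rep(0, D), kappa0 = 1e-12,
                         S0 = diag(1e-12, D), rho0 = D - 1 + 1e-9),
                    class = "smm_priors")
  th <- smm_init(Z, 1, seed = 3)
  st <- smm_e_step(Z, th)
  out <- smm_m_step(Z, st, flat, th)
  wmean <- colSums(Z * st$zeta[, 1]) / sum(st$zeta[, 1])
  expect_equal(out$mu[1, ], wmean, tolerance = 1e-6)

  th3 <- smm_init(Z, 3, seed = 3)
  st3 <- smm_e_step(Z, th3)
  out3 <- smm_m_step(Z, st3, flat, th3)
  expect_equal(out3$pi, colSums(st3$r) / nrow(Z), tolerance = 1e-9)
})

test_that("the penalized objective never decreases across EM sweeps", {
  set.seed(4)
  Z <- rbind(rmvt_fix(70, c(0, 0, 0, 0), diag(4), 6),
             rmvt_fix(70, c(4, 4, 0, 0), diag(4), 6),
             rmvt_fix(60, c(-4, 3, 2, 0), diag(4), 6))
  pri <- smm_priors(Z)
  for (s in 1:20) {
    fit <- fit_smm_map(Z, 3, pri, init = "random", max_iter = 12, seed = s)
    d <- diff(fit$objective)
    expect_true(all(d >= -1e-8 * (abs(fit$objective[-length(fit$objective)]) + 1)))
  }
})

test_that("well-separated components are recovered accurately and robustly", {
  D <- 8; n <- 500
  set.seed(5)
  mus <- rbind(rep(0, D), c(rep(8, 4), rep(0, 4)), c(rep(-8, 4), rep(4, 4)))
  Z <- rbind(rmvt_fix(n, mus[1, ], diag(D), 5),
             rmvt_fix(n, mus[2, ], diag(D), 5),
             rmvt_fix(n, mus[3, ], diag(D), 5))
  truth <- rep(1:3, each = n)
  fit <- fit_smm_map(Z, 3, max_iter = 60, seed = 6)
  expect_gte(ari(fit$stats$hard, truth), 0.95)

  # mean estimation error below half a (unit) standard deviation
  perm <- apply(fit$theta$mu, 1, function(m)
    which.min(colSums((t(mus) - m)^2)))
  err <- sqrt(rowSums((fit$theta$mu - mus[perm, ])^2))
  expect_true(all(err < 0.5))

  # 2% gross outliers at 20 sigma barely move the t-mixture means...
  n_out <- round(0.02 * nrow(Z))
  Zo <- rbind(Z, matrix(20, n_out, D))
  fit_o <- fit_smm_map(Zo, 3, max_iter = 60, seed = 6)
  perm_o <- apply(fit_o$theta$mu, 1, function(m)
    which.min(colSums((t(mus) - m)^2)))
  shift_t <- sqrt(rowSums((fit_o$theta$mu - mus[perm_o, ])^2))
  expect_true(all(shift_t < 0.5))

  # ...whereas a Gaussian mixture (independent implementation) shifts more
  suppressMessages(withr::local_package("mclust"))
  gm <- mclust::Mclust(Zo, G = 3, modelNames = "EII", verbose = FALSE)
  gmu <- t(gm$parameters$mean)
  perm_g <- apply(gmu, 1, function(m) which.min(colSums((t(mus) - m)^2)))
  shift_g <- sqrt(rowSums((gmu - mus[perm_g, ])^2))
  expect_gt(max(shift_g), max(shift_t))
})

test_that("EM is deterministic and label-permutation equivariant", {
  set.seed(7)
  Z <- matrix(rnorm(300), 100, 3)
  f1 <- fit_smm_map(Z, 4, max_iter = 10, seed = 9)
  f2 <- fit_smm_map(Z, 4, max_iter = 10, seed = 9)
  expect_identical(f1$theta, f2$theta)

  # permuting the initial component order permutes the fit
  pri <- smm_priors(Z)
  th <- smm_init(Z, 4, seed = 9)
  pp <- c(3, 1, 4, 2)
  thp <- th
  thp$pi <- th$pi[pp]; thp$mu <- th$mu[pp, ]
  thp$Sigma <- th$Sigma[pp]; thp$v <- th$v[pp]
  a <- fit_smm_map(Z, 4, pri, theta0 = th, max_iter = 5, seed = 1)
  b <- fit_smm_map(Z, 4, pri, theta0 = thp, max_iter = 5, seed = 1)
  expect_equal(b$theta$mu, a$theta$mu[pp, ], tolerance = 1e-8)
  expect_equal(b$theta$pi, a$theta$pi[pp], tolerance = 1e-8)
})

test_that("Cauchy mode pins the degrees of freedom at one", {
  set.seed(8)
  Z <- matrix(rnorm(240), 80, 3)
  fc <- fit_smm_map(Z, 3, max_iter = 10, seed = 2, cauchy_mode = TRUE)
  expect_equal(fc$theta$v, rep(1, 3))

  # a free-v parameter set clamped to v = 1 produces the identical E-step
  th <- fc$theta; th$cauchy_mode <- FALSE
  expect_equal(smm_e_step(Z, th)$r, fc$stats$r, tolerance = 1e-12)

  expect_error(fit_smm_map(Z, 90, seed = 1), "exceeds")
})
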