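# linear-Gaussian surrogate shared across blocks
make_linear_problem <- function(n = 120, N = 4, sigma2 = 0.25, seed = 42) {
  set.seed(seed)
  G <- matrix(rnorm(n * N), n, N)
  theta_true <- rnorm(N, sd = 0.5)
  y <- as.vector(G %*% theta_true) + rnorm(n, sd = sqrt(sigma2))
  priors <- list(mean = setNames(rep(0, N), paste0("p", 1:N)),
                 var = rep(1, N))
  list(G = G, y = y, theta_true = theta_true, sigma2 = sigma2,
       priors = priors, forward = function(th) as.vector(G %*% th))
}

test_that("a single E-step from the prior mean solves the conjugate problem", {
  pb <- make_linear_problem()
  lam <- log(1 / pb$sigma2)
  prec <- identity_precision(length(pb$y), lam)
  jac <- erpdcm:::fd_jacobian(pb$forward, pb$priors$mean)
  es <- e_step(pb$y, pb$forward, pb$forward(pb$priors$mean), jac$J,
               pb$priors$mean, lam, pb$priors, prec)
  oracle <- conjugate_posterior(pb$y, pb$G, 0, pb$priors$var[1], pb$sigma2)
  expect_true(es$accepted)
  expect_lt(max(abs(es$theta - oracle$mean)), 1e-8)
})

test_that("a perfect fit at the prior mean proposes no move and frozen
           parameters never move", {
  pb <- make_linear_problem()
  y0 <- pb$forward(pb$priors$mean)  # zero everywhere
  prec <- identity_precision(length(y0), 0)
  jac <- erpdcm:::fd_jacobian(pb$forward, pb$priors$mean)
  es <- e_step(y0, pb$forward, y0, jac$J, pb$priors$mean, 0, pb$priors, prec)
  expect_equal(es$theta, pb$priors$mean)
  # freeze parameter 2 with zero prior variance
  pr <- pb$priors; pr$var[2] <- 0
  es2 <- e_step(pb$y, pb$forward, pb$forward(pr$mean), jac$J, pr$mean,
                log(1 / pb$sigma2), pr, prec)
  expect_equal(unname(es2$theta[2]), 0)
  expect_gt(max(abs(es2$theta[-2])), 0)
})

test_that("ReML recovers the noise variance and scales equivariantly", {
  set.seed(7)
  n <- 2000
  G <- matrix(rnorm(n * 3), n, 3)
  sigma2 <- 0.5
  e <- rnorm(n, sd = sqrt(sigma2))
  priors <- list(mean = setNames(rep(0, 3), paste0("p", 1:3)),
                 var = rep(1, 3))
  prec <- identity_precision(n)
  lam <- m_step(e, G, 0, prec, priors, n_iter = 20)
  expect_lt(abs(exp(-lam) / sigma2 - 1), 0.1)
  # doubling the residuals quadruples the fitted variance
  lam2 <- m_step(2 * e, G, 0, prec, priors, n_iter = 20)
  expect_equal(exp(-lam2) / exp(-lam), 4, tolerance = 1e-3)
})

test_that("zero residuals push the log-precision up to the clip", {
  set.seed(1)
  G <- matrix(rnorm(100), 50, 2)
  priors <- list(mean = c(a = 0, b = 0), var = rep(1, 2))
  prec <- identity_precision(50)
  lam <- 0
  trace <- numeric(6)
  for (k in 1:6) {
    lam <- m_step(rep(0, 50), G, lam, prec, priors, n_iter = 8)
    trace[k] <- lam
  }
  expect_true(all(diff(c(0, trace)) >= 0))
  expect_gt(trace[1], 0)
  expect_equal(trace[6], 32)   # saturates at the clip
  lam_hi <- m_step(rep(0, 50), G, 31.5, prec, priors, n_iter = 8)
  expect_lte(lam_hi, 32)
})

test_that("free energy equals its closed form at a perfect prior-mean fit", {
  pb <- make_linear_problem()
  y0 <- pb$forward(pb$priors$mean)
  lam <- 1.3
  prec <- identity_precision(length(y0), lam)
  jac <- erpdcm:::fd_jacobian(pb$forward, pb$priors$mean)
  Fv <- free_energy(y0, y0, pb$priors$mean, lam, pb$priors, prec, jac$J)
  n <- length(y0)
  P <- crossprod(pb$G) * exp(lam) + diag(1, 4)
  F_closed <- 0.5 * n * lam - 0.5 * as.numeric(determinant(P)$modulus) -
    0.5 * n * log(2 * pi)
  expect_equal(Fv, F_closed, tolerance = 1e-10)
})

test_that("free energy peaks at the analytic optimum of a linear model", {
  pb <- make_linear_problem()
  lam <- log(1 / pb$sigma2)
  prec <- identity_precision(length(pb$y), lam)
  jac <- erpdcm:::fd_jacobian(pb$forward, pb$priors$mean)
  oracle <- conjugate_posterior(pb$y, pb$G, 0, 1, pb$sigma2)
  F_opt <- free_energy(pb$y, pb$forward(oracle$mean), oracle$mean, lam,
                       pb$priors, prec, jac$J)
  for (k in 1:5) {
    th <- oracle$mean + rnorm(4, sd = 0.2)
    expect_lt(free_energy(pb$y, pb$forward(th), th, lam, pb$priors, prec,
                          jac$J), F_opt)
  }
})

test_that("full inversion of the linear surrogate matches the conjugate
           closed form in a few iterations", {
  pb <- make_linear_problem()
  lam <- log(1 / pb$sigma2)
  post <- invert(pb$y, pb$forward, pb$priors,
                 identity_precision(length(pb$y), lam),
                 options = list(update_lambda = FALSE))
  oracle <- conjugate_posterior(pb$y, pb$G, 0, 1, pb$sigma2)
  expect_true(post$converged)
  expect_lte(post$iterations, 3L)
  expect_lt(max(abs(post$mean - oracle$mean)), 1e-6)
  expect_lt(max(abs(post$cov - oracle$cov)), 1e-6)
  expect_equal(post$F_trace[length(post$F_trace)], oracle$log_marginal,
               tolerance = 1e-6)
  expect_true(all(diff(post$F_trace) >= 0))
})

test_that("serial and pooled Jacobian backends give identical inversions", {
  d <- recovery_study_design()
  ds <- simulate_erp(d$spec, d$theta_true, d$leadfield, d$input, snr = 10,
                     seed = 3, grid = seq(0, 200, by = 4))
  opts <- list(max_iter = 6L)
  ps <- dcm_invert(ds, d$spec, d$leadfield, input = d$input,
                   backend = "serial", options = opts)
  pp <- dcm_invert(ds, d$spec, d$leadfield, input = d$input,
                   backend = "pool", strategy = "blockX", workers = 2L,
                   options = opts)
  expect_lt(max(abs(ps$F_trace - pp$F_trace)), 1e-10)
  expect_equal(ps$mean, pp$mean)
})
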