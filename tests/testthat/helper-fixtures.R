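# shared fixtures: a small two-source model (1 -> 2 forward, 2 -> 1 backward,
# input to source 1) and a fast grid
two_source_spec <- function(...) {
  model_spec(2,
             F_mask = matrix(c(0, 1, 0, 0), 2, 2),
             B_mask = matrix(c(0, 0, 1, 0), 2, 2),
             U_mask = c(TRUE, FALSE), ...)
}

fast_grid <- seq(0, 200, by = 2)

# central finite-difference oracle for the system Jacobian
fd_system_jacobian <- function(x, u, spec, theta, h = 1e-6) {
  d <- length(x)
  vapply(seq_len(d), function(i) {
    e <- rep(0, d); e[i] <- h
    (state_derivative(x + e, u, spec, theta) -
       state_derivative(x - e, u, spec, theta)) / (2 * h)
  }, numeric(d))
}

# linear-Gaussian conjugate posterior and log marginal likelihood
conjugate_posterior <- function(y, G, prior_mean, prior_var, sigma2) {
  P <- diag(1 / prior_var, ncol(G)) + crossprod(G) / sigma2
  S <- solve(P)
  m <- S %*% (crossprod(G, y) / sigma2 + prior_mean / prior_var)
  Sy <- diag(sigma2, length(y)) + G %*% diag(prior_var, ncol(G)) %*% t(G)
  llm <- -0.5 * (length(y) * log(2 * pi) +
                   as.numeric(determinant(Sy)$modulus) +
                   as.numeric(t(y) %*% solve(Sy, y)))
  list(mean = as.numeric(m), cov = S, log_marginal = llm)
}
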