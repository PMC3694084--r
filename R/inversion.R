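#' Observation-noise precision model
#'
#' The observation precision is a mixture of fixed diagonal components scaled
#' by log-precision hyperparameters: \eqn{\Pi(\lambda) = \sum_i e^{\lambda_i} Q_i}.
#' Components are stored as diagonal vectors over the stacked response.
#'
#' @param Q list of nonnegative diagonal vectors (equal lengths); at least one
#' @param lambda initial log-precisions, one per component
#' @return object of class `erpdcm_precision`
#' @export
precision_model <- function(Q, lambda = rep(0, length(Q))) {
  if (length(Q) == 0) stop("at least one precision component is required")
  n <- length(Q[[1]])
  stopifnot(all(vapply(Q, length, integer(1)) == n),
            all(unlist(Q) >= 0), length(lambda) == length(Q))
  if (!all(Reduce(`+`, Q) > 0))
    stop("precision components must jointly cover every sample")
  structure(list(Q = Q, lambda = as.numeric(lambda), n = n),
            class = "erpdcm_precision")
}

#' Single identity precision component
#'
#' @param n stacked response length
#' @param lambda initial log-precision
#' @export
identity_precision <- function(n, lambda = 0)
  precision_model(list(rep(1, n)), lambda)

#' Per-channel precision components for a stacked multi-condition response
#'
#' One identity component per sensor, shared across time points and
#' conditions.
#'
#' @param n_channels,n_time,n_conditions stacking dimensions (channels vary
#'   fastest, then time, then condition)
#' @param lambda initial log-precision (recycled per channel)
#' @export
channel_precision <- function(n_channels, n_time, n_conditions = 1,
                              lambda = 0) {
  chan <- rep(rep(seq_len(n_channels), times = n_time), times = n_conditions)
  Q <- lapply(seq_len(n_channels), function(c) as.numeric(chan == c))
  precision_model(Q, rep_len(lambda, n_channels))
}

# diagonal of Pi(lambda)
pi_diagonal <- function(precision, lambda) {
  d <- numeric(precision$n)
  for (i in seq_along(precision$Q))
    d <- d + exp(lambda[i]) * precision$Q[[i]]
  d
}

# log-determinant of a symmetric positive-definite matrix via Cholesky
logdet <- function(M) 2 * sum(log(diag(chol(M))))

# posterior precision over the free parameters, with a logged ridge when
# numerically singular
posterior_precision <- function(J, pi_d, prior_var, free) {
  Jf <- J[, free, drop = FALSE]
  P <- crossprod(Jf, Jf * pi_d) + diag(1 / prior_var[free], sum(free))
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-8 * sum(diag(P)) / sum(free)
    warning("posterior precision numerically singular; adding ridge ",
            signif(ridge, 3), call. = FALSE)
    P <- P + diag(ridge, sum(free))
    ch <- chol(P)
  }
  list(P = P, chol = ch)
}

#' Variational-Laplace free energy
#'
#' The bound on log model evidence that both EM steps ascend:
#' \deqn{F = -\tfrac12 e^T\Pi e + \tfrac12\log|\Pi|
#'   - \tfrac12(\theta-\mu)^T\Sigma_\theta^{-1}(\theta-\mu)
#'   + \tfrac12\log\frac{|\Sigma_{post}|}{|\Sigma_\theta|}
#'   - \tfrac{n}{2}\log 2\pi}
#' with residual `e = y - h(theta)` and the posterior covariance from the
#' Gauss-Newton approximation at the supplied response Jacobian. Frozen
#' parameters (zero prior variance) are excluded from the prior and posterior
#' terms.
#'
#' @param y stacked observed response
#' @param h stacked predicted response at `theta`
#' @param theta parameter vector
#' @param lambda log-precisions
#' @param priors list with `mean` and `var`
#' @param precision an `erpdcm_precision`
#' @param J response Jacobian matrix (rows = stacked response)
#' @return free energy in nats (finite, or an error naming the offending
#'   component)
#' @export
free_energy <- function(y, h, theta, lambda, priors, precision, J) {
  e <- y - h
  pi_d <- pi_diagonal(precision, lambda)
  free <- priors$var > 0
  pp <- posterior_precision(J, pi_d, priors$var, free)
  dth <- (theta - priors$mean)[free]
  terms <- c(accuracy = -0.5 * sum(e^2 * pi_d),
             logdet_pi = 0.5 * sum(log(pi_d)),
             prior = -0.5 * sum(dth^2 / priors$var[free]),
             occam = 0.5 * (-logdet(pp$P) - sum(log(priors$var[free]))),
             norm = -0.5 * length(y) * log(2 * pi))
  if (!all(is.finite(terms)))
    stop("non-finite free energy; components: ",
         paste(names(terms), signif(terms, 4), sep = "=", collapse = ", "))
  sum(terms)
}

#' Gauss-Newton E-step
#'
#' Proposes an updated parameter estimate from the current response Jacobian:
#' \deqn{\Delta\theta = (J^T\Pi J + \Sigma_\theta^{-1})^{-1}
#'   \left(J^T\Pi(y-h) + \Sigma_\theta^{-1}(\mu-\theta)\right)}
#' followed by step-size halving (up to `max_halvings`) until the step does
#' not decrease the free energy. Frozen parameters never move.
#'
#' @inheritParams free_energy
#' @param forward function mapping a parameter vector to the stacked response
#' @param max_halvings maximum step halvings
#' @return list: `theta` (accepted estimate), `h` (its response), `F` (its
#'   free energy), `accepted`, `halvings`
#' @export
e_step <- function(y, forward, h, J, theta, lambda, priors, precision,
                   max_halvings = 8L) {
  pi_d <- pi_diagonal(precision, lambda)
  free <- priors$var > 0
  pp <- posterior_precision(J, pi_d, priors$var, free)
  g <- crossprod(J[, free, drop = FALSE], (y - h) * pi_d) +
    ((priors$mean - theta)[free]) / priors$var[free]
  delta <- backsolve(pp$chol, backsolve(pp$chol, g, transpose = TRUE))
  F0 <- free_energy(y, h, theta, lambda, priors, precision, J)
  for (k in 0:max_halvings) {
    th <- theta
    th[free] <- th[free] + delta / 2^k
    hk <- tryCatch(forward(th), error = function(e) NULL)
    if (is.null(hk)) next
    Fk <- tryCatch(free_energy(y, hk, th, lambda, priors, precision, J),
                   error = function(e) -Inf)
    if (Fk >= F0)
      return(list(theta = th, h = hk, F = Fk, accepted = TRUE, halvings = k))
  }
  list(theta = theta, h = h, F = F0, accepted = FALSE,
       halvings = max_halvings)
}

#' ReML M-step for the noise log-precisions
#'
#' Fisher-scoring ascent of the restricted likelihood: the gradient accounts
#' for posterior parameter uncertainty through the Gauss-Newton posterior
#' covariance, so the noise estimate is not biased by the fitted parameters.
#' Log-precisions are clipped to `[-32, 32]`.
#'
#' @param e stacked residual vector `y - h(theta)`
#' @param J response Jacobian
#' @param lambda current log-precisions
#' @param precision an `erpdcm_precision`
#' @param priors list with `mean` and `var`
#' @param n_iter Fisher-scoring iterations
#' @return updated `lambda`
#' @export
m_step <- function(e, J, lambda, precision, priors, n_iter = 8L) {
  free <- priors$var > 0
  Jf <- J[, free, drop = FALSE]
  for (it in seq_len(n_iter)) {
    pi_d <- pi_diagonal(precision, lambda)
    pp <- posterior_precision(J, pi_d, priors$var, free)
    Sigma_post <- chol2inv(pp$chol)
    g <- H <- NULL
    g <- vapply(seq_along(precision$Q), function(i) {
      qi <- exp(lambda[i]) * precision$Q[[i]]
      # tr(Sigma_post J^T diag(qi) J) without forming the full product
      tr_unc <- sum(Sigma_post * crossprod(Jf, Jf * qi))
      0.5 * (sum(qi / pi_d) - tr_unc - sum(e^2 * qi))
    }, numeric(1))
    H <- outer(seq_along(precision$Q), seq_along(precision$Q),
               Vectorize(function(i, j)
                 0.5 * sum(exp(lambda[i] + lambda[j]) *
                             precision$Q[[i]] * precision$Q[[j]] / pi_d^2)))
    if (!all(is.finite(g)) || !all(is.finite(H))) {
      warning("non-finite ReML gradient; log-precisions left unchanged",
              call. = FALSE)
      return(lambda)
    }
    dl <- tryCatch(solve(H + diag(1e-8 * max(diag(H)), nrow(H)), g),
                   error = function(err) rep(0, length(g)))
    dl <- pmin(pmax(dl, -4), 4)        # damp single Fisher steps
    lambda <- pmin(pmax(lambda + dl, -32), 32)
    if (max(abs(dl)) < 1e-6) break
  }
  lambda
}

#' Invert a forward model by variational EM
#'
#' Alternates response-Jacobian computation, the Gauss-Newton E-step and the
#' ReML M-step, starting from the prior mean, until the free energy gain
#' falls below `tol` on two consecutive iterations (or `max_iter` is
#' reached). Every accepted move is required not to decrease the free energy,
#' so the recorded trace is non-decreasing.
#'
#' @param y stacked observed response
#' @param forward function: parameter vector -> stacked predicted response
#' @param priors list with `mean` (named vector) and `var`
#' @param precision an `erpdcm_precision`; defaults to a single identity
#'   component
#' @param jacobian function `(theta, base)` returning an `erpdcm_jacobian`;
#'   defaults to serial one-sided finite differences of `forward`
#' @param options list: `max_iter` (128), `tol` (0.01), `update_lambda`
#'   (TRUE), `m_iter` (8), `fd_step` (1e-4), `max_halvings` (8)
#' @return object of class `erpdcm_posterior`: posterior `mean` and
#'   covariance `cov` of the parameters, `lambda`, free-energy trace
#'   `F_trace`, `iterations`, `converged`
#' @export
invert <- function(y, forward, priors,
                   precision = identity_precision(length(y)),
                   jacobian = NULL, options = list()) {
  o <- utils::modifyList(list(max_iter = 128L, tol = 0.01,
                              update_lambda = TRUE, m_iter = 8L,
                              fd_step = 1e-4, max_halvings = 8L), options)
  if (is.null(jacobian))
    jacobian <- function(theta, base)
      fd_jacobian(forward, theta, step = o$fd_step, base = base)
  theta <- priors$mean
  lambda <- precision$lambda
  free <- priors$var > 0
  h <- forward(theta)
  F_trace <- numeric(0)
  stalled <- 0L
  converged <- FALSE
  J_best <- NULL
  for (it in seq_len(o$max_iter)) {
    jac <- jacobian(theta, h)
    J <- jac$J
    es <- e_step(y, forward, h, J, theta, lambda, priors, precision,
                 max_halvings = o$max_halvings)
    theta_new <- es$theta; h_new <- es$h
    F_it <- es$F
    lambda_new <- lambda
    if (o$update_lambda) {
      lam_prop <- m_step(y - h_new, J, lambda, precision, priors,
                         n_iter = o$m_iter)
      # keep the ascent monotone: damp the hyperparameter move if needed
      for (k in 0:8) {
        lam_try <- lambda + (lam_prop - lambda) / 2^k
        F_try <- tryCatch(free_energy(y, h_new, theta_new, lam_try, priors,
                                      precision, J),
                          error = function(e) -Inf)
        if (F_try >= F_it) { lambda_new <- lam_try; F_it <- F_try; break }
      }
    }
    # iteration-level acceptance: the Jacobian (hence the Occam term) is
    # re-linearized each iteration, so guard the recorded trace explicitly
    if (it == 1L || F_it >= F_trace[length(F_trace)]) {
      theta <- theta_new; h <- h_new; lambda <- lambda_new; J_best <- J
      F_trace <- c(F_trace, F_it)
    } else {
      F_trace <- c(F_trace, F_trace[length(F_trace)])
    }
    gain <- if (it == 1L) Inf else
      F_trace[length(F_trace)] - F_trace[length(F_trace) - 1L]
    stalled <- if (gain < o$tol) stalled + 1L else 0L
    if (stalled >= 2L) { converged <- TRUE; break }
  }
  pi_d <- pi_diagonal(precision, lambda)
  pp <- posterior_precision(J_best, pi_d, priors$var, free)
  cov_free <- chol2inv(pp$chol)
  cov_full <- matrix(0, length(theta), length(theta),
                     dimnames = list(names(theta), names(theta)))
  cov_full[free, free] <- cov_free
  structure(list(mean = theta, cov = cov_full, lambda = lambda,
                 F_trace = F_trace, iterations = length(F_trace),
                 converged = converged, n_data = length(y)),
            class = "erpdcm_posterior")
}

#' @export
print.erpdcm_posterior <- function(x, ...) {
  cat("ERP model inversion:", x$iterations, "EM iteration(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("final free energy:", format(x$F_trace[length(x$F_trace)]), "nats\n")
  cat("posterior means:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Invert a neural-mass model on an ERP dataset
#'
#' End-to-end model inversion: builds the stacked response and the forward
#' map from the model specification and lead field, computes the response
#' Jacobian serially or on the worker fabric, and runs the variational EM of
#' [invert()].
#'
#' @param dataset an `erpdcm_dataset` (see [simulate_erp()] or
#'   [read_dataset()])
#' @param spec an `erpdcm_spec`
#' @param leadfield gain matrix (channels x sources)
#' @param priors parameter priors; defaults to [default_priors()]
#' @param input stimulus; defaults to the dataset's stored input if present
#' @param precision noise model; defaults to a single identity component
#' @param backend `"serial"` or `"pool"`
#' @param strategy task arrangement for the pool backend
#' @param fabric a [fabric_descriptor()]
#' @param workers pool worker count
#' @param options EM options passed to [invert()]
#' @return an `erpdcm_posterior` with the parameter map attached
#' @export
dcm_invert <- function(dataset, spec, leadfield,
                       priors = default_priors(spec),
                       input = NULL, precision = NULL,
                       backend = c("serial", "pool"),
                       strategy = "blockX", fabric = fabric_descriptor(),
                       workers = 1L, options = list()) {
  backend <- match.arg(backend)
  if (is.null(input))
    input <- dataset$input %||% stimulus_input()
  grid <- dataset$times
  conditions <- dataset$conditions
  y <- stack_response(dataset$y[conditions])
  if (is.null(precision)) precision <- identity_precision(length(y))
  forward <- function(th)
    stack_response(predict_response(spec, th, leadfield, input, grid, conditions))
  fd_step <- options$fd_step %||% 1e-4
  jacobian <- if (backend == "serial") {
    function(theta, base)
      response_jacobian_serial(spec, theta, leadfield, input, grid,
                               conditions, step = fd_step, base = base)
  } else {
    function(theta, base)
      response_jacobian_parallel(spec, theta, leadfield, input, grid,
                                 conditions, step = fd_step, base = base,
                                 strategy = strategy, fabric = fabric,
                                 workers = workers)
  }
  post <- invert(y, forward, priors, precision, jacobian, options)
  post$map <- parameter_map(spec)
  post$spec <- spec
  post
}

`%||%` <- function(a, b) if (is.null(a)) b else a
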