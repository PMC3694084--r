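#' Centered firing-rate sigmoid
#'
#' Converts membrane potential to population firing rate with a logistic
#' sigmoid centered so that the resting potential maps to zero rate:
#' \deqn{S(v) = 1/(1+e^{-r(v-\eta)}) - 1/(1+e^{r\eta})}
#'
#' @param v membrane potential (mV); vectorized
#' @param params `source_parameters()` supplying slope `r` and threshold `eta`
#' @return firing rate (a.u.), strictly increasing and bounded in v
#' @export
erp_sigmoid <- function(v, params = source_parameters()) {
  1 / (1 + exp(-params$r * (v - params$eta))) - 1 / (1 + exp(params$r * params$eta))
}

# derivative of the sigmoid wrt membrane potential
erp_sigmoid_deriv <- function(v, params = source_parameters()) {
  e <- exp(-params$r * (v - params$eta))
  params$r * e / (1 + e)^2
}

#' Effective connectivity under a parameter vector and condition
#'
#' Builds the dense coupling matrices: entry (i, j) of each extrinsic matrix
#' is the baseline strength of its connection type times `exp(theta)` for the
#' coupling log-scaling, times `exp(theta_mod)` when the connection is
#' modulated and the condition is not the baseline. Entries outside the masks
#' are exactly zero.
#'
#' @param spec an `erpdcm_spec`
#' @param theta flat parameter vector
#' @param condition condition label (must be one of `spec$conditions`)
#' @return list of dense matrices `AF`, `AB`, `AL` (n x n) and input gain
#'   vector `CU` (length n)
#' @export
effective_connectivity <- function(spec, theta = prior_mean_theta(spec),
                                   condition = spec$conditions[1]) {
  if (!(condition %in% spec$conditions))
    stop("unknown condition label: ", condition)
  st <- theta_to_structured(spec, theta)
  mod <- matrix(0, spec$n_sources, spec$n_sources)
  if (condition != spec$conditions[1] && !is.null(st$M[[condition]]))
    mod <- st$M[[condition]]
  bs <- spec$base_strengths
  list(AF = bs[["F"]] * spec$F_mask * exp(st$F + mod * (spec$M_mask * 1)),
       AB = bs[["B"]] * spec$B_mask * exp(st$B + mod * (spec$M_mask * 1)),
       AL = bs[["L"]] * spec$L_mask * exp(st$L + mod * (spec$M_mask * 1)),
       CU = bs[["U"]] * spec$U_mask * exp(st$U))
}

# Precompute everything the state equations need for one (theta, condition):
# dense coupling matrices, per-source constants after intrinsic deviations,
# and the population-target composition matrices M4 (stellate), M5
# (pyramidal), M8 (inhibitory) that multiply the pyramidal firing rate.
compile_model <- function(spec, theta, condition) {
  conn <- effective_connectivity(spec, theta, condition)
  st <- theta_to_structured(spec, theta)
  p <- spec$params
  n <- spec$n_sources
  # gains are mV per unit rate with rates per second; time runs in ms, so
  # the synaptic drive carries a 1/1000 factor (equivalently: H_e tau_e in
  # mV.s sets the static gain of one synapse)
  He <- p$H_e / 1000 * exp(st$I[, "H_e"])
  Hi <- p$H_i / 1000 * exp(st$I[, "H_i"])
  Te <- p$tau_e * exp(st$I[, "tau_e"])
  Ti <- p$tau_i * exp(st$I[, "tau_i"])
  g <- p$gamma
  tgt <- function(pop) {
    m <- matrix(0, n, n)
    if (pop %in% spec$targets$F) m <- m + conn$AF
    if (pop %in% spec$targets$B) m <- m + conn$AB
    if (pop %in% spec$targets$L) m <- m + conn$AL
    m
  }
  list(n = n, He = He, Hi = Hi, Te = Te, Ti = Ti, g = g,
       r = p$r, eta = p$eta, CU = conn$CU,
       M4 = tgt("stellate") + g[1] * diag(n),
       M5 = tgt("pyramidal"),
       M8 = tgt("inhibitory") + g[3] * diag(n))
}

# state-block indices: state k of all sources occupies ((k-1)*n+1):(k*n)
state_block <- function(k, n) ((k - 1L) * n + 1L):(k * n)

#' Neuronal state derivative
#'
#' Right-hand side of the nine-states-per-source three-population model:
#' spiny-stellate, pyramidal and inhibitory populations with second-order
#' synaptic kinetics. Forward connections drive the spiny-stellate
#' population; backward and lateral connections drive the pyramidal and
#' inhibitory populations; the stimulus enters the spiny-stellate population.
#' States are stored population-major: state k of all sources is the block
#' `((k-1)*n+1):(k*n)`.
#'
#' @param x state vector of length `9 * n_sources`
#' @param u scalar stimulus value at the current time
#' @param spec an `erpdcm_spec`
#' @param theta flat parameter vector
#' @param condition condition label
#' @param model optional precompiled model (internal fast path)
#' @return dx/dt (per ms), same length as `x`
#' @export
state_derivative <- function(x, u, spec, theta = prior_mean_theta(spec),
                             condition = spec$conditions[1], model = NULL) {
  if (is.null(model)) model <- compile_model(spec, theta, condition)
  n <- model$n
  if (length(x) != 9L * n)
    stop("state vector has length ", length(x), ", expected ", 9L * n)
  b <- lapply(1:9, state_block, n = n)
  S9 <- 1 / (1 + exp(-model$r * (x[b[[9]]] - model$eta))) - 1 / (1 + exp(model$r * model$eta))
  S1 <- 1 / (1 + exp(-model$r * (x[b[[1]]] - model$eta))) - 1 / (1 + exp(model$r * model$eta))
  S7 <- 1 / (1 + exp(-model$r * (x[b[[7]]] - model$eta))) - 1 / (1 + exp(model$r * model$eta))
  f <- numeric(9L * n)
  f[b[[1]]] <- x[b[[4]]]
  f[b[[2]]] <- x[b[[5]]]
  f[b[[3]]] <- x[b[[6]]]
  f[b[[7]]] <- x[b[[8]]]
  f[b[[4]]] <- (model$He * (model$M4 %*% S9 + model$CU * u) -
                  2 * x[b[[4]]] - x[b[[1]]] / model$Te) / model$Te
  f[b[[5]]] <- (model$He * (model$M5 %*% S9 + model$g[2] * S1) -
                  2 * x[b[[5]]] - x[b[[2]]] / model$Te) / model$Te
  f[b[[6]]] <- (model$Hi * model$g[4] * S7 -
                  2 * x[b[[6]]] - x[b[[3]]] / model$Ti) / model$Ti
  f[b[[8]]] <- (model$He * (model$M8 %*% S9) -
                  2 * x[b[[8]]] - x[b[[7]]] / model$Te) / model$Te
  f[b[[9]]] <- x[b[[5]]] - x[b[[6]]]
  f
}

#' System Jacobian of the state equations
#'
#' Analytic derivative of [state_derivative()] with respect to the states,
#' used by the local-linearization integrator. Agrees with a central
#' finite-difference of the state derivative.
#'
#' @inheritParams state_derivative
#' @return square matrix `9 n_sources` x `9 n_sources` (per ms)
#' @export
system_jacobian <- function(x, u, spec, theta = prior_mean_theta(spec),
                            condition = spec$conditions[1], model = NULL) {
  if (is.null(model)) model <- compile_model(spec, theta, condition)
  n <- model$n
  if (length(x) != 9L * n)
    stop("state vector has length ", length(x), ", expected ", 9L * n)
  b <- lapply(1:9, state_block, n = n)
  sp <- function(v) {
    e <- exp(-model$r * (v - model$eta))
    model$r * e / (1 + e)^2
  }
  d9 <- sp(x[b[[9]]]); d1 <- sp(x[b[[1]]]); d7 <- sp(x[b[[7]]])
  J <- matrix(0, 9L * n, 9L * n)
  id <- diag(n)
  J[b[[1]], b[[4]]] <- id
  J[b[[2]], b[[5]]] <- id
  J[b[[3]], b[[6]]] <- id
  J[b[[7]], b[[8]]] <- id
  De <- diag(model$He / model$Te, n)
  J[b[[4]], b[[9]]] <- De %*% model$M4 %*% diag(d9, n)
  J[b[[4]], b[[1]]] <- diag(-1 / model$Te^2, n)
  J[b[[4]], b[[4]]] <- diag(-2 / model$Te, n)
  J[b[[5]], b[[9]]] <- De %*% model$M5 %*% diag(d9, n)
  J[b[[5]], b[[1]]] <- diag(model$He * model$g[2] * d1 / model$Te, n)
  J[b[[5]], b[[2]]] <- diag(-1 / model$Te^2, n)
  J[b[[5]], b[[5]]] <- diag(-2 / model$Te, n)
  J[b[[6]], b[[7]]] <- diag(model$Hi * model$g[4] * d7 / model$Ti, n)
  J[b[[6]], b[[3]]] <- diag(-1 / model$Ti^2, n)
  J[b[[6]], b[[6]]] <- diag(-2 / model$Ti, n)
  J[b[[8]], b[[9]]] <- De %*% model$M8 %*% diag(d9, n)
  J[b[[8]], b[[7]]] <- diag(-1 / model$Te^2, n)
  J[b[[8]], b[[8]]] <- diag(-2 / model$Te, n)
  J[b[[9]], b[[5]]] <- id
  J[b[[9]], b[[6]]] <- -id
  J
}

#' Gaussian-bump stimulus input
#'
#' The deterministic experimental input: a Gaussian bump in time.
#'
#' @param onset bump center (ms)
#' @param width bump standard deviation (ms), nonnegative
#' @param amplitude peak value (a.u.)
#' @return object of class `erpdcm_input`; evaluate on a grid with
#'   [input_values()]
#' @export
stimulus_input <- function(onset = 64, width = 16, amplitude = 1) {
  stopifnot(width >= 0, is.finite(onset), is.finite(amplitude))
  structure(list(onset = onset, width = width, amplitude = amplitude),
            class = "erpdcm_input")
}

#' Evaluate a stimulus input on a time grid
#'
#' @param input an `erpdcm_input`
#' @param grid time points (ms)
#' @export
input_values <- function(input, grid) {
  if (input$width == 0) return(ifelse(grid == input$onset, input$amplitude, 0))
  input$amplitude * exp(-(grid - input$onset)^2 / (2 * input$width^2))
}

# one local-linearization step: dx = (expm(dt J) - I) J^{-1} f. The 9-state
# layout carries a conserved mode (the pyramidal potential mirrors the
# difference of its current integrals), so J is structurally singular and a
# Moore-Penrose pseudo-inverse (tol 1e-10) replaces the solve; the null
# component of f (zero when f is dynamically consistent) advances linearly.
ll_step <- function(x, f, J, dt) {
  E <- as.matrix(Matrix::expm(J * dt)) - diag(nrow(J))
  z <- NULL
  if (Matrix::rcond(J) >= 1e-10)
    z <- tryCatch(solve(J, f), error = function(e) NULL)
  if (is.null(z) || !all(is.finite(z))) {
    s <- svd(J)
    pos <- s$d > 1e-10 * max(s$d)
    z <- s$v[, pos, drop = FALSE] %*%
      ((t(s$u[, pos, drop = FALSE]) %*% f) / s$d[pos])
  }
  fn <- f - as.vector(J %*% z)
  x + as.vector(E %*% z) + dt * fn
}

#' Integrate the neuronal state equations
#'
#' Local linearization: at each step the flow is advanced with the matrix
#' exponential of the current system Jacobian,
#' \eqn{x_{k+1} = x_k + (e^{\Delta t J_k} - I) J_k^{-1} f(x_k, u_k)},
#' starting from rest (x = 0). Returns the pyramidal depolarization of each
#' source at every grid point.
#'
#' @param spec an `erpdcm_spec`
#' @param theta flat parameter vector
#' @param condition condition label
#' @param input an `erpdcm_input` (or numeric vector of input values on the
#'   grid)
#' @param grid strictly increasing time points (ms); the state at `grid[1]`
#'   is the resting state
#' @param full_state return the full state trajectory instead of pyramidal
#'   potentials?
#' @param engine `"compiled"` (default) runs the C++ hot loop; `"reference"`
#'   runs the plain-R implementation of the identical update — the two are
#'   cross-checked in the test suite
#' @return `n_sources` x `length(grid)` matrix of pyramidal depolarization
#'   (mV), or the full `9 n_sources` x `length(grid)` state trajectory
#' @export
integrate_states <- function(spec, theta = prior_mean_theta(spec),
                             condition = spec$conditions[1],
                             input = stimulus_input(),
                             grid = seq(0, 500, by = 1),
                             full_state = FALSE,
                             engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  if (any(diff(grid) <= 0)) stop("time grid must be strictly increasing")
  # the input is held constant over each step at its midpoint value (second
  # order in the step for a smooth stimulus); an explicit numeric input is
  # used as sampled, left endpoints
  if (inherits(input, "erpdcm_input")) {
    u <- input_values(input, (grid[-1] + grid[-length(grid)]) / 2)
  } else {
    u <- as.numeric(input)
    if (length(u) != length(grid)) stop("input values do not match the grid")
    u <- u[-length(u)]
  }
  model <- compile_model(spec, theta, condition)
  if (engine == "compiled")
    return(ll_integrate_cpp(model, u, grid, full_state))
  n <- model$n
  d <- 9L * n
  x <- numeric(d)
  X <- matrix(0, d, length(grid))
  for (k in seq_len(length(grid) - 1L)) {
    dt <- grid[k + 1L] - grid[k]
    f <- state_derivative(x, u[k], spec, model = model)
    J <- system_jacobian(x, u[k], spec, model = model)
    x <- ll_step(x, f, J, dt)
    if (!all(is.finite(x)))
      stop("state integration diverged at time index ", k + 1L,
           " (t = ", grid[k + 1L], " ms)")
    X[, k + 1L] <- x
  }
  if (full_state) return(X)
  X[state_block(9L, n), , drop = FALSE]
}

#' Write a source trajectory as TSV
#'
#' @param trajectory matrix from [integrate_states()] (sources x time)
#' @param grid matching time points (ms)
#' @param path output file
#' @param source_names optional column labels
#' @export
write_trajectory_tsv <- function(trajectory, grid, path,
                                 source_names = rownames(trajectory)) {
  if (is.null(source_names))
    source_names <- paste0("S", seq_len(nrow(trajectory)))
  df <- data.frame(time_ms = grid, t(trajectory))
  names(df) <- c("time_ms", source_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
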