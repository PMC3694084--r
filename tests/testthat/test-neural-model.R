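test_that("firing-rate sigmoid is centered, bounded and strictly increasing", {
  p <- source_parameters()
  expect_equal(erp_sigmoid(0, p), 0)
  # closed form via plogis at r = 0.56, eta = 6
  v <- c(-12, -3, 1.5, 6, 20)
  expect_equal(erp_sigmoid(v, p),
               plogis(0.56 * (v - 6)) - plogis(-0.56 * 6))
  asym <- erp_sigmoid(v, p) + erp_sigmoid(-v, p)
  expect_equal(asym, plogis(0.56 * (v - 6)) + plogis(0.56 * (-v - 6)) -
                 2 * plogis(-0.56 * 6))
  set.seed(1)
  a <- rnorm(1000, sd = 5); b <- a + runif(1000, 0.01, 1)
  expect_true(all(erp_sigmoid(b, p) > erp_sigmoid(a, p)))
  expect_true(all(abs(erp_sigmoid(rnorm(100, sd = 100), p)) < 1))
})

test_that("effective connectivity applies masks, scalings and modulation", {
  s <- two_source_spec(M_mask = matrix(c(0, 1, 0, 0), 2, 2),
                       conditions = c("standard", "deviant"))
  th0 <- prior_mean_theta(s)
  cc <- effective_connectivity(s, th0, "standard")
  expect_equal(cc$AF, s$base_strengths[["F"]] * (s$F_mask * 1))
  expect_equal(cc$AB, s$base_strengths[["B"]] * (s$B_mask * 1))
  expect_equal(cc$CU, s$base_strengths[["U"]] * c(1, 0))
  # modulation log 2 doubles the modulated entry in the deviant condition only
  th <- th0; th["M_2_1_deviant"] <- log(2)
  expect_equal(effective_connectivity(s, th, "deviant")$AF[2, 1],
               2 * cc$AF[2, 1])
  expect_equal(effective_connectivity(s, th, "standard")$AF[2, 1],
               cc$AF[2, 1])
  # masked-out entries stay zero for any scaling
  expect_equal(effective_connectivity(s, th0 + 3, "standard")$AL,
               matrix(0, 2, 2))
  expect_error(effective_connectivity(s, th0, "oddball"), "unknown condition")
})

test_that("rest is a fixed point and drive terms scale with the gains", {
  s <- two_source_spec()
  th <- prior_mean_theta(s)
  expect_equal(state_derivative(rep(0, 18), 0, s, th), rep(0, 18))
  expect_error(state_derivative(rep(0, 7), 0, s, th), "length")
  # f4 at rest with input is linear in H_e
  f1 <- state_derivative(rep(0, 18), 1, s, th)
  s2 <- two_source_spec(params = source_parameters(H_e = 8))
  f2 <- state_derivative(rep(0, 18), 1, s2, th)
  expect_equal(f2[7:8], 2 * f1[7:8])  # stellate current block (state 4)
})

test_that("analytic system Jacobian matches a finite-difference oracle", {
  s <- two_source_spec(L_mask = matrix(c(0, 1, 1, 0), 2, 2))
  th <- prior_mean_theta(s) + 0.1
  expect_lt(max(abs(system_jacobian(rep(0, 18), 0.3, s, th) -
                      fd_system_jacobian(rep(0, 18), 0.3, s, th))), 1e-6)
  set.seed(42)
  for (k in 1:10) {
    x <- rnorm(18, sd = 3); u <- runif(1)
    expect_lt(max(abs(system_jacobian(x, u, s, th) -
                        fd_system_jacobian(x, u, s, th))), 1e-6)
  }
})

test_that("Jacobian is block-diagonal without extrinsic connections and the
           rest point is stable up to the conserved mode", {
  s <- model_spec(2, U_mask = c(TRUE, TRUE))  # no extrinsic connections
  th <- prior_mean_theta(s)
  J <- system_jacobian(rep(0, 18), 0, s, th)
  src <- rep(rep(1:2, 9) , 1)  # population-major layout: source id per state
  cross <- outer(src, src, "!=")
  expect_true(all(J[cross] == 0))
  # each source carries one conserved mode (x9 mirrors x2 - x3): one zero
  # eigenvalue per source, all remaining eigenvalues strictly damped
  ev <- eigen(J, only.values = TRUE)$values
  expect_true(all(Re(ev) < 1e-10))
  expect_equal(sum(abs(ev) < 1e-10), 2L)
  expect_true(all(Re(ev[abs(ev) > 1e-10]) < -1e-3))
})

test_that("integration from rest with no input stays at rest", {
  s <- two_source_spec()
  x <- integrate_states(s, input = stimulus_input(amplitude = 0),
                        grid = fast_grid)
  expect_equal(max(abs(x)), 0)
})

test_that("small-signal response follows the second-order synaptic kernel", {
  # one isolated synapse (intrinsic couplings disabled), weak brief input:
  # the stellate potential is exactly the convolution of the input with
  # k(t) = (H_e/1000) (t/tau_e) exp(-t/tau_e)
  s <- model_spec(1, U_mask = TRUE,
                  params = source_parameters(gamma = rep(0, 4)))
  grid <- seq(0, 150, by = 0.5)
  inp <- stimulus_input(onset = 30, width = 4, amplitude = 1e-4)
  X <- integrate_states(s, input = inp, grid = grid, full_state = TRUE)
  x1 <- X[1, ]
  p <- s$params
  tt <- seq(0, 150, by = 0.01)
  kern <- (p$H_e / 1000) * (tt / p$tau_e) * exp(-tt / p$tau_e)
  drive <- s$base_strengths[["U"]] * input_values(inp, tt)
  conv <- stats::convolve(drive, rev(kern), type = "open")[seq_along(tt)] * 0.01
  oracle <- stats::approx(tt, conv, xout = grid)$y
  expect_lt(max(abs(x1 - oracle)), 1e-3 * max(abs(oracle)))
})

test_that("autonomous dynamics make the response shift with the input onset", {
  s <- two_source_spec()
  grid <- seq(0, 400, by = 2)
  x0 <- integrate_states(s, input = stimulus_input(onset = 100, amplitude = 5),
                         grid = grid)
  x1 <- integrate_states(s, input = stimulus_input(onset = 150, amplitude = 5),
                         grid = grid)
  shift <- 25L  # 50 ms at 2 ms steps
  n <- ncol(x0)
  expect_lt(max(abs(x1[, (shift + 1):n] - x0[, 1:(n - shift)])),
            1e-5 * max(abs(x0)))
})

test_that("compiled and reference integration engines agree", {
  s <- two_source_spec(M_mask = matrix(c(0, 1, 0, 0), 2, 2),
                       conditions = c("standard", "deviant"))
  th <- prior_mean_theta(s) + 0.15
  for (cond in s$conditions) {
    xc <- integrate_states(s, th, cond, stimulus_input(amplitude = 5),
                           fast_grid)
    xr <- integrate_states(s, th, cond, stimulus_input(amplitude = 5),
                           fast_grid, engine = "reference")
    expect_lt(max(abs(xc - xr)), 1e-9 * max(abs(xc)))
  }
})

test_that("baseline responses are insensitive to modulation parameters", {
  s <- two_source_spec(M_mask = matrix(c(0, 1, 0, 0), 2, 2),
                       conditions = c("standard", "deviant"))
  th <- prior_mean_theta(s)
  th2 <- th; th2["M_2_1_deviant"] <- 0.7
  x_base <- integrate_states(s, th, "standard", stimulus_input(amplitude = 5),
                             fast_grid)
  x_pert <- integrate_states(s, th2, "standard", stimulus_input(amplitude = 5),
                             fast_grid)
  expect_equal(x_base, x_pert)
  expect_gt(max(abs(integrate_states(s, th2, "deviant",
                                     stimulus_input(amplitude = 5),
                                     fast_grid) - x_base)), 0)
})
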