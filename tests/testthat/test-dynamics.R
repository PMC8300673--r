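test_that("linear model wraps its drift matrix exactly", {
  J <- rbind(c(-1, 0.5), c(0, -2))
  m <- linear_model(J)
  expect_equal(m$rhs(c(1, 1), m$params), drop(J %*% c(1, 1)))
  expect_equal(m$rhs(c(0, 0), m$params), c(0, 0))
  expect_equal(numeric_jacobian(m, c(0, 0)), J, tolerance = 1e-8)
})

test_that("single-patch RM model satisfies the coexistence identities", {
  params <- rm_default_params()
  model <- rm_metacommunity_model(params, NULL)
  ss <- find_steady_state(model, c(0.4, 0.5))
  expect_lt(ss$residual, 1e-10)
  b <- ss$x[1]; cc <- ss$x[2]
  fr <- params[["a"]] * b / (1 + params[["a"]] * params[["h"]] * b)
  # predator balance: eps * functional response = m + g c*
  expect_equal(params[["eps"]] * fr, params[["m"]] + params[["g"]] * cc,
               tolerance = 1e-10)
  # prey balance: logistic growth = predation loss
  expect_equal(params[["r"]] * b * (1 - b / params[["K"]]), fr * cc,
               tolerance = 1e-10)
})

test_that("numeric Jacobian matches the hand-differentiated RM derivatives", {
  p <- rm_default_params()
  model <- rm_metacommunity_model(p, NULL)
  ss <- find_steady_state(model, c(0.4, 0.5))
  b <- ss$x[1]; cc <- ss$x[2]
  a <- p[["a"]]; h <- p[["h"]]
  den <- 1 + a * h * b
  J_exact <- rbind(
    c(p[["r"]] * (1 - 2 * b / p[["K"]]) - cc * a / den^2,
      -a * b / den),
    c(p[["eps"]] * cc * a / den^2,
      p[["eps"]] * a * b / den - p[["m"]] - 2 * p[["g"]] * cc)
  )
  expect_equal(numeric_jacobian(model, ss), J_exact, tolerance = 1e-6)

  # quadratic 1-D rhs: f(x) = -x + x^2 has slope -1 at the origin
  quad <- jacrecon:::.new_dyn_model(1L, function(x, p) -x + x^2,
                                    numeric(0), "x")
  expect_equal(numeric_jacobian(quad, 0)[1, 1], -1, tolerance = 1e-9)
})

test_that("homogeneous metacommunity states carry no dispersal flux and block structure", {
  setup <- rm_test_setup()
  single <- rm_metacommunity_model(setup$params, NULL)
  ss1 <- find_steady_state(single, c(0.4, 0.5))
  x_hom <- rep(ss1$x, setup$net$n_nodes)
  # replicated single-patch root is a root of the metacommunity
  expect_lt(max(abs(setup$model$rhs(x_hom, setup$params))), 1e-10)

  P_intra <- numeric_jacobian(single, ss1)
  L <- laplacian_matrix(setup$net)
  J_block <- kronecker(diag(setup$net$n_nodes), P_intra) -
    kronecker(L, diag(c(setup$params[["delta_b"]],
                        setup$params[["delta_c"]])))
  J_num <- numeric_jacobian(setup$model, x_hom)
  expect_equal(J_num, J_block, tolerance = 1e-6)

  # zero dispersal decouples the patches: block-diagonal Jacobian
  p0 <- setup$params
  p0["delta_b"] <- 0; p0["delta_c"] <- 0
  m0 <- rm_metacommunity_model(p0, setup$net)
  J0 <- numeric_jacobian(m0, x_hom)
  expect_equal(J0, kronecker(diag(6), numeric_jacobian(
    rm_metacommunity_model(p0, NULL), ss1$x)), tolerance = 1e-6)
})

test_that("steady-state search converges, rejects infeasible starts, and reports negativity", {
  m <- linear_model(-diag(2))
  ss <- find_steady_state(m, c(5, -3))
  expect_equal(ss$x, c(0, 0), tolerance = 1e-10)

  # divergent start for the RM model (far outside the basin)
  model <- rm_metacommunity_model(rm_default_params(), NULL)
  expect_error(find_steady_state(model, c(1e8, 1e8), max_iter = 5),
               "failed|converge")
})

test_that("master stability spectrum equals the direct eigendecomposition", {
  setup <- rm_test_setup()
  single <- rm_metacommunity_model(setup$params, NULL)
  ss1 <- find_steady_state(single, c(0.4, 0.5))
  P_intra <- numeric_jacobian(single, ss1)
  coupling <- c(setup$params[["delta_b"]], setup$params[["delta_c"]])

  # single patch: Laplacian eigenvalue 0 only
  expect_equal(msf_spectrum(P_intra, coupling, 0),
               jacobian_spectrum(P_intra)$values, tolerance = 1e-10)

  # two patches, one edge: Laplacian eigenvalues {0, 2}
  net2 <- patch_network(rbind(c(1, 2)), 2)
  m2 <- rm_metacommunity_model(setup$params, net2)
  J2 <- numeric_jacobian(m2, rep(ss1$x, 2))
  msf2 <- msf_spectrum(P_intra, coupling,
                       eigen(laplacian_matrix(net2), symmetric = TRUE)$values)
  expect_equal(msf2, jacobian_spectrum(J2)$values, tolerance = 1e-6)
})

test_that("Euler-Maruyama respects fixed points, determinism and the linear flow", {
  # zero noise at the fixed point stays put
  m <- linear_model(diag(c(-1, -2)))
  cfg <- sim_config(dt = 1e-3, n_samples = 100, seed = 1)
  ts <- euler_maruyama(m, noise_spec(0), cfg, x0 = c(0, 0))
  expect_true(all(ts$values == 0))

  # zero noise from x0: matches exp(J t) x0 to O(dt)
  ts <- euler_maruyama(m, noise_spec(0),
                       sim_config(dt = 1e-3, n_samples = 1000, seed = 1),
                       x0 = c(1, 1))
  exact <- exp(outer(ts$times, c(-1, -2)))
  expect_lt(max(abs(ts$values - exact)), 5e-3)

  # identical config implies bit-identical series (native and R paths)
  ns <- noise_spec(0.5)
  cfg <- sim_config(dt = 0.01, n_samples = 500, stride = 2,
                    burn_in = 100, seed = 77)
  expect_identical(euler_maruyama(m, ns, cfg)$values,
                   euler_maruyama(m, ns, cfg)$values)
  generic <- jacrecon:::.new_dyn_model(2L, function(x, p) -x,
                                       numeric(0), c("x1", "x2"))
  expect_identical(euler_maruyama(generic, ns, cfg, x0 = c(1, 1))$values,
                   euler_maruyama(generic, ns, cfg, x0 = c(1, 1))$values)

  # non-finite trajectories abort with a step index
  boom <- linear_model(matrix(10, 1, 1))
  expect_error(
    euler_maruyama(boom, noise_spec(1),
                   sim_config(dt = 1, n_samples = 1000, seed = 1),
                   x0 = 1),
    "non-finite"
  )
})

test_that("1-D OU long-run variance approaches sigma^2 / (2 theta)", {
  theta <- 1
  sigma <- sqrt(2)           # stationary variance 1
  m <- linear_model(matrix(-theta, 1, 1))
  cfg <- sim_config(dt = 0.01, n_samples = 5e4, stride = 5,
                    burn_in = 1000, seed = 5)
  ts <- euler_maruyama(m, noise_spec(sigma), cfg)
  v <- drop(estimate_covariance(ts))
  # T = 2500 time units, correlation time 1: ~1250 effective samples
  expect_lt(abs(v - sigma^2 / (2 * theta)), 3 * sqrt(2 / 1250))
})

test_that("simulated OU covariance converges to the forward Lyapunov solution", {
  J <- rbind(c(-1, 0.3), c(-0.2, -2))
  D <- diag(2)                     # additive sigma = sqrt(2)
  cfg <- sim_config(dt = 0.005, n_samples = 1e5, stride = 4,
                    burn_in = 2000, seed = 11)
  ts <- euler_maruyama(linear_model(J), noise_spec(sqrt(2)), cfg)
  G_hat <- estimate_covariance(ts)
  G <- forward_lyapunov(J, D)
  expect_lt(max(abs(G_hat - G)), 0.05)
})

test_that("fluctuation matrix follows the noise convention", {
  expect_equal(fluctuation_from_noise(noise_spec(sqrt(2)), n = 2), diag(2))
  D <- fluctuation_from_noise(noise_spec(1, "multiplicative"),
                              xstar = c(2, 3))
  expect_equal(D, diag(c(2, 4.5)))
  expect_error(fluctuation_from_noise(noise_spec(1, "multiplicative")),
               "steady state")
})

test_that("positive-orthant trajectories are rejected (not clipped) at the floor", {
  setup <- rm_test_setup()
  ss <- find_steady_state(setup$model, setup$x0)
  # absurdly strong noise forces the state below zero immediately
  expect_error(
    euler_maruyama(setup$model, noise_spec(50),
                   sim_config(dt = 0.01, n_samples = 100, seed = 1),
                   x0 = ss$x, max_retries = 1),
    "floor"
  )
})

test_that("parameter ramps interpolate linearly and validate the name", {
  setup <- rm_test_setup()
  ss <- find_steady_state(setup$model, setup$x0)
  cfg <- sim_config(dt = 0.01, n_samples = 200, stride = 5,
                    burn_in = 50, seed = 3)
  ns <- noise_spec(0.01)

  # degenerate ramp reproduces the fixed-parameter run exactly
  fixed <- euler_maruyama(setup$model, ns, cfg, x0 = ss$x)
  flat <- parameter_ramp(setup$model, "K", setup$params[["K"]],
                         setup$params[["K"]], ns, cfg, x0 = ss$x)
  expect_identical(fixed$values, flat$values)

  ramped <- parameter_ramp(setup$model, "K", 1.0, 1.4, ns, cfg,
                           x0 = ss$x)
  expect_equal(ramped$param_trace[1], 1.0, tolerance = 1e-2)
  expect_equal(ramped$param_trace[length(ramped$param_trace)], 1.4,
               tolerance = 1e-6)
  expect_true(all(diff(ramped$param_trace) > 0))

  expect_error(parameter_ramp(setup$model, "zeta", 0, 1, ns, cfg,
                              x0 = ss$x), "unknown parameter")

  # ramping an unused parameter of a generic model leaves dynamics unchanged
  generic <- jacrecon:::.new_dyn_model(1L, function(x, p) -x,
                                       c(mu = 0), "x")
  a <- parameter_ramp(generic, "mu", 0, 5, ns, cfg, x0 = 1)
  b <- parameter_ramp(generic, "mu", 0, 0, ns, cfg, x0 = 1)
  expect_identical(a$values, b$values)
})
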