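# Shared fixtures for the test suite; everything is generated in code.

# random symmetric positive-definite matrix
rand_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n, n)
  crossprod(A) / n + diag(n)
}

# random square matrix
rand_mat <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * n), n, n)
}

# six-patch RM metacommunity with a K override, plus its zero pattern
rm_test_setup <- function(K = NULL) {
  params <- rm_default_params()
  if (!is.null(K)) params["K"] <- K
  net <- fixture_asym6()
  model <- rm_metacommunity_model(params, net)
  idx <- multilayer_index(2L, net$n_nodes)
  list(params = params, net = net, model = model, idx = idx,
       pattern = multilayer_zero_pattern(idx, net),
       x0 = rep(c(0.45, 0.6), net$n_nodes))
}

# ground truth (steady state, Jacobian, leading eigenvalue) at one K
rm_truth <- function(K, x0 = rep(c(0.45, 0.6), 6)) {
  setup <- rm_test_setup(K)
  ss <- find_steady_state(setup$model, x0)
  J <- numeric_jacobian(setup$model, ss)
  list(model = setup$model, ss = ss, J = J,
       leading = jacobian_spectrum(J)$leading)
}
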