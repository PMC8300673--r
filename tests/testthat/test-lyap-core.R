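test_that("build_design reproduces the printed 2x2 pattern and the product identity", {
  G <- rbind(c(2, 1), c(1, 3))
  B <- build_design(G)
  expect_equal(B, rbind(c(4, 0, 2, 0), c(1, 2, 3, 1),
                        c(1, 2, 3, 1), c(0, 2, 0, 6)))

  # Gamma = I: B = I + C, so B vec(J) = vec(J + J')
  BI <- build_design(diag(3))
  expect_equal(BI, diag(9) + commutation_matrix(3))

  set.seed(23)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    G <- rand_spd(n)
    J <- rand_mat(n)
    expect_equal(drop(build_design(G) %*% vec(J)),
                 vec(J %*% G + G %*% t(J)), tolerance = 1e-12)
  }
})

test_that("asymmetric covariance input is symmetrised or rejected", {
  G <- rbind(c(2, 1), c(1, 3))
  Gp <- G + rbind(c(0, 1e-6), c(0, 0))
  expect_warning(build_design(Gp), "asymmetric")
  expect_error(build_design(Gp, on_asymmetric = "error"), "asymmetric")
  expect_error(build_design(G + rbind(c(0, 1), c(0, 0))), "asymmetric")
  expect_silent(build_design(G))
})

test_that("middle rows of the 2x2 design coincide and the rank is N(N+1)/2", {
  set.seed(31)
  G <- rand_spd(2)
  B <- build_design(G)
  expect_equal(B[2, ], B[3, ])
  expect_equal(qr(B)$rank, 3L)
  for (n in 3:5) {
    expect_equal(qr(build_design(rand_spd(n)))$rank, n * (n + 1L) / 2L)
  }
})

test_that("stack_constraints appends the printed unit row and handles edge cases", {
  G <- rbind(c(2, 1), c(1, 3))
  B <- build_design(G)
  D <- diag(2)
  sys <- stack_constraints(B, -2 * vec(D), zero_pattern(rbind(c(1, 2)), 2))
  expect_equal(nrow(sys$design), 5L)
  expect_equal(sys$design[5, ], c(0, 0, 1, 0))     # vec-position of (1,2)
  expect_equal(sys$rhs, c(-2, 0, 0, -2, 0))

  # empty pattern leaves the design untouched
  sys0 <- stack_constraints(B, -2 * vec(D), zero_pattern(NULL, 2))
  expect_equal(sys0$design, B)

  # full pattern appends a row permutation of the identity
  full <- which(matrix(TRUE, 2, 2), arr.ind = TRUE)
  sysf <- stack_constraints(B, -2 * vec(D), zero_pattern(full, 2))
  U <- sysf$design[5:8, ]
  expect_equal(sort(apply(U, 1, which.max)), 1:4)
  expect_true(all(rowSums(U) == 1))

  expect_error(zero_pattern(rbind(c(1, 3)), 2), "indices")
  expect_error(zero_pattern(rbind(c(1, 2), c(1, 2)), 2), "duplicate")
})

test_that("solver matches the closed-form normal equations and recovers the worked case", {
  # exactly determined consistent system
  set.seed(41)
  A <- rand_mat(3)
  x <- rnorm(3)
  sys <- structure(list(design = A, rhs = drop(A %*% x), n = 1L,
                        n_data = 3L), class = "design_system")
  sol <- solve_reconstruction(sys)
  expect_equal(sol$coefficients, x, tolerance = 1e-10)
  expect_lt(sol$residual_norm, 1e-10)

  # worked 2-variable case: J = [[-1,0],[0.5,-2]], D = I, J12 = 0
  J <- rbind(c(-1, 0), c(0.5, -2))
  D <- diag(2)
  G <- forward_lyapunov(J, D)
  expect_equal(G, rbind(c(1, 1 / 6), c(1 / 6, 13 / 24)),
               tolerance = 1e-12)
  sys <- stack_constraints(build_design(G), -2 * vec(D),
                           zero_pattern(rbind(c(1, 2)), 2))
  sol <- solve_reconstruction(sys)
  expect_equal(sol$coefficients, c(-1, 0.5, 0, -2), tolerance = 1e-9)

  # overdetermined inconsistent system vs explicit (A'A)^{-1} A'b
  set.seed(43)
  A <- matrix(rnorm(40), 10, 4)
  b <- rnorm(10)
  sys <- structure(list(design = A, rhs = b, n = 2L, n_data = 10L),
                   class = "design_system")
  sol <- solve_reconstruction(sys)
  expect_equal(sol$coefficients,
               drop(solve(crossprod(A), crossprod(A, b))),
               tolerance = 1e-10)

  expect_error(solve_reconstruction(
    structure(list(design = matrix(0, 4, 4), rhs = numeric(4),
                   n = 2L, n_data = 4L), class = "design_system")),
    "degenerate")
})

test_that("forward_lyapunov solves the Lyapunov equation and rejects unstable drift", {
  expect_equal(forward_lyapunov(-diag(2), diag(2)), diag(2))
  expect_equal(forward_lyapunov(diag(c(-1, -2)), diag(2)),
               diag(c(1, 0.5)))
  set.seed(47)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    J <- rand_mat(n) - diag(n) * (n + 1)
    D <- rand_spd(n)
    G <- forward_lyapunov(J, D)
    expect_equal(G, t(G))
    resid <- J %*% G + G %*% t(J) + 2 * D
    expect_lt(sqrt(sum(resid^2)), 1e-10 * sqrt(sum(D^2)))
    expect_gte(min(eigen(G, symmetric = TRUE)$values), -1e-12)
  }
  expect_error(forward_lyapunov(diag(c(1, -1)), diag(2)), "Hurwitz")
})

test_that("spectrum ordering puts the leading eigenvalue first with deterministic ties", {
  s <- jacobian_spectrum(diag(c(-1, -3)))
  expect_equal(s$leading, -1 + 0i)
  expect_equal(s$type, "real")

  s <- jacobian_spectrum(rbind(c(0, -1), c(1, 0)))
  expect_equal(s$leading, 0 + 1i)      # nonnegative imaginary first
  expect_equal(s$type, "complex-pair")

  set.seed(53)
  for (rep in 1:10) {
    J <- rand_mat(4)
    s <- jacobian_spectrum(J)
    ref <- eigen(J, only.values = TRUE)$values
    expect_equal(sort(Re(s$values)), sort(Re(ref)), tolerance = 1e-10)
    expect_equal(max(Re(s$values)), Re(s$leading), tolerance = 1e-12)
    expect_true(all(diff(Re(s$values)) < 1e-12))
  }
})

test_that("reconstruction round-trips random stable sparse Jacobians", {
  for (seed in 1:5) {
    fx <- fixture_stable_jacobian(6, density = 0.3, seed = seed)
    expect_gte(length(fx$pattern), 15)
    D <- diag(6)
    G <- forward_lyapunov(fx$jacobian, D)
    rec <- reconstruct_jacobian(G, D, fx$pattern)
    expect_lt(max(abs(rec$jacobian - fx$jacobian)), 1e-8)
    expect_false(rec$underdetermined)
    expect_true(all(rec$jacobian[fx$pattern$positions] == 0))
  }
})

test_that("decoupled diagonal system recovers exactly with Gamma = -D/J on the diagonal", {
  J <- diag(c(-1, -2, -3))
  D <- diag(3)
  G <- forward_lyapunov(J, D)
  expect_equal(G, diag(c(1, 1 / 2, 1 / 3)))
  offdiag <- which(!diag(TRUE, 3), arr.ind = TRUE)
  rec <- reconstruct_jacobian(G, D, zero_pattern(offdiag, 3))
  expect_equal(rec$jacobian, J, tolerance = 1e-10)
})

test_that("underdetermined patterns trigger a warning and are flagged", {
  set.seed(59)
  G <- rand_spd(3)
  D <- diag(3)
  expect_warning(
    rec <- reconstruct_jacobian(G, D, zero_pattern(rbind(c(1, 2)), 3)),
    "underdetermined"
  )
  expect_true(rec$underdetermined)
})

test_that("normal-equations fast path agrees with the QR path", {
  for (seed in c(2, 9)) {
    fx <- fixture_stable_jacobian(12, density = 0.2, seed = seed)
    D <- diag(12)
    G <- forward_lyapunov(fx$jacobian, D)
    r_qr <- reconstruct_jacobian(G, D, fx$pattern, method = "qr")
    r_ne <- reconstruct_jacobian(G, D, fx$pattern, method = "normal")
    expect_lt(max(abs(r_qr$jacobian - r_ne$jacobian)), 1e-10)
  }
})

test_that("reconstruction is linear in D and equivariant under permutations", {
  fx <- fixture_stable_jacobian(6, density = 0.3, seed = 13)
  D <- diag(6)
  G <- forward_lyapunov(fx$jacobian, D)
  r1 <- reconstruct_jacobian(G, D, fx$pattern)
  r3 <- reconstruct_jacobian(G, 3 * D, fx$pattern)
  expect_equal(r3$jacobian, 3 * r1$jacobian, tolerance = 1e-9)

  set.seed(61)
  perm <- sample(6)
  Gp <- G[perm, perm]
  Dp <- D[perm, perm]
  inv <- order(perm)
  pos <- fx$pattern$positions
  patp <- zero_pattern(cbind(inv[pos[, 1]], inv[pos[, 2]]), 6)
  rp <- reconstruct_jacobian(Gp, Dp, patp)
  expect_equal(rp$jacobian, r1$jacobian[perm, perm], tolerance = 1e-8)
})

test_that("without zero enforcement constrained entries are small but nonzero in noise", {
  fx <- fixture_stable_jacobian(5, density = 0.3, seed = 3)
  D <- diag(5)
  G <- forward_lyapunov(fx$jacobian, D)
  # perturb the covariance slightly, as a finite sample would
  set.seed(7)
  E <- matrix(rnorm(25, sd = 1e-4), 5, 5)
  Gn <- G + (E + t(E)) / 2
  raw <- reconstruct_jacobian(Gn, D, fx$pattern, enforce_zeros = FALSE)
  enf <- reconstruct_jacobian(Gn, D, fx$pattern, enforce_zeros = TRUE)
  expect_gt(max(abs(raw$jacobian[fx$pattern$positions])), 0)
  expect_true(all(enf$jacobian[fx$pattern$positions] == 0))
})
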