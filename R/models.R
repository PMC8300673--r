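# Ground-truth model library: deterministic vector fields with known
# steady states and Jacobians, used to generate validation time series.

.new_dyn_model <- function(n, rhs, params, labels, native = NULL,
                           native_data = NULL, positive = FALSE) {
  structure(
    list(n = n, rhs = rhs, params = params, labels = labels,
         native = native, native_data = native_data, positive = positive),
    class = "dyn_model"
  )
}

#' @export
print.dyn_model <- function(x, ...) {
  cat("Dynamical model (", if (is.null(x$native)) "generic" else x$native,
      "), N = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Linear (Ornstein-Uhlenbeck) test-bed model
#'
#' The model `xdot = J x` with steady state at the origin and exact
#' Jacobian `J` everywhere. Driven with additive noise this is a
#' multivariate Ornstein-Uhlenbeck process whose stationary covariance
#' is the forward Lyapunov solution, making it the canonical surrogate
#' for validating the reconstruction.
#'
#' @param J A square drift matrix.
#' @return A `dyn_model`.
#' @export
linear_model <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("J must be square")
  n <- nrow(J)
  .new_dyn_model(
    n = n,
    rhs = function(x, params) drop(J %*% x),
    params = numeric(0),
    labels = paste0("x", seq_len(n)),
    native = "linear",
    native_data = list(jacobian = J)
  )
}

#' Default Rosenzweig-MacArthur metacommunity parameters
#'
#' Read from the packaged configuration file
#' (`inst/extdata/rm_defaults.json`). The set was chosen by a numeric
#' scan so that the single-patch coexistence state undergoes a Hopf
#' bifurcation as the carrying capacity `K` is increased (at default
#' values the crossing sits near `K = 1.47`), with equal prey/predator
#' dispersal so the homogeneous mode is the first to destabilise.
#'
#' @return Named numeric vector with elements `r`, `K`, `a`, `h`,
#'   `eps`, `m`, `g`, `delta_b`, `delta_c`.
#' @export
rm_default_params <- function() {
  path <- system.file("extdata", "rm_defaults.json", package = "jacrecon")
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(vals[c("r", "K", "a", "h", "eps", "m", "g",
                "delta_b", "delta_c")])
}

#' Rosenzweig-MacArthur predator-prey metacommunity
#'
#' Per patch `p`, prey biomass `b_p` and predator biomass `c_p` follow
#' logistic growth, a Holling type-II functional response, linear plus
#' quadratic predator mortality, and diffusive dispersal along the
#' patch network:
#' \deqn{\dot b_p = r b_p (1 - b_p/K) - \frac{a b_p c_p}{1 + a h b_p}
#'   + \delta_b \sum_q A_{pq} (b_q - b_p)}
#' \deqn{\dot c_p = \frac{\epsilon a b_p c_p}{1 + a h b_p} - m c_p
#'   - g c_p^2 + \delta_c \sum_q A_{pq} (c_q - c_p)}
#' Variables are flattened species-fastest: `(b_1, c_1, b_2, c_2, ...)`,
#' so `N = 2 P`.
#'
#' @param params Named vector as returned by [rm_default_params()];
#'   `delta_b`, `delta_c` are the prey/predator dispersal rates.
#' @param net A [patch_network()] or `NULL` for a single isolated patch.
#' @return A `dyn_model` with `positive = TRUE` (states live on the
#'   positive orthant).
#' @export
rm_metacommunity_model <- function(params = rm_default_params(),
                                   net = NULL) {
  need <- c("r", "K", "a", "h", "eps", "m", "g", "delta_b", "delta_c")
  if (!all(need %in% names(params))) {
    stop("params must contain: ", paste(need, collapse = ", "))
  }
  params <- params[need]
  if (any(params[c("r", "K", "a", "h", "eps", "m")] <= 0)) {
    stop("rates r, K, a, h, eps, m must be positive")
  }
  if (any(params[c("g", "delta_b", "delta_c")] < 0)) {
    stop("g, delta_b, delta_c must be nonnegative")
  }
  if (is.null(net)) net <- patch_network(NULL, 1L)
  P <- net$n_nodes
  A <- net$adjacency
  rhs <- function(x, params) {
    b <- x[seq(1, 2 * P, by = 2)]
    cc <- x[seq(2, 2 * P, by = 2)]
    fr <- params[["a"]] * b / (1 + params[["a"]] * params[["h"]] * b)
    db <- params[["r"]] * b * (1 - b / params[["K"]]) - fr * cc +
      params[["delta_b"]] * (drop(A %*% b) - rowSums(A) * b)
    dc <- params[["eps"]] * fr * cc - params[["m"]] * cc -
      params[["g"]] * cc^2 +
      params[["delta_c"]] * (drop(A %*% cc) - rowSums(A) * cc)
    out <- numeric(2 * P)
    out[seq(1, 2 * P, by = 2)] <- db
    out[seq(2, 2 * P, by = 2)] <- dc
    out
  }
  .new_dyn_model(
    n = 2L * P,
    rhs = rhs,
    params = params,
    labels = as.vector(rbind(paste0("b", seq_len(P)),
                             paste0("c", seq_len(P)))),
    native = "rm",
    native_data = list(adjacency = A, n_patches = P),
    positive = TRUE
  )
}

#' Find a steady state by damped Newton iteration
#'
#' Solves `f(x*) = 0` by Newton steps with step-halving damping, using
#' the finite-difference Jacobian. For models on the positive orthant
#' (`model$positive`), solutions with negative components are rejected
#' and the offending components reported.
#'
#' @param model A `dyn_model`.
#' @param x0 Starting point.
#' @param tol Convergence tolerance on `max |f(x)|` (default 1e-12).
#' @param max_iter Maximum Newton iterations.
#' @return List of class `steady_state`: `x` (the root), `residual`
#'   (`||f(x*)||`), `iterations`.
#' @export
find_steady_state <- function(model, x0, tol = 1e-12, max_iter = 100L) {
  stopifnot(inherits(model, "dyn_model"))
  x <- as.numeric(x0)
  if (length(x) != model$n) stop("x0 has length ", length(x),
                                 ", model dimension is ", model$n)
  if (!all(is.finite(x))) stop("x0 must be finite")
  f <- model$rhs(x, model$params)
  trace_norm <- max(abs(f))
  for (iter in seq_len(max_iter)) {
    if (max(abs(f)) <= tol) break
    J <- numeric_jacobian(model, x)
    step <- tryCatch(-solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      stop("steady-state search failed: singular Jacobian at iteration ",
           iter, " (|f| trace: ", paste(signif(trace_norm, 3),
                                        collapse = ", "), ")")
    }
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- model$rhs(xn, model$params)
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(f))) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    if (lambda < 1e-12) {
      stop("steady-state search failed to make progress at iteration ",
           iter, " (|f| trace: ", paste(signif(trace_norm, 3),
                                        collapse = ", "), ")")
    }
    x <- xn
    f <- fn
    trace_norm <- c(trace_norm, max(abs(f)))
  }
  if (max(abs(f)) > tol) {
    stop("steady-state search did not converge after ", max_iter,
         " iterations (|f| trace: ",
         paste(signif(utils::tail(trace_norm, 5), 3), collapse = ", "), ")")
  }
  if (isTRUE(model$positive) && any(x < -1e-9)) {
    bad <- which(x < -1e-9)
    stop("steady state has negative components at position(s) ",
         paste(bad, collapse = ", "),
         " (values ", paste(signif(x[bad], 3), collapse = ", "), ")")
  }
  structure(list(x = x, residual = sqrt(sum(f^2)), iterations = iter),
            class = "steady_state")
}

#' Finite-difference Jacobian of a model at a point
#'
#' Central differences with per-variable step `step * max(1, |x_i|)`
#' (truncation error `O(step^2)`). Serves as the analytic ground truth
#' against which reconstructions are compared.
#'
#' @param model A `dyn_model`.
#' @param x Evaluation point (a `steady_state` or numeric vector).
#' @param step Base step size (default 1e-6).
#' @return An `N` x `N` matrix.
#' @export
numeric_jacobian <- function(model, x, step = 1e-6) {
  stopifnot(inherits(model, "dyn_model"))
  if (inherits(x, "steady_state")) x <- x$x
  x <- as.numeric(x)
  n <- model$n
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- step * max(1, abs(x[j]))
    e <- numeric(n)
    e[j] <- h
    J[, j] <- (model$rhs(x + e, model$params) -
                 model$rhs(x - e, model$params)) / (2 * h)
  }
  J
}

#' Master-stability spectrum of a homogeneous steady state
#'
#' For diffusively coupled identical patches at a homogeneous steady
#' state, the full `S P` x `S P` Jacobian block-diagonalises over the
#' Laplacian eigenmodes: its spectrum is the union over Laplacian
#' eigenvalues `lambda_k` of the spectra of
#' `P_intra - lambda_k * diag(coupling)`.
#'
#' @param intra_jacobian The `S` x `S` within-patch Jacobian at the
#'   homogeneous state (including any self-coupling from local terms,
#'   excluding dispersal).
#' @param coupling Per-species dispersal rates (length `S`).
#' @param laplacian_eigenvalues Eigenvalues of the patch-network
#'   Laplacian (length `P`).
#' @return Complex vector of all `S * P` eigenvalues, ordered as in
#'   [jacobian_spectrum()].
#' @export
msf_spectrum <- function(intra_jacobian, coupling, laplacian_eigenvalues) {
  intra_jacobian <- as.matrix(intra_jacobian)
  S <- nrow(intra_jacobian)
  if (ncol(intra_jacobian) != S) stop("intra_jacobian must be square")
  if (length(coupling) != S) {
    stop("coupling must have one rate per species (length ", S, ")")
  }
  vals <- lapply(laplacian_eigenvalues, function(lk) {
    eigen(intra_jacobian - lk * diag(coupling, nrow = S),
          only.values = TRUE)$values
  })
  v <- as.complex(unlist(vals))
  v[order(-Re(v), abs(Im(v)), -Im(v))]
}
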