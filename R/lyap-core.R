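# Core of the package: closed-form constrained reconstruction of a
# Jacobian J from the stationary covariance Gamma and the noise
# fluctuation matrix D via J Gamma + Gamma J' = -2 D, plus the exact
# forward solver used as a ground-truth oracle.

# Symmetry gate for covariance-like inputs. Sample covariances are
# symmetric by construction; mild asymmetry is numerical noise and is
# averaged away, large asymmetry signals a user error.
.check_symmetric <- function(X, label, warn_tol = 1e-8, fail_tol = 1e-3,
                             on_asymmetric = c("warn", "error")) {
  on_asymmetric <- match.arg(on_asymmetric)
  scale <- max(abs(X), 1e-300)
  asym <- max(abs(X - t(X))) / scale
  if (asym > fail_tol || (asym > warn_tol && on_asymmetric == "error")) {
    stop(label, " is asymmetric (relative asymmetry ", signif(asym, 3), ")")
  }
  if (asym > warn_tol) {
    warning(label, " is slightly asymmetric (relative asymmetry ",
            signif(asym, 3), "); symmetrising")
  }
  (X + t(X)) / 2
}

#' Design matrix of the vectorised Lyapunov relation
#'
#' Builds `B = (Gamma \%x\% I) + (I \%x\% Gamma) C`, the `N^2` x `N^2`
#' matrix with `B vec(J) = vec(J Gamma + Gamma J')` for every `N` x `N`
#' matrix `J`. `C` is the [commutation_matrix()].
#'
#' Because the Lyapunov relation equates two symmetric matrices, `B` has
#' rank `N (N + 1) / 2` for generic positive-definite `Gamma`: the rows
#' belonging to entry `(i, j)` and entry `(j, i)` are identical.
#'
#' @param Gamma Symmetric covariance matrix of the fluctuations.
#' @param on_asymmetric `"warn"` (default) symmetrises mildly asymmetric
#'   input with a warning; `"error"` fails instead. Relative asymmetry
#'   above 1e-3 always fails.
#' @return A dense `N^2` x `N^2` matrix.
#' @export
build_design <- function(Gamma, on_asymmetric = c("warn", "error")) {
  Gamma <- as.matrix(Gamma)
  if (nrow(Gamma) != ncol(Gamma)) stop("Gamma must be square")
  Gamma <- .check_symmetric(Gamma, "Gamma", on_asymmetric = on_asymmetric)
  n <- nrow(Gamma)
  I <- diag(n)
  q <- .vec_transpose_perm(n)
  # (I %x% Gamma) C permutes columns of I %x% Gamma by the involution q
  kronecker(Gamma, I) + kronecker(I, Gamma)[, q, drop = FALSE]
}

#' Stack structural-zero constraints under the Lyapunov design
#'
#' Appends one row per structural zero to the design matrix: row `m` has
#' a single entry `weight` in the column of the vec-position of the
#' `m`-th constrained Jacobian entry, with right-hand side 0. The
#' resulting stacked system `B_hat j = d_hat` is what the closed-form
#' least-squares solution acts on.
#'
#' @param B Design matrix from [build_design()].
#' @param d Right-hand side of the unconstrained block; for the Lyapunov
#'   relation this is `-2 * vec(D)`.
#' @param pattern A [zero_pattern()].
#' @param weight Scalar weight of the constraint rows (default 1, the
#'   plain stacked system).
#' @return An object of class `design_system`: list with `design`,
#'   `rhs`, `n`, `n_data` (number of data rows), `pattern`, `weight`.
#' @export
stack_constraints <- function(B, d, pattern, weight = 1) {
  B <- as.matrix(B)
  n2 <- ncol(B)
  n <- as.integer(round(sqrt(n2)))
  if (n * n != n2) stop("design matrix must have N^2 columns")
  if (length(d) != nrow(B)) stop("length(d) must equal nrow(B)")
  if (!inherits(pattern, "zero_pattern")) pattern <- zero_pattern(pattern, n)
  if (pattern$n != n) {
    stop("pattern dimension (", pattern$n, ") does not match design (", n, ")")
  }
  pos <- .pattern_vec_pos(pattern)
  U <- matrix(0, nrow = length(pos), ncol = n2)
  if (length(pos)) U[cbind(seq_along(pos), pos)] <- weight
  structure(
    list(design = rbind(B, U), rhs = c(d, numeric(length(pos))),
         n = n, n_data = nrow(B), pattern = pattern, weight = weight),
    class = "design_system"
  )
}

#' Least-squares solution of a stacked reconstruction system
#'
#' Minimises `||B_hat j - d_hat||^2` by a rank-revealing orthogonal
#' decomposition (LAPACK QR with column pivoting). On full-column-rank
#' systems this equals the normal-equations solution
#' `(B_hat' B_hat)^{-1} B_hat' d_hat`; rank-deficient systems fall back
#' to the SVD minimum-norm solution and are flagged.
#'
#' @param system A `design_system` from [stack_constraints()].
#' @return List with `coefficients` (the vectorised Jacobian estimate),
#'   `rank`, `rank_deficient`, and `residual_norm` (Euclidean norm of
#'   the misfit over the data rows only, excluding constraint rows).
#' @export
solve_reconstruction <- function(system) {
  stopifnot(inherits(system, "design_system"))
  A <- system$design
  b <- system$rhs
  if (all(A == 0)) stop("degenerate input: design matrix is identically zero")
  qrA <- qr(A, LAPACK = TRUE)
  rdiag <- abs(diag(qr.R(qrA)))
  tol <- max(dim(A)) * .Machine$double.eps * max(rdiag, 0)
  rank <- sum(rdiag > tol)
  if (rank == ncol(A)) {
    j <- qr.coef(qrA, b)
  } else {
    # minimum-norm least-squares via SVD
    sv <- svd(A)
    keep <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
    j <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
    j <- drop(j)
  }
  resid <- A[seq_len(system$n_data), , drop = FALSE] %*% j -
    b[seq_len(system$n_data)]
  list(coefficients = unname(j), rank = rank,
       rank_deficient = rank < ncol(A),
       residual_norm = sqrt(sum(resid^2)))
}

# Fast path for large systems: the normal equations of the stacked
# system have the closed form
#   B'B = 2 (Gamma^2 (x) I) + (Gamma (x) Gamma) C + C (Gamma (x) Gamma)
#   B'(-2 vec D) = -2 vec(D Gamma + D' Gamma)
# (C the commutation matrix, applied as an index permutation), so the
# stacked design never has to be materialised. Solved by Cholesky;
# failure (rank deficiency) falls back to the explicit QR/SVD route.
.solve_normal_gamma <- function(Gamma, D, pattern, weight) {
  n <- nrow(Gamma)
  q <- .vec_transpose_perm(n)
  K <- kronecker(Gamma, Gamma)
  Kq <- K[, q, drop = FALSE]
  M <- 2 * kronecker(Gamma %*% Gamma, diag(n)) + Kq + t(Kq)
  pos <- .pattern_vec_pos(pattern)
  if (length(pos)) {
    idx <- cbind(pos, pos)
    M[idx] <- M[idx] + weight^2
  }
  rhs <- -2 * vec(D %*% Gamma + crossprod(D, Gamma))
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  j <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  list(coefficients = unname(drop(j)), rank = n * n, rank_deficient = FALSE)
}

#' Reconstruct a Jacobian from covariance, noise and structural zeros
#'
#' The closed-form reconstruction: given the stationary covariance
#' `Gamma` of fluctuations about a steady state, the fluctuation matrix
#' `D` of the driving noise, and a set of structurally zero Jacobian
#' entries, solves the stacked least-squares system built from the
#' vectorised Lyapunov relation `J Gamma + Gamma J' = -2 D` and returns
#' the Jacobian estimate together with its spectrum.
#'
#' With fewer than `N (N - 1) / 2` structural zeros the system is
#' underdetermined and a warning is issued; the minimum-norm solution is
#' still returned, flagged in the result.
#'
#' @param Gamma Symmetric `N` x `N` covariance matrix.
#' @param D Symmetric `N` x `N` fluctuation matrix of the noise.
#' @param pattern A [zero_pattern()] of structural zeros.
#' @param enforce_zeros If `TRUE` (default) the constrained entries of
#'   the returned Jacobian are set exactly to zero after the solve,
#'   which improves the accuracy of the reconstructed eigenvalues.
#' @param weight Scalar weight for the constraint rows (default 1).
#' @param method `"auto"` (default) uses the explicit orthogonal
#'   decomposition up to `N = 40` and the equivalent normal-equations
#'   fast path above; `"qr"` and `"normal"` force a path.
#' @param on_asymmetric Passed to [build_design()].
#' @return An object of class `jac_reconstruction`: list with
#'   `jacobian`, `residual_norm`, `rank`, `rank_deficient`,
#'   `eigenvalues` (sorted by descending real part), `leading_eigenvalue`,
#'   `leading_type` (`"real"` or `"complex-pair"`), `zeros_enforced`,
#'   `underdetermined`.
#' @examples
#' J <- rbind(c(-1, 0), c(0.5, -2))
#' D <- diag(2)
#' G <- forward_lyapunov(J, D)
#' reconstruct_jacobian(G, D, zero_pattern(rbind(c(1, 2)), 2))
#' @export
reconstruct_jacobian <- function(Gamma, D, pattern,
                                 enforce_zeros = TRUE, weight = 1,
                                 method = c("auto", "qr", "normal"),
                                 on_asymmetric = c("warn", "error")) {
  method <- match.arg(method)
  Gamma <- as.matrix(Gamma)
  D <- as.matrix(D)
  n <- nrow(Gamma)
  if (ncol(Gamma) != n || !all(dim(D) == n)) {
    stop("Gamma and D must be square matrices of the same dimension")
  }
  Gamma <- .check_symmetric(Gamma, "Gamma", on_asymmetric = on_asymmetric)
  D <- .check_symmetric(D, "D", on_asymmetric = on_asymmetric)
  if (!inherits(pattern, "zero_pattern")) pattern <- zero_pattern(pattern, n)
  if (pattern$n != n) stop("pattern dimension does not match Gamma")

  suff <- sufficiency_check(pattern, n)
  if (!suff$sufficient) {
    warning("only ", suff$count, " structural zeros supplied; ",
            suff$required, " are needed for a determined system -- ",
            "the reconstruction is underdetermined")
  }

  if (method == "auto") method <- if (n * n <= 1600) "qr" else "normal"

  sol <- NULL
  if (method == "normal") {
    sol <- .solve_normal_gamma(Gamma, D, pattern, weight)
    # NULL means the penalised normal matrix was not positive definite
    # (rank-deficient system); fall through to the explicit route.
  }
  if (is.null(sol)) {
    B <- build_design(Gamma, on_asymmetric = "warn")
    system <- stack_constraints(B, -2 * vec(D), pattern, weight = weight)
    sol <- solve_reconstruction(system)
  }

  J <- unvec(sol$coefficients, n)
  if (enforce_zeros && length(pattern) > 0L) {
    J[pattern$positions] <- 0
  }
  # misfit of the returned Jacobian over the data block of the stack
  resid <- J %*% Gamma + Gamma %*% t(J) + 2 * D
  spec <- jacobian_spectrum(J)
  structure(
    list(jacobian = J,
         residual_norm = sqrt(sum(resid^2)),
         rank = sol$rank,
         rank_deficient = isTRUE(sol$rank_deficient),
         eigenvalues = spec$values,
         leading_eigenvalue = spec$leading,
         leading_type = spec$type,
         zeros_enforced = enforce_zeros,
         underdetermined = !suff$sufficient,
         pattern = pattern),
    class = "jac_reconstruction"
  )
}

#' @export
print.jac_reconstruction <- function(x, ...) {
  n <- nrow(x$jacobian)
  cat("Jacobian reconstruction (N = ", n, ")\n", sep = "")
  cat("  leading eigenvalue: ", format(x$leading_eigenvalue, digits = 6),
      "  [", x$leading_type, "]\n", sep = "")
  cat("  residual norm (data rows): ", signif(x$residual_norm, 4), "\n",
      sep = "")
  if (x$underdetermined) cat("  WARNING: underdetermined system\n")
  if (x$rank_deficient) cat("  note: rank-deficient design (rank ",
                            x$rank, ")\n", sep = "")
  invisible(x)
}

#' Solve the forward Lyapunov equation
#'
#' Computes the stationary covariance `Gamma` with
#' `J Gamma + Gamma J' = -2 D` for a Hurwitz-stable `J`. This is the
#' exact forward model of the fluctuations and serves as the
#' ground-truth oracle for the reconstruction: simulated stationary
#' covariances converge to it.
#'
#' The solver diagonalises `J` and solves entrywise in the eigenbasis;
#' if `J` is defective or the residual check fails it falls back to a
#' dense solve of the `N^2` Kronecker system.
#'
#' @param J A Hurwitz-stable Jacobian (all eigenvalue real parts < 0).
#' @param D Symmetric positive-semidefinite fluctuation matrix.
#' @return The symmetric covariance matrix `Gamma`.
#' @export
forward_lyapunov <- function(J, D) {
  J <- as.matrix(J)
  D <- as.matrix(D)
  n <- nrow(J)
  if (ncol(J) != n || !all(dim(D) == n)) {
    stop("J and D must be square matrices of the same dimension")
  }
  ev <- eigen(J)
  if (max(Re(ev$values)) >= 0) {
    stop("J is not Hurwitz-stable (leading real part ",
         signif(max(Re(ev$values)), 4),
         "); no stationary covariance exists")
  }
  Gamma <- NULL
  if (min(svd(ev$vectors)$d) > 1e-10) {
    V <- ev$vectors
    W <- solve(V)
    Dt <- W %*% D %*% t(W)
    denom <- outer(ev$values, ev$values, `+`)
    Gt <- -2 * Dt / denom
    Gamma <- Re(V %*% Gt %*% t(V))
    Gamma <- (Gamma + t(Gamma)) / 2
    resid <- J %*% Gamma + Gamma %*% t(J) + 2 * D
    if (sqrt(sum(resid^2)) > 1e-10 * max(sqrt(sum(D^2)), 1e-300)) {
      Gamma <- NULL
    }
  }
  if (is.null(Gamma)) {
    # dense Kronecker solve: (I (x) J + J (x) I) vec(Gamma) = -2 vec(D)
    A <- kronecker(diag(n), J) + kronecker(J, diag(n))
    Gamma <- unvec(solve(A, -2 * vec(D)), n)
    Gamma <- (Gamma + t(Gamma)) / 2
  }
  Gamma
}

#' Eigenvalue spectrum of a Jacobian, ordered for stability analysis
#'
#' Eigenvalues sorted by descending real part, ties broken by ascending
#' `|Im|`, conjugate partners with nonnegative imaginary part first, so
#' the first entry is the leading eigenvalue that determines local
#' stability. The leading eigenvalue is tagged `"real"` (fold-type
#' candidate) or `"complex-pair"` (Hopf-type candidate).
#'
#' @param J A square numeric matrix with finite entries.
#' @param imag_tol Relative tolerance below which the leading imaginary
#'   part is treated as zero.
#' @return List with `values` (complex vector), `leading`, `type`.
#' @export
jacobian_spectrum <- function(J, imag_tol = 1e-8) {
  J <- as.matrix(J)
  if (!all(is.finite(J))) stop("J contains non-finite entries")
  v <- eigen(J, only.values = TRUE)$values
  v <- as.complex(v)
  ord <- order(-Re(v), abs(Im(v)), -Im(v))
  v <- v[ord]
  lead <- v[1]
  type <- if (abs(Im(lead)) <= imag_tol * max(1, abs(lead))) {
    "real"
  } else {
    "complex-pair"
  }
  list(values = v, leading = lead, type = type)
}
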