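#' Structural zero pattern of a Jacobian
#'
#' A set of matrix positions `(i, j)` at which the Jacobian is known to be
#' exactly zero because the corresponding variables cannot interact
#' directly. These constraints are what make the Lyapunov inversion
#' determined; at least `n (n - 1) / 2` of them are needed for a full
#' reconstruction (see [sufficiency_check()]).
#'
#' @param positions A two-column matrix (or data.frame) of 1-based
#'   `(row, col)` index pairs; may have zero rows.
#' @param n Dimension of the Jacobian the pattern refers to.
#' @return An object of class `zero_pattern` with fields `positions`
#'   (integer matrix) and `n`.
#' @examples
#' zero_pattern(rbind(c(1, 2)), n = 2)   # J[1,2] = 0
#' @export
zero_pattern <- function(positions, n) {
  n <- as.integer(n)
  if (is.null(positions) || NROW(positions) == 0L) {
    pos <- matrix(integer(0), ncol = 2L)
  } else {
    pos <- as.matrix(positions)
    if (ncol(pos) != 2L) stop("positions must have two columns (row, col)")
    storage.mode(pos) <- "integer"
  }
  if (nrow(pos) > 0L) {
    if (any(pos < 1L) || any(pos > n)) {
      stop("pattern indices must lie in [1, ", n, "]")
    }
    key <- .vec_pos(pos[, 1L], pos[, 2L], n)
    if (anyDuplicated(key)) stop("pattern contains duplicate positions")
  }
  dimnames(pos) <- list(NULL, c("row", "col"))
  structure(list(positions = pos, n = n), class = "zero_pattern")
}

#' @export
length.zero_pattern <- function(x) nrow(x$positions)

#' @export
print.zero_pattern <- function(x, ...) {
  cat("Structural zero pattern: ", length(x), " positions in a ",
      x$n, "x", x$n, " Jacobian\n", sep = "")
  suff <- sufficiency_check(x, x$n)
  cat(if (suff$sufficient) "sufficient" else "NOT sufficient",
      " for full reconstruction (", suff$count, " of ",
      suff$required, " required)\n", sep = "")
  invisible(x)
}

# vec-positions of the constrained entries
.pattern_vec_pos <- function(pattern) {
  if (length(pattern) == 0L) return(integer(0))
  .vec_pos(pattern$positions[, 1L], pattern$positions[, 2L], pattern$n)
}

#' Does a zero pattern determine the reconstruction?
#'
#' The symmetric Lyapunov relation supplies `n (n + 1) / 2` independent
#' conditions on the `n^2` Jacobian entries, so at least `n (n - 1) / 2`
#' structural zeros are needed to pin down the remainder. The count is
#' checked by explicit enumeration.
#'
#' The count is necessary but not always enough: the *placement* of the
#' zeros decides identifiability. (Example: if two variables form a
#' block with no constrained entry inside it and none connecting it to
#' the rest, their mutual couplings stay undetermined however many
#' zeros sit elsewhere.) With `structural = TRUE` the check also
#' verifies, at a generic covariance, that no unconstrained direction
#' remains: the stacked system is rank deficient exactly when some
#' nonzero `X = A G^{-1}` with antisymmetric `A` vanishes at every
#' pattern position, so full column rank of the corresponding
#' constraint matrix certifies a determined reconstruction.
#'
#' @param pattern A [zero_pattern()] (or two-column index matrix).
#' @param n Jacobian dimension.
#' @param structural If `TRUE`, additionally perform the rank-based
#'   identifiability test (deterministic; cost grows as `n^4`).
#' @param Gamma Optional covariance matrix at which to test
#'   identifiability. If omitted, a fixed generic matrix is used, which
#'   tests the pattern's placement for a system in general position;
#'   supplying the actual `Gamma` tests the specific system (a
#'   block-decoupled system, for instance, inherits extra degeneracy
#'   that a generic covariance does not show).
#' @return A list with `sufficient` (logical), `count`, `required`,
#'   and — when `structural = TRUE` — `identifiable`. `sufficient` then
#'   requires both the count and identifiability.
#' @export
sufficiency_check <- function(pattern, n, structural = FALSE,
                              Gamma = NULL) {
  if (!inherits(pattern, "zero_pattern")) pattern <- zero_pattern(pattern, n)
  cnt <- length(pattern)
  req <- n * (n - 1L) / 2
  out <- list(sufficient = cnt >= req, count = cnt, required = req)
  if (structural) {
    out$identifiable <- out$sufficient &&
      .pattern_identifiable(pattern, n, Gamma)
    out$sufficient <- out$identifiable
  }
  out
}

# Rank-based identifiability: the unconstrained Lyapunov design has
# null space {vec(A G^-1) : A antisymmetric}; the pattern determines
# the system iff no nonzero such matrix vanishes at all constrained
# positions, i.e. iff the constraint matrix over the antisymmetric
# basis has full column rank. Without a covariance a fixed generic M
# (deterministic congruential values, RNG-free) stands in for G^-1.
.pattern_identifiable <- function(pattern, n, Gamma = NULL) {
  if (n == 1L) return(TRUE)
  nb <- n * (n - 1L) / 2L
  if (length(pattern) < nb) return(FALSE)
  if (is.null(Gamma)) {
    v <- ((seq_len(n * n) * 48271) %% 65537) / 65537
    M <- matrix(v, n, n) + diag(n)
  } else {
    M <- solve(Gamma)
  }
  kl <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pos <- pattern$positions
  C <- matrix(0, nrow(pos), nb)
  for (b in seq_len(nb)) {
    k <- kl[b, 1L]
    l <- kl[b, 2L]
    C[, b] <- (pos[, 1L] == k) * M[l, pos[, 2L]] -
      (pos[, 1L] == l) * M[k, pos[, 2L]]
  }
  qr(C)$rank == nb
}
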