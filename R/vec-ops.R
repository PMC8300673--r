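#' Vectorise a square matrix by column stacking
#'
#' Stacks the columns of `X` on top of each other, so that element
#' `(i, j)` of the matrix lands at position `(j - 1) * N + i` of the
#' vector. This is the convention under which `vec(J Gamma) =
#' (Gamma' \%x\% I) vec(J)` and friends hold.
#'
#' @param X A square numeric matrix.
#' @return A numeric vector of length `N^2`.
#' @seealso [unvec()], [commutation_matrix()]
#' @examples
#' vec(matrix(1:4, 2, 2))
#' @export
vec <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) != ncol(X)) {
    stop("vec() expects a square matrix, got ", nrow(X), "x", ncol(X))
  }
  as.vector(X)
}

#' Invert the column-stacking vectorisation
#'
#' @param v A numeric vector of length `n^2`.
#' @param n Row (= column) dimension of the result.
#' @return An `n` x `n` matrix with `vec(unvec(v, n)) == v`.
#' @export
unvec <- function(v, n) {
  if (length(v) != n * n) {
    stop("unvec() needs a vector of length n^2 = ", n * n,
         ", got length ", length(v))
  }
  matrix(v, nrow = n, ncol = n)
}

# Permutation q with (C v)[k] = v[q[k]], i.e. the vec-transpose shuffle.
# q is an involution: applying it twice restores the original order.
.vec_transpose_perm <- function(n) {
  as.vector(matrix(seq_len(n * n), n, n, byrow = TRUE))
}

# vec-position of matrix entry (i, j) in an n x n matrix
.vec_pos <- function(i, j, n) (j - 1L) * n + i

#' Commutation matrix
#'
#' The `N^2` x `N^2` permutation matrix `C` with `C %*% vec(X) ==
#' vec(t(X))` for every `N` x `N` matrix `X`. `C` is symmetric and
#' self-inverse. In block form the `(n, m)` block of size `N` x `N` has
#' entries `(C_nm)_ij = delta_im delta_nj`.
#'
#' @param n Matrix dimension `N` (positive integer).
#' @return A dense `n^2` x `n^2` 0/1 matrix.
#' @examples
#' commutation_matrix(2)
#' @export
commutation_matrix <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  q <- .vec_transpose_perm(n)
  diag(n * n)[q, , drop = FALSE]
}
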