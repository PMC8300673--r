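# Deterministic fixture generators used by the tests and the CLI.

#' Six-node completely asymmetric fixture graph
#'
#' A six-node, six-edge connected graph whose only automorphism is the
#' identity (asserted by brute force in the test suite). Serves as the
#' small spatial topology for metacommunity experiments; it is a
#' documented stand-in, not a claim to reproduce any particular
#' published topology.
#'
#' @return A [patch_network()] with edges 1-2, 2-3, 3-1, 3-4, 4-5, 1-6.
#' @export
fixture_asym6 <- function() {
  patch_network(rbind(c(1, 2), c(2, 3), c(3, 1),
                      c(3, 4), c(4, 5), c(1, 6)), 6L)
}

#' Count graph automorphisms by brute force
#'
#' Enumerates all vertex permutations (feasible for `n <= 8`) and
#' counts those preserving adjacency. A completely asymmetric graph
#' returns 1.
#'
#' @param net A [patch_network()].
#' @return Integer count of automorphisms.
#' @export
graph_automorphism_count <- function(net) {
  stopifnot(inherits(net, "patch_network"))
  n <- net$n_nodes
  if (n > 8L) stop("brute-force automorphism count is limited to n <= 8")
  A <- net$adjacency
  perms <- .permutations(n)
  sum(vapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    identical(A[p, p], A)
  }, logical(1)))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' 15-node random geometric fixture graph
#'
#' Nodes are placed uniformly in the unit square and joined when closer
#' than `radius` (via `igraph::sample_grg`). The generator retries with
#' seeds derived deterministically from `seed` until the graph is
#' connected, so the result is reproducible.
#'
#' @param seed Integer seed.
#' @param radius Connection radius (default 0.4).
#' @return A connected [patch_network()] on 15 nodes.
#' @export
fixture_rgg15 <- function(seed = 42L, radius = 0.4) {
  for (try in 0:50) {
    set.seed(seed + 101L * try)
    g <- igraph::sample_grg(15L, radius)
    el <- igraph::as_edgelist(g, names = FALSE)
    net <- suppressWarnings(patch_network(el, 15L))
    if (.is_connected(net)) return(net)
  }
  stop("no connected geometric graph found; increase the radius")
}

#' Random stable sparse Jacobian with known zero pattern
#'
#' Off-diagonal entries are nonzero independently with probability
#' `density` (values uniform on `[-1, 1]`); each diagonal entry is set
#' below minus the absolute row sum, so the matrix is strictly
#' diagonally dominant and hence Hurwitz-stable by Gershgorin's
#' theorem. Draws whose interaction graph (the undirected support of
#' the off-diagonal entries) is disconnected are rejected and redrawn
#' with a seed derived from `seed`: the fixture emulates one coupled
#' network, and a decoupled block with no constrained entry would make
#' its couplings genuinely unrecoverable from covariance data. The
#' zero pattern collects all off-diagonal zeros, which for
#' `density <= 0.5` is enough to determine the reconstruction.
#'
#' @param n Dimension.
#' @param density Probability of an off-diagonal entry being nonzero.
#' @param seed Integer seed.
#' @return List with `jacobian` and `pattern` (a [zero_pattern()]).
#' @export
fixture_stable_jacobian <- function(n, density = 0.15, seed = 1L) {
  for (attempt in 0:200) {
    set.seed(seed + 613L * attempt)
    J <- matrix(0, n, n)
    off <- which(!diag(TRUE, n))
    nz <- off[stats::runif(length(off)) < density]
    J[nz] <- stats::runif(length(nz), -1, 1)
    diag(J) <- -rowSums(abs(J)) - stats::runif(n, 0.5, 1.5)
    support <- (J != 0 | t(J) != 0) & !diag(TRUE, n)
    net <- structure(list(n_nodes = n, adjacency = support + 0L),
                     class = "patch_network")
    if (n == 1L || .is_connected(net)) {
      zeros <- which(J == 0 & !diag(TRUE, n), arr.ind = TRUE)
      return(list(jacobian = J, pattern = zero_pattern(zeros, n)))
    }
  }
  stop("no connected interaction graph found; increase the density")
}
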