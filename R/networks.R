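# Structural-zero patterns from network and multilayer topology.
# Non-adjacent nodes cannot interact directly, so the corresponding
# Jacobian entries are structurally zero; in a metacommunity a species
# additionally cannot affect a *different* species in a *different*
# patch, which alone supplies S*P*(S-1)*(P-1) zeros.

#' Spatial patch network
#'
#' An undirected network of habitat patches (or generic nodes). Only
#' the topology matters: edges carry no weights.
#'
#' @param edges Two-column matrix of 1-based undirected edges; may have
#'   zero rows.
#' @param n_nodes Number of nodes `P`.
#' @return Object of class `patch_network` with fields `n_nodes`,
#'   `edges`, `adjacency` (0/1 symmetric matrix) and `mean_degree`.
#' @examples
#' patch_network(rbind(c(1, 2), c(2, 3)), 3)  # path graph
#' @export
patch_network <- function(edges, n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("n_nodes must be >= 1")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
  }
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_nodes)) stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  A <- matrix(0L, n_nodes, n_nodes)
  if (nrow(edges)) {
    A[edges] <- 1L
    A[edges[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  net <- structure(
    list(n_nodes = n_nodes, edges = edges, adjacency = A,
         mean_degree = if (n_nodes) 2 * nrow(edges) / n_nodes else 0),
    class = "patch_network"
  )
  if (!.is_connected(net)) {
    warning("patch network is not connected")
  }
  net
}

.is_connected <- function(net) {
  n <- net$n_nodes
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(net$adjacency[v, ] > 0L & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.patch_network <- function(x, ...) {
  cat("Patch network: ", x$n_nodes, " nodes, ", nrow(x$edges),
      " edges (mean degree ", signif(x$mean_degree, 3), ")\n", sep = "")
  invisible(x)
}

#' Graph Laplacian of a patch network
#'
#' `L = diag(degree) - A`. Its eigenvalues index the spatial modes of
#' diffusively coupled dynamics (see [msf_spectrum()]).
#'
#' @param net A [patch_network()].
#' @return A symmetric `P` x `P` matrix.
#' @export
laplacian_matrix <- function(net) {
  stopifnot(inherits(net, "patch_network"))
  diag(rowSums(net$adjacency)) - net$adjacency
}

#' Trophic food web
#'
#' Directed predator-prey links among `S` species.
#'
#' @param links Two-column matrix of 1-based (predator, prey) pairs.
#' @param n_species Number of species `S`.
#' @return Object of class `foodweb_graph`.
#' @export
foodweb_graph <- function(links, n_species) {
  n_species <- as.integer(n_species)
  if (n_species < 1L) stop("n_species must be >= 1")
  if (is.null(links) || NROW(links) == 0L) {
    links <- matrix(integer(0), ncol = 2L)
  } else {
    links <- as.matrix(links)
    storage.mode(links) <- "integer"
  }
  if (ncol(links) != 2L) stop("links must have two columns (predator, prey)")
  if (nrow(links)) {
    if (any(links < 1L) || any(links > n_species)) {
      stop("link index out of range")
    }
    if (anyDuplicated(paste(links[, 1L], links[, 2L]))) {
      stop("duplicate links are not allowed")
    }
  }
  structure(list(n_species = n_species, links = links),
            class = "foodweb_graph")
}

#' Index flattening for multilayer (species x patch) systems
#'
#' Maps variable (species `s`, patch `p`) to flat index
#' `(p - 1) * S + s` (species-fastest), so the full dynamical dimension
#' is `N = S * P` and the state vector lists all species of patch 1,
#' then all species of patch 2, and so on.
#'
#' @param S Number of species per patch.
#' @param P Number of patches.
#' @return Object of class `multilayer_index` with fields `S`, `P`, `n`
#'   and `flat(s, p)`.
#' @export
multilayer_index <- function(S, P) {
  S <- as.integer(S)
  P <- as.integer(P)
  if (S < 1L || P < 1L) stop("S and P must be positive")
  structure(
    list(S = S, P = P, n = S * P,
         flat = function(s, p) (p - 1L) * S + s),
    class = "multilayer_index"
  )
}

#' Structural zeros from network non-adjacency
#'
#' In dynamics on a network only neighbouring nodes interact directly,
#' so every ordered pair of distinct non-adjacent nodes is a structural
#' zero of the Jacobian. Diagonal entries are never included.
#'
#' @param net A [patch_network()].
#' @return A [zero_pattern()] of dimension `P`.
#' @examples
#' network_zero_pattern(patch_network(rbind(c(1, 2), c(2, 3)), 3))
#' @export
network_zero_pattern <- function(net) {
  stopifnot(inherits(net, "patch_network"))
  n <- net$n_nodes
  nonadj <- which(net$adjacency == 0L & !diag(TRUE, n), arr.ind = TRUE)
  zero_pattern(nonadj, n)
}

#' Structural zeros of a multilayer metacommunity Jacobian
#'
#' Combines up to three categories of forbidden interactions in a
#' species-by-patch system:
#' \describe{
#'   \item{cross-layer}{a species in one patch cannot affect a
#'     *different* species in a *different* patch; always
#'     `S P (S - 1)(P - 1)` ordered pairs, independent of topology.}
#'   \item{spatial}{the same species in two distinct *non-adjacent*
#'     patches cannot interact (dispersal is along edges only).}
#'   \item{trophic}{within one patch, species without a trophic link in
#'     either direction. Off by default: shared predators make
#'     unlinked species interact indirectly (prey switching), so absent
#'     links do not guarantee Jacobian zeros.}
#' }
#'
#' @param idx A [multilayer_index()].
#' @param net A [patch_network()] on `P` patches.
#' @param web A [foodweb_graph()] on `S` species (only needed when
#'   `trophic = TRUE`).
#' @param cross_layer,spatial,trophic Logical switches for the three
#'   categories.
#' @return A [zero_pattern()] of dimension `S * P`.
#' @export
multilayer_zero_pattern <- function(idx, net, web = NULL,
                                    cross_layer = TRUE, spatial = TRUE,
                                    trophic = FALSE) {
  stopifnot(inherits(idx, "multilayer_index"))
  stopifnot(inherits(net, "patch_network"))
  if (net$n_nodes != idx$P) stop("patch network size does not match index")
  S <- idx$S
  P <- idx$P
  rows <- list()
  if (cross_layer) {
    for (p in seq_len(P)) for (q in seq_len(P)) {
      if (p == q) next
      for (s in seq_len(S)) for (u in seq_len(S)) {
        if (s == u) next
        rows[[length(rows) + 1L]] <- c(idx$flat(s, p), idx$flat(u, q))
      }
    }
  }
  if (spatial) {
    for (p in seq_len(P)) for (q in seq_len(P)) {
      if (p == q || net$adjacency[p, q] > 0L) next
      for (s in seq_len(S)) {
        rows[[length(rows) + 1L]] <- c(idx$flat(s, p), idx$flat(s, q))
      }
    }
  }
  if (trophic) {
    if (is.null(web)) stop("trophic zeros need a foodweb_graph")
    if (web$n_species != S) stop("food web size does not match index")
    linked <- matrix(FALSE, S, S)
    if (nrow(web$links)) {
      linked[web$links] <- TRUE
      linked[web$links[, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    for (p in seq_len(P)) {
      for (s in seq_len(S)) for (u in seq_len(S)) {
        if (s == u || linked[s, u]) next
        rows[[length(rows) + 1L]] <- c(idx$flat(s, p), idx$flat(u, p))
      }
    }
  }
  zero_pattern(do.call(rbind, rows), idx$n)
}
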