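#' Pairwise projections, shadows and traces
#'
#' The (A,B)-projection of a tripartite hypergraph is the bipartite
#' *multigraph* on A and B whose multiplicity between `(a_i, b_j)` is the
#' number of vertices `c_k` with `(a_i, b_j, c_k)` a hyperedge; it is stored
#' as an `n1 x n2` count matrix.  The (A,B)-shadow is the bipartite *simple*
#' graph between the pair-vertices `(a_i, b_j)` and the class C, containing
#' `((a_i,b_j), c_k)` exactly when `(a_i, b_j, c_k)` is a hyperedge.  The
#' degree of a pair-vertex in the shadow equals the projection multiplicity.
#'
#' @param H A `tri_hypergraph`.
#' @param pair Which class pair to project on: `"AB"`, `"BC"` or `"AC"`.
#' @return `project()` returns an integer count matrix of class
#'   `projection_matrix` with attribute `pair`; its row sums are the first
#'   class's hypergraph degrees and its column sums the second class's.
#' @export
project <- function(H, pair = c("AB", "BC", "AC")) {
  pair <- match.arg(pair)
  idx <- switch(pair, AB = c(1L, 2L), BC = c(2L, 3L), AC = c(1L, 3L))
  dims <- c(H$n1, H$n2, H$n3)[idx]
  m <- matrix(0L, dims[1L], dims[2L])
  e <- H$edges
  if (nrow(e)) {
    tab <- table(factor(e[, idx[1L]], levels = seq_len(dims[1L])),
                 factor(e[, idx[2L]], levels = seq_len(dims[2L])))
    m[] <- as.integer(tab)
  }
  structure(m, pair = pair, class = c("projection_matrix", class(m)))
}

#' @rdname project
#' @return `shadow()` returns a `shadow_graph`: a list with the pair grid
#'   dimensions `n1`, `n2`, the co-class size `n3`, and `edges`, a 2-column
#'   matrix of (pair-vertex index, C-vertex index) with pair-vertex
#'   `(i, j)` linearized as `i + n1 * (j - 1)`.
#' @export
shadow <- function(H) {
  e <- H$edges
  pair <- e[, 1L] + H$n1 * (e[, 2L] - 1L)
  structure(list(n1 = H$n1, n2 = H$n2, n3 = H$n3,
                 edges = cbind(pair = as.integer(pair), c = e[, 3L])),
            class = "shadow_graph")
}

#' Lift a shadow graph back to a tripartite hypergraph
#'
#' Inverse of [shadow()]: each shadow edge `((a_i, b_j), c_k)` becomes the
#' hyperedge `(a_i, b_j, c_k)`.  `lift_shadow(shadow(H))` reproduces `H` up
#' to edge order.
#'
#' @param G A `shadow_graph`.
#' @return A `tri_hypergraph`.
#' @export
lift_shadow <- function(G) {
  p <- G$edges[, 1L] - 1L
  i <- p %% G$n1 + 1L
  j <- p %/% G$n1 + 1L
  tri_hypergraph(G$n1, G$n2, G$n3, cbind(i, j, G$edges[, 2L]))
}

#' Column balance of a projection matrix
#'
#' A projection column for vertex `b` is *balanced* when all its entries lie
#' in `{l, l - 1}` with `l = ceiling(d(b) / n1)`; the whole projection is
#' B-balanced when every column is.  Equivalently each column takes at most
#' two distinct values differing by one.
#'
#' @param P A count matrix (projection).
#' @return `TRUE` or `FALSE`.
#' @export
is_b_balanced <- function(P) {
  all(apply(P, 2L, function(col) max(col) - min(col) <= 1L))
}

#' Trace of a B-balanced projection
#'
#' In each column of a B-balanced projection, the ceiling value `l` is
#' replaced by 1 and `l - 1` by 0 (an all-equal column maps to all 1s).
#' The result is the adjacency matrix of a bipartite simple graph.
#'
#' @param P A B-balanced count matrix.
#' @return A 0-1 integer matrix of the same shape.
#' @export
trace_of_projection <- function(P) {
  if (!is_b_balanced(P)) stop("projection is not B-balanced; trace undefined")
  out <- matrix(0L, nrow(P), ncol(P))
  for (j in seq_len(ncol(P))) out[, j] <- as.integer(P[, j] == max(P[, j]))
  out
}
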