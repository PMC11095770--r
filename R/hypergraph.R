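#' Tripartite 3-uniform hypergraphs
#'
#' A `tri_hypergraph` is a simple 3-uniform hypergraph on three disjoint
#' vertex classes A, B, C, where every hyperedge contains exactly one vertex
#' from each class.  Vertices are 1-based integer indices within their class;
#' hyperedges are stored as an integer matrix with one row `(i, j, k)` per
#' edge.  Parallel hyperedges are not allowed.
#'
#' @param n1,n2,n3 Sizes of the vertex classes A, B and C.
#' @param edges Integer matrix with 3 columns (or anything coercible to one,
#'   including an empty value for the edgeless hypergraph).  Row `(i, j, k)`
#'   means vertex `i` of A, `j` of B and `k` of C share a hyperedge.
#' @return An object of class `tri_hypergraph` with fields `n1`, `n2`, `n3`
#'   and `edges`.
#' @examples
#' H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(1, 2, 2)))
#' degree_sequence_of(H)
#' @export
tri_hypergraph <- function(n1, n2, n3, edges = NULL) {
  n1 <- as.integer(n1); n2 <- as.integer(n2); n3 <- as.integer(n3)
  stopifnot(length(n1) == 1L, length(n2) == 1L, length(n3) == 1L,
            n1 >= 1L, n2 >= 1L, n3 >= 1L)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 3L)
  } else {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 3L)
  }
  colnames(edges) <- c("a", "b", "c")
  H <- structure(list(n1 = n1, n2 = n2, n3 = n3, edges = edges),
                 class = "tri_hypergraph")
  validate_tri_hypergraph(H)
  H
}

validate_tri_hypergraph <- function(H) {
  e <- H$edges
  if (nrow(e)) {
    if (any(e[, 1L] < 1L | e[, 1L] > H$n1) ||
        any(e[, 2L] < 1L | e[, 2L] > H$n2) ||
        any(e[, 3L] < 1L | e[, 3L] > H$n3))
      stop("hyperedge vertex index out of range")
    if (anyDuplicated(edge_keys(H)))
      stop("parallel hyperedges are not allowed")
  }
  invisible(H)
}

#' @export
print.tri_hypergraph <- function(x, ...) {
  cat(sprintf("tri_hypergraph on classes (%d, %d, %d) with %d hyperedges\n",
              x$n1, x$n2, x$n3, nrow(x$edges)))
  invisible(x)
}

#' @export
format.tri_hypergraph <- function(x, ...) {
  sprintf("tri_hypergraph(%d,%d,%d; m=%d)", x$n1, x$n2, x$n3, nrow(x$edges))
}

# Linear cell key in 1..n1*n2*n3 for an edge matrix; the hypergraph state
# space is the hypercube {0,1}^(n1*n2*n3) indexed by these keys.
edge_keys <- function(H, edges = H$edges) {
  if (!nrow(edges)) return(integer(0))
  (edges[, 1L] - 1L) + H$n1 * ((edges[, 2L] - 1L) + H$n2 * (edges[, 3L] - 1L)) + 1L
}

keys_to_edges <- function(H, keys) {
  keys <- as.integer(keys) - 1L
  i <- keys %% H$n1
  r <- keys %/% H$n1
  j <- r %% H$n2
  k <- r %/% H$n2
  cbind(a = i + 1L, b = j + 1L, c = k + 1L)
}

#' @rdname tri_hypergraph
#' @param H A `tri_hypergraph`.
#' @export
n_edges <- function(H) nrow(H$edges)

# Canonical signature: edge keys sorted; used for de-duplication and
# symmetric differences of realizations.
hypergraph_signature <- function(H) sort(edge_keys(H))

#' Symmetric difference of two hypergraphs on the same classes
#'
#' @param H1,H2 `tri_hypergraph` objects on identical class sizes.
#' @return Integer matrix of the hyperedges present in exactly one of the two.
#' @export
edge_symmetric_difference <- function(H1, H2) {
  stopifnot(H1$n1 == H2$n1, H1$n2 == H2$n2, H1$n3 == H2$n3)
  k1 <- edge_keys(H1); k2 <- edge_keys(H2)
  keys_to_edges(H1, c(setdiff(k1, k2), setdiff(k2, k1)))
}

#' Prescribed tripartite degree sequences
#'
#' Bundles the three per-class lists of prescribed vertex degrees
#' `(D_A, D_B, D_C)`.  A degree sequence is *class balanced* when the three
#' lists have equal sums (a necessary condition for being graphic, since each
#' hyperedge contributes one unit of degree to every class).
#'
#' @param dA,dB,dC Non-negative integer vectors of per-vertex degrees.
#' @return An object of class `tri_degseq`.
#' @examples
#' D <- tri_degseq(c(2, 4, 7), c(2, 4, 7), c(2, 4, 7))
#' is_class_balanced(D)
#' @export
tri_degseq <- function(dA, dB, dC) {
  dA <- as.integer(dA); dB <- as.integer(dB); dC <- as.integer(dC)
  if (any(c(dA, dB, dC) < 0L)) stop("degrees must be non-negative")
  if (!length(dA) || !length(dB) || !length(dC))
    stop("each class needs at least one vertex")
  structure(list(dA = dA, dB = dB, dC = dC), class = "tri_degseq")
}

#' @export
print.tri_degseq <- function(x, ...) {
  cat(sprintf("tri_degseq: |A|=%d (sum %d), |B|=%d (sum %d), |C|=%d (sum %d)\n",
              length(x$dA), sum(x$dA), length(x$dB), sum(x$dB),
              length(x$dC), sum(x$dC)))
  invisible(x)
}

#' @rdname tri_degseq
#' @param D A `tri_degseq`.
#' @export
is_class_balanced <- function(D) {
  sum(D$dA) == sum(D$dB) && sum(D$dB) == sum(D$dC)
}

# Quick per-class capacity check: a degree can never exceed the number of
# co-class vertex pairs available to its vertex.
degseq_within_capacity <- function(D) {
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  all(D$dA <= n2 * n3) && all(D$dB <= n1 * n3) && all(D$dC <= n1 * n2)
}

#' Degree sequence of a hypergraph
#'
#' Counts, for every vertex of every class, the number of incident
#' hyperedges.
#'
#' @param H A `tri_hypergraph`.
#' @return A `tri_degseq` whose three lists each sum to `n_edges(H)`.
#' @export
degree_sequence_of <- function(H) {
  e <- H$edges
  tri_degseq(tabulate(e[, 1L], nbins = H$n1),
             tabulate(e[, 2L], nbins = H$n2),
             tabulate(e[, 3L], nbins = H$n3))
}

#' Energy of a hypergraph relative to a prescribed degree sequence
#'
#' The energy is the L1 deviation between the hypergraph's degree sequence
#' and the prescribed one, summed over all vertices of the three classes.
#' It is zero exactly when `H` realizes `D`.  The Boltzmann distribution at
#' temperature `T` puts mass proportional to `exp(-energy/T)` on every
#' hypergraph over the fixed classes.
#'
#' @param H A `tri_hypergraph`.
#' @param D A `tri_degseq` whose class lengths match `H`'s class sizes.
#' @return Non-negative integer.
#' @examples
#' H <- tri_hypergraph(3, 3, 3)
#' energy(H, tri_degseq(c(2, 4, 7), c(2, 4, 7), c(2, 4, 7)))  # 39
#' @export
energy <- function(H, D) {
  if (length(D$dA) != H$n1 || length(D$dB) != H$n2 || length(D$dC) != H$n3)
    stop("degree sequence dimensions do not match hypergraph classes")
  d <- degree_sequence_of(H)
  sum(abs(d$dA - D$dA)) + sum(abs(d$dB - D$dB)) + sum(abs(d$dC - D$dC))
}

#' Complete and empty hypergraphs
#'
#' @param n1,n2,n3 Class sizes.
#' @return A `tri_hypergraph` with all `n1*n2*n3` (respectively no) edges.
#' @export
complete_hypergraph <- function(n1, n2, n3) {
  tri_hypergraph(n1, n2, n3,
                 as.matrix(expand.grid(a = seq_len(n1), b = seq_len(n2),
                                       c = seq_len(n3))))
}

#' @rdname complete_hypergraph
#' @export
empty_hypergraph <- function(n1, n2, n3) tri_hypergraph(n1, n2, n3)

#' Read and write hyperedge lists
#'
#' The edge-list text format has one `i j k` triple per line using 0-based
#' vertex indices; lines starting with `#` are comments.  Duplicate triples
#' are rejected on read.
#'
#' @param path File path.
#' @param n1,n2,n3 Class sizes (required on read; the file stores only
#'   edges).
#' @return `read_edge_list` returns a `tri_hypergraph`;
#'   `write_edge_list` returns `path`, invisibly.
#' @export
read_edge_list <- function(path, n1, n2, n3) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hypergraph(n1, n2, n3))
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 3L)) stop("malformed edge-list line")
  m <- matrix(as.integer(unlist(parts)), ncol = 3L, byrow = TRUE) + 1L
  tri_hypergraph(n1, n2, n3, m)
}

#' @rdname read_edge_list
#' @param H A `tri_hypergraph` to write.
#' @export
write_edge_list <- function(H, path) {
  e <- H$edges - 1L
  writeLines(sprintf("%d %d %d", e[, 1L], e[, 2L], e[, 3L]), path)
  invisible(path)
}

#' Read and write degree sequences as JSON
#'
#' Format: `{"dA": [...], "dB": [...], "dC": [...]}`.
#'
#' @param path File path.
#' @return `read_degseq_json` returns a `tri_degseq`.
#' @export
read_degseq_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tri_degseq(x$dA, x$dB, x$dC)
}

#' @rdname read_degseq_json
#' @param D A `tri_degseq` to write.
#' @export
write_degseq_json <- function(D, path) {
  jsonlite::write_json(list(dA = D$dA, dB = D$dB, dC = D$dC), path,
                       auto_unbox = FALSE)
  invisible(path)
}
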