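#' Typed infeasibility results
#'
#' Deciders in this package return a typed `hypernull_infeasible` object —
#' rather than throwing — when a degree sequence has no realization.  The
#' object records which condition failed (`"sum_mismatch"`, `"capacity"`,
#' `"bipartite_sum_mismatch"`, `"gale_ryser"`) and free-form detail.
#'
#' @param reason Short machine-readable tag.
#' @param detail Optional human-readable detail.
#' @return An object of class `hypernull_infeasible`.
#' @export
infeasible <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail),
            class = "hypernull_infeasible")
}

#' @rdname infeasible
#' @param x Any object.
#' @export
is_infeasible <- function(x) inherits(x, "hypernull_infeasible")

#' @export
print.hypernull_infeasible <- function(x, ...) {
  cat("infeasible:", x$reason,
      if (!is.null(x$detail)) paste0("(", x$detail, ")"), "\n")
  invisible(x)
}

#' Third almost-regularity
#'
#' A tripartite degree sequence is *third almost-regular* when all degrees
#' of its first class lie in `{k, k - 1}` for some `k`.  For such sequences
#' graphicality is decidable (and a realization constructible) in polynomial
#' time via [realize_third_almost_regular()].
#'
#' @param D A `tri_degseq`, or a plain integer vector taken as the first
#'   class's degrees.
#' @return A list with `ok` (logical) and, when `ok`, the witness `k`
#'   (`k = max(dA)`; for an all-equal class the common value).
#' @export
is_third_almost_regular <- function(D) {
  dA <- if (inherits(D, "tri_degseq")) D$dA else as.integer(D)
  ok <- (max(dA) - min(dA)) <= 1L
  list(ok = ok, k = if (ok) max(dA) else NA_integer_)
}

#' Realize a bipartite multigraph degree sequence
#'
#' North-west-corner filling: a multiplicity matrix with prescribed row sums
#' `dA` and column sums `dB` exists whenever the two sums agree, and the
#' greedy fill constructs one.
#'
#' @param dA,dB Non-negative integer row/column sums.
#' @return An integer matrix with the prescribed margins, or an
#'   [infeasible()] result when `sum(dA) != sum(dB)`.
#' @export
realize_bipartite_multigraph <- function(dA, dB) {
  dA <- as.integer(dA); dB <- as.integer(dB)
  if (sum(dA) != sum(dB))
    return(infeasible("bipartite_sum_mismatch",
                      sprintf("sum(dA)=%d sum(dB)=%d", sum(dA), sum(dB))))
  P <- matrix(0L, length(dA), length(dB))
  r <- dA; cs <- dB
  for (i in seq_along(dA)) {
    for (j in seq_along(dB)) {
      if (!r[i]) break
      x <- min(r[i], cs[j])
      P[i, j] <- x
      r[i] <- r[i] - x
      cs[j] <- cs[j] - x
    }
  }
  P
}

# Prescribed balanced values for one projection column, given the remaining
# (not-yet-fixed) row sums.  Rows with the larger remaining sum take the
# ceiling value first; ties broken by lowest index.
balanced_column_target <- function(d, row_sums) {
  n1 <- length(row_sums)
  q <- d %/% n1                         # floor value; ceiling is q + 1
  n_l <- d %% n1                        # count of ceiling entries
  ord <- order(-row_sums, seq_len(n1))  # sum-k rows first, stable
  presc <- rep.int(q, n1)
  if (n_l > 0L) presc[ord[seq_len(n_l)]] <- q + 1L
  as.integer(presc)
}

#' Balance a projection column by column via degree-preserving exchanges
#'
#' Rewrites a multiplicity matrix with almost-regular row sums into a
#' B-balanced matrix with the same row and column sums.  Columns are
#' processed in ascending index order; inside a column, while an entry
#' exceeds its balanced prescription, one unit is moved to an entry below
#' its prescription, compensated in a witness column so that all margins are
#' preserved (the matrix-level image of a hyperedge switch).  Every exchange
#' reduces the column's L1 deviation from its prescription by 2, so the
#' procedure terminates within half the total initial deviation.
#'
#' @param P Integer multiplicity matrix whose row sums all lie in
#'   `{k, k - 1}`.
#' @return A list with `P` (the balanced matrix) and `exchanges` (number of
#'   unit exchanges performed).
#' @export
balance_projection <- function(P) {
  P <- matrix(as.integer(P), nrow(P), ncol(P))
  rs <- rowSums(P)
  if (max(rs) - min(rs) > 1L)
    stop("row sums are not almost-regular; balancing is not defined")
  n1 <- nrow(P); n2 <- ncol(P)
  remaining_rs <- rowSums(P)
  moves <- 0L
  for (j in seq_len(n2)) {
    presc <- balanced_column_target(sum(P[, j]), remaining_rs)
    repeat {
      over <- which(P[, j] > presc)
      if (!length(over)) break
      under <- which(P[, j] < presc)
      i <- over[1L]; ip <- under[1L]
      cand <- setdiff(seq_len(n2), seq_len(j))  # only not-yet-fixed columns
      wit <- cand[P[ip, cand] > P[i, cand]]
      if (!length(wit))
        stop("internal error: no witness column during balancing")
      j2 <- wit[1L]
      P[i, j]  <- P[i, j]  - 1L; P[ip, j]  <- P[ip, j]  + 1L
      P[ip, j2] <- P[ip, j2] - 1L; P[i, j2] <- P[i, j2] + 1L
      moves <- moves + 1L
    }
    remaining_rs <- remaining_rs - P[, j]
    if (max(remaining_rs) - min(remaining_rs) > 1L)
      stop("internal error: cropped row sums lost almost-regularity")
  }
  list(P = P, exchanges = moves)
}

#' Bipartite Havel-Hakimi realization of a shadow degree sequence
#'
#' Builds a simple bipartite graph between the `n1 * n2` pair-vertices
#' (degrees `d_pairs`, the entries of a balanced projection) and the class C
#' (degrees `dC`), or certifies infeasibility.  Pair-vertices are processed
#' in non-increasing degree order (stable by index); each is joined to the
#' C-vertices of currently largest residual degree, ties broken by lowest
#' index.  This greedy succeeds exactly when the Gale-Ryser conditions hold.
#'
#' @param d_pairs Integer vector of pair-vertex degrees, linearized as
#'   `(i, j) -> i + n1 * (j - 1)`.
#' @param dC Integer vector of C-vertex degrees.
#' @param n1,n2 Pair grid dimensions (`length(d_pairs) == n1 * n2`).
#' @return A `shadow_graph`, or an [infeasible()] result.
#' @export
gale_ryser_realize <- function(d_pairs, dC, n1, n2) {
  d_pairs <- as.integer(d_pairs); dC <- as.integer(dC)
  n3 <- length(dC)
  stopifnot(length(d_pairs) == n1 * n2)
  if (sum(d_pairs) != sum(dC))
    return(infeasible("bipartite_sum_mismatch",
                      sprintf("pairs sum %d vs C sum %d", sum(d_pairs), sum(dC))))
  if (any(d_pairs > n3))
    return(infeasible("capacity", "a pair-degree exceeds |C|"))
  if (any(dC > n1 * n2))
    return(infeasible("capacity", "a C-degree exceeds the number of pairs"))
  res <- dC
  ord <- order(-d_pairs, seq_along(d_pairs))
  edges <- vector("list", length(d_pairs))
  for (p in ord) {
    d <- d_pairs[p]
    if (!d) next
    pick <- order(-res, seq_len(n3))[seq_len(d)]
    if (res[pick[d]] <= 0L)
      return(infeasible("gale_ryser",
                        sprintf("pair-vertex %d cannot place degree %d", p, d)))
    res[pick] <- res[pick] - 1L
    edges[[p]] <- cbind(pair = rep.int(p, d), c = pick)
  }
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = n3,
                 edges = do.call(rbind, c(list(matrix(integer(0), ncol = 2L,
                                       dimnames = list(NULL, c("pair", "c")))),
                                          edges))),
            class = "shadow_graph")
}

#' Decide and construct realizations of third almost-regular sequences
#'
#' Polynomial-time pipeline: realize `(dA, dB)` as a bipartite multigraph,
#' balance it column by column ([balance_projection()]), treat the balanced
#' multiplicities as pair-vertex degrees of a shadow sequence, realize that
#' with [gale_ryser_realize()], and lift the shadow back to a tripartite
#' hypergraph.  The sequence is graphic exactly when every stage succeeds.
#'
#' @param D A class-balanced `tri_degseq` whose first class is third
#'   almost-regular.
#' @return A `tri_hypergraph` realizing `D`, or an [infeasible()] result.
#'   Non-almost-regular first classes are an error (use the sampler for
#'   those; the general decision problem is NP-complete).
#' @examples
#' realize_third_almost_regular(tri_degseq(c(1, 1), c(1, 1), c(2, 0)))
#' @export
realize_third_almost_regular <- function(D) {
  stopifnot(inherits(D, "tri_degseq"))
  if (!is_third_almost_regular(D)$ok)
    stop("first class is not almost-regular; this constructor does not apply")
  if (!is_class_balanced(D))
    return(infeasible("sum_mismatch", "class sums differ"))
  if (!degseq_within_capacity(D))
    return(infeasible("capacity", "a degree exceeds its co-class capacity"))
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  P <- realize_bipartite_multigraph(D$dA, D$dB)
  if (is_infeasible(P)) return(P)
  B <- balance_projection(P)$P
  G <- gale_ryser_realize(as.vector(B), D$dC, n1, n2)
  if (is_infeasible(G)) return(G)
  H <- lift_shadow(G)
  stopifnot(identical(degree_sequence_of(H)$dA, D$dA),
            identical(degree_sequence_of(H)$dB, D$dB),
            identical(degree_sequence_of(H)$dC, D$dC))
  H
}

#' Almost-regular flattening target for a class
#'
#' The almost-regular sequence with the same sum: `k = ceiling(m / n1)`
#' copies structure — `m_k` entries equal to `k` and the rest `k - 1`, where
#' `m_k` solves `m_k * k + (n1 - m_k) * (k - 1) = m`.  Entries are returned
#' non-increasing (the `k`s first).
#'
#' @param n1 Class size.
#' @param m Total degree (number of hyperedges).
#' @return Integer vector of length `n1`.
#' @export
flat_target <- function(n1, m) {
  k <- as.integer(ceiling(m / n1))
  m_k <- as.integer(m - n1 * (k - 1L))
  c(rep.int(k, m_k), rep.int(k - 1L, n1 - m_k))
}

#' Flatten the first class by hinge flips
#'
#' Transforms `H` into a hypergraph whose class-A degrees equal an
#' almost-regular target while classes B and C keep their degrees.  Each
#' hinge flip moves one hyperedge endpoint from an over-target A-vertex to
#' an under-target one, reducing the L1 distance to the target by 2, so at
#' most half the initial distance many flips are used.  By default the
#' target assigns the ceiling degrees to the currently highest-degree
#' vertices (non-increasing convention).
#'
#' @param H A `tri_hypergraph`.
#' @param targetA Optional integer vector of target class-A degrees; must be
#'   almost-regular and sum to `n_edges(H)`.
#' @return A list with `H` (the flattened hypergraph) and `flips` (number of
#'   hinge flips performed).
#' @export
flatten_class_by_hinge_flips <- function(H, targetA = NULL) {
  m <- n_edges(H)
  cur <- degree_sequence_of(H)$dA
  if (is.null(targetA)) {
    flat <- flat_target(H$n1, m)
    targetA <- integer(H$n1)
    targetA[order(-cur, seq_len(H$n1))] <- flat
  }
  targetA <- as.integer(targetA)
  if (sum(targetA) != m) stop("target sum differs from the edge count")
  if (max(targetA) - min(targetA) > 1L) stop("target is not almost-regular")
  flips <- 0L
  while (any(cur != targetA)) {
    i <- which(cur > targetA)
    i <- i[length(i)]                 # largest over-target index
    jj <- which(cur < targetA)[1L]    # smallest under-target index
    e <- H$edges
    in_i <- e[e[, 1L] == i, , drop = FALSE]
    keys_j <- (e[e[, 1L] == jj, 2L] - 1L) + H$n2 * (e[e[, 1L] == jj, 3L] - 1L)
    keys_i <- (in_i[, 2L] - 1L) + H$n2 * (in_i[, 3L] - 1L)
    pick <- which(!(keys_i %in% keys_j))[1L]
    if (is.na(pick)) stop("internal error: no hinge-flip witness pair")
    op <- make_hinge_flip(in_i[pick, ], 1L, jj)
    H <- apply_op(H, op)
    cur[i] <- cur[i] - 1L; cur[jj] <- cur[jj] + 1L
    flips <- flips + 1L
  }
  list(H = H, flips = flips)
}
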