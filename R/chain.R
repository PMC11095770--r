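#' Propose a random edit operation (one step of the proposal kernel)
#'
#' Draws one proposal of the mixture kernel: with the given weights a
#' switch, a hinge flip, or a toggle.  Switch: two edges drawn independently
#' and uniformly (with replacement) from the current edge set plus a uniform
#' class; hinge flip: a uniform edge, a uniform class, and a uniform
#' replacement vertex among the class members not in the edge; toggle: a
#' uniform cell of the `n1 x n2 x n3` grid, removed if present and inserted
#' otherwise.  Proposals that would duplicate an existing hyperedge, draw
#' the same edge twice, or find no material to act on (no edges, class of
#' size one) are *invalid* and correspond to lazy self-loops of the chain.
#'
#' @param H A `tri_hypergraph`.
#' @param weights Probabilities of (switch, hinge flip, toggle); default
#'   uniform thirds.
#' @return A list with `kind`, `valid` (logical) and `op` (an `edit_op`, or
#'   `NULL` for proposals that never materialize an operation).
#' @export
propose_op <- function(H, weights = c(1, 1, 1) / 3) {
  kind_id <- sample.int(3L, 1L, prob = weights)
  m <- n_edges(H)
  N <- H$n1 * H$n2 * H$n3
  if (kind_id == 1L) {                       # switch
    if (m == 0L) return(list(kind = "switch", valid = FALSE, op = NULL))
    i1 <- sample.int(m, 1L); i2 <- sample.int(m, 1L)
    cls <- sample.int(3L, 1L)
    if (i1 == i2) return(list(kind = "switch", valid = FALSE, op = NULL))
    op <- make_switch(H$edges[i1, ], H$edges[i2, ], cls)
    list(kind = "switch", valid = op_is_valid(H, op), op = op)
  } else if (kind_id == 2L) {                # hinge flip
    if (m == 0L) return(list(kind = "hinge_flip", valid = FALSE, op = NULL))
    e <- H$edges[sample.int(m, 1L), ]
    cls <- sample.int(3L, 1L)
    size <- c(H$n1, H$n2, H$n3)[cls]
    if (size == 1L) return(list(kind = "hinge_flip", valid = FALSE, op = NULL))
    others <- setdiff(seq_len(size), e[cls])
    x <- others[sample.int(length(others), 1L)]
    op <- make_hinge_flip(e, cls, x)
    list(kind = "hinge_flip", valid = op_is_valid(H, op), op = op)
  } else {                                   # toggle
    key <- sample.int(N, 1L)
    cell <- keys_to_edges(H, key)
    if (key %in% edge_keys(H)) {
      list(kind = "toggle", valid = TRUE,
           op = edit_op("toggle_out", cell, NULL))
    } else {
      list(kind = "toggle", valid = TRUE,
           op = edit_op("toggle_in", NULL, cell))
    }
  }
}

#' One Metropolis step of the single-temperature chain
#'
#' Proposes with [propose_op()] and accepts with probability
#' `min(1, exp((energy(H) - energy(H')) / T))`; invalid proposals leave the
#' state unchanged (lazy self-loop).  Energy-preserving proposals — every
#' valid switch in particular — are always accepted.
#'
#' @param H Current `tri_hypergraph` state.
#' @param D Prescribed `tri_degseq`.
#' @param temperature Positive temperature `T`.
#' @param weights Proposal mixture weights.
#' @return A list with the next state `H`, the proposal `kind`, and flags
#'   `valid` and `accepted`.
#' @export
metropolis_step <- function(H, D, temperature, weights = c(1, 1, 1) / 3) {
  stopifnot(temperature > 0)
  p <- propose_op(H, weights)
  if (!p$valid)
    return(list(H = H, kind = p$kind, valid = FALSE, accepted = FALSE))
  H2 <- apply_op(H, p$op)
  dE <- energy(H2, D) - energy(H, D)
  accept <- dE <= 0 || log(stats::runif(1L)) <= -dE / temperature
  list(H = if (accept) H2 else H, kind = p$kind, valid = TRUE,
       accepted = accept)
}

#' Run the single-temperature Metropolis chain
#'
#' Compiled inner loop over the mixture kernel of [propose_op()] with
#' Metropolis acceptance at temperature `T`.  The chain converges to the
#' Boltzmann distribution over all hypergraphs on the fixed classes, with
#' mass proportional to `exp(-energy/T)`.
#'
#' @param H0 Starting `tri_hypergraph`.
#' @param D Prescribed `tri_degseq`.
#' @param temperature Positive temperature.
#' @param n_steps Number of proposals (invalid proposals advance the clock).
#' @param weights Proposal mixture weights (switch, hinge flip, toggle).
#' @param energy_every If positive, record the energy every this many steps.
#' @param check_every If positive, cross-check the incrementally maintained
#'   energy against a full recomputation every this many steps (debugging).
#' @param track_states Count visits per state (instances of at most 20
#'   cells); used for comparing the empirical state distribution with the
#'   exact Boltzmann distribution.
#' @return A list with the final state `H`, its `energy`, the per-kind
#'   bookkeeping matrix `stats` (proposed = invalid + accepted + rejected),
#'   `energy_trace`, and (when tracked) `state_visits` indexed by occupancy
#'   bitmask + 1.
#' @export
run_chain <- function(H0, D, temperature, n_steps,
                      weights = c(1, 1, 1) / 3,
                      energy_every = 0, check_every = 0,
                      track_states = FALSE) {
  stopifnot(inherits(H0, "tri_hypergraph"), inherits(D, "tri_degseq"),
            temperature > 0, n_steps >= 0)
  if (length(D$dA) != H0$n1 || length(D$dB) != H0$n2 || length(D$dC) != H0$n3)
    stop("degree sequence dimensions do not match the state's classes")
  weights <- weights / sum(weights)
  res <- cpp_run_chain(H0$n1, H0$n2, H0$n3, H0$edges - 1L,
                       D$dA, D$dB, D$dC, temperature, n_steps, weights,
                       as.integer(energy_every), as.integer(check_every),
                       track_states)
  list(H = tri_hypergraph(H0$n1, H0$n2, H0$n3, res$edges + 1L),
       energy = res$energy, stats = res$stats,
       energy_trace = res$energy_trace,
       state_visits = if (track_states) res$state_visits)
}

#' Exact proposal distribution of the mixture kernel (tiny states)
#'
#' Enumerates every random choice of the proposal kernel and accumulates
#' the exact probability of proposing each neighbouring hypergraph, plus
#' the total self-loop probability from invalid proposals.  Intended for
#' state spaces small enough to enumerate; used to verify the symmetry of
#' the kernel (the probability of proposing `H'` from `H` equals that of
#' proposing `H` from `H'`).
#'
#' @param H A `tri_hypergraph`.
#' @param weights Proposal mixture weights.
#' @return A named numeric vector: names are `"|"`-prefixed comma-separated
#'   sorted cell keys of the neighbour states, plus the entry `".self"`.
#' @export
proposal_distribution <- function(H, weights = c(1, 1, 1) / 3) {
  weights <- weights / sum(weights)
  probs <- new.env(parent = emptyenv())
  bump <- function(sig, p) {
    cur <- if (is.null(probs[[sig]])) 0 else probs[[sig]]
    assign(sig, cur + p, envir = probs)
  }
  sig_of <- function(H2) state_sig(edge_keys(H2))
  m <- n_edges(H)
  N <- H$n1 * H$n2 * H$n3
  # switch branch
  if (m == 0L) bump(".self", weights[1]) else {
    for (i1 in seq_len(m)) for (i2 in seq_len(m)) for (cls in 1:3) {
      p <- weights[1] / (m * m * 3)
      if (i1 == i2) { bump(".self", p); next }
      op <- make_switch(H$edges[i1, ], H$edges[i2, ], cls)
      if (op_is_valid(H, op)) bump(sig_of(apply_op(H, op)), p)
      else bump(".self", p)
    }
  }
  # hinge-flip branch
  if (m == 0L) bump(".self", weights[2]) else {
    sizes <- c(H$n1, H$n2, H$n3)
    for (i in seq_len(m)) for (cls in 1:3) {
      p_cls <- weights[2] / (m * 3)
      if (sizes[cls] == 1L) { bump(".self", p_cls); next }
      others <- setdiff(seq_len(sizes[cls]), H$edges[i, cls])
      for (x in others) {
        p <- p_cls / length(others)
        op <- make_hinge_flip(H$edges[i, ], cls, x)
        if (op_is_valid(H, op)) bump(sig_of(apply_op(H, op)), p)
        else bump(".self", p)
      }
    }
  }
  # toggle branch
  keys <- edge_keys(H)
  for (key in seq_len(N)) {
    p <- weights[3] / N
    cell <- keys_to_edges(H, key)
    op <- if (key %in% keys) edit_op("toggle_out", cell, NULL)
          else edit_op("toggle_in", NULL, cell)
    bump(sig_of(apply_op(H, op)), p)
  }
  unlist(as.list(probs, all.names = TRUE))
}

# canonical state label: "|" followed by the sorted cell keys
state_sig <- function(keys) paste0("|", paste(sort(keys), collapse = ","))

#' Exact Boltzmann distribution by full state enumeration (tiny classes)
#'
#' Enumerates all `2^(n1*n2*n3)` hypergraphs on the given classes and
#' returns their exact Boltzmann probabilities at temperature `T` for the
#' prescribed degree sequence.  Only feasible for a handful of cells.
#'
#' @param n1,n2,n3 Class sizes.
#' @param D Prescribed `tri_degseq`.
#' @param temperature Positive temperature.
#' @return A data frame with one row per state: `sig` (as in
#'   [proposal_distribution()]), `energy` and `prob`.
#' @export
boltzmann_enumeration <- function(n1, n2, n3, D, temperature) {
  N <- n1 * n2 * n3
  if (N > 20) stop("state space too large to enumerate")
  n_states <- 2^N
  sig <- character(n_states); en <- numeric(n_states)
  for (s in seq_len(n_states) - 1L) {
    keys <- which(bitwAnd(bitwShiftR(s, seq_len(N) - 1L), 1L) == 1L)
    H <- tri_hypergraph(n1, n2, n3, keys_to_edges(list(n1 = n1, n2 = n2), keys))
    sig[s + 1L] <- state_sig(keys)
    en[s + 1L] <- energy(H, D)
  }
  wgt <- exp(-en / temperature)
  data.frame(sig = sig, energy = en, prob = wgt / sum(wgt),
             stringsAsFactors = FALSE)
}
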