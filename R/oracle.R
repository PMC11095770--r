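#' Exhaustively enumerate tripartite realizations of a degree sequence
#'
#' Ground-truth brute force for desk-scale instances: backtracks over the
#' incidence slice of each A-vertex (which (b, c) cells it occupies), with
#' running B/C capacity pruning.  A-vertices are processed in non-increasing
#' degree order; results are reported with the original labels.
#'
#' @param D A `tri_degseq`.
#' @param count_only If `TRUE`, return only the number of realizations.
#' @param guard Refuse instances with `n1 * n2 * n3` above this bound
#'   (oracles must either finish or refuse; they never truncate silently).
#' @return A list of `tri_hypergraph` realizations (possibly empty), or an
#'   integer count.  The list is duplicate-free by construction.
#' @examples
#' length(enumerate_partite_realizations(
#'   tri_degseq(c(2, 4, 7), c(2, 4, 7), c(2, 4, 7))))  # 2
#' @export
enumerate_partite_realizations <- function(D, count_only = FALSE, guard = 60) {
  stopifnot(inherits(D, "tri_degseq"))
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  if (n1 * n2 * n3 > guard)
    stop("instance exceeds the enumeration guard (", guard, " cells)")
  if (!is_class_balanced(D) || !degseq_within_capacity(D)) {
    return(if (count_only) 0L else list())
  }
  ord <- order(-D$dA, seq_len(n1))
  degs <- D$dA[ord]
  cells <- as.matrix(expand.grid(j = seq_len(n2), k = seq_len(n3)))
  n_cells <- nrow(cells)
  remB <- D$dB; remC <- D$dC
  count <- 0L
  found <- list()
  slices <- vector("list", n1)   # chosen cell indices per (reordered) agent

  emit <- function() {
    if (count_only) { count <<- count + 1L; return() }
    rows <- lapply(seq_len(n1), function(ii) {
      s <- slices[[ii]]
      if (!length(s)) return(NULL)
      cbind(ord[ii], cells[s, 1L], cells[s, 2L])
    })
    found[[length(found) + 1L]] <<-
      tri_hypergraph(n1, n2, n3, do.call(rbind, rows))
  }

  # choose remaining `need` cells for agent ai starting from cell index `from`
  choose_cells <- function(ai, from, need, picked) {
    if (need == 0L) { agent_done(ai + 1L); return() }
    if (n_cells - from + 1L < need) return()
    for (s in from:n_cells) {
      j <- cells[s, 1L]; k <- cells[s, 2L]
      if (remB[j] > 0L && remC[k] > 0L) {
        remB[j] <<- remB[j] - 1L; remC[k] <<- remC[k] - 1L
        slices[[ai]][picked + 1L] <<- s
        choose_cells(ai, s + 1L, need - 1L, picked + 1L)
        remB[j] <<- remB[j] + 1L; remC[k] <<- remC[k] + 1L
      }
      if (n_cells - s < need) break
    }
  }

  agent_done <- function(ai) {
    if (ai > n1) {
      if (all(remB == 0L) && all(remC == 0L)) emit()
      return()
    }
    left <- n1 - ai + 1L
    if (any(remB > left * n3) || any(remC > left * n2)) return()
    slices[[ai]] <- integer(degs[ai])
    choose_cells(ai, 1L, degs[ai], 0L)
  }

  agent_done(1L)
  if (count_only) count else found
}

#' Count simple 3-uniform hypergraph realizations (non-partite)
#'
#' Exact count of loop-free, simple 3-uniform hypergraphs on `n` labelled
#' vertices with the prescribed degrees, by pruned backtracking over the
#' `choose(n, 3)` candidate triples (compiled).  Returns 0 when the degree
#' sum is not divisible by 3.
#'
#' @param degrees Integer vector of prescribed vertex degrees.
#' @param guard Refuse instances with more than `guard` vertices.
#' @return The exact count (numeric; counts can exceed integer range).
#' @examples
#' count_nonpartite_3uniform_realizations(c(1, 1, 1))  # 1
#' @export
count_nonpartite_3uniform_realizations <- function(degrees, guard = 9) {
  degrees <- as.integer(degrees)
  if (any(degrees < 0L)) stop("degrees must be non-negative")
  if (length(degrees) > guard)
    stop("instance exceeds the enumeration guard (", guard, " vertices)")
  cpp_count_3uniform(degrees)
}

#' Numerical 3-dimensional matching instances
#'
#' An instance partitions `[n] = [3k]` into classes A, B, C of size `k`,
#' attaches an integer weight to every element, and asks for a set of `k`
#' disjoint triples — one element per class each — whose weights each sum to
#' the bound `b`.
#'
#' @param wA,wB,wC Integer weight vectors of equal length `k` for the three
#'   classes.  Internally elements are indexed `A = 1..k`, `B = k+1..2k`,
#'   `C = 2k+1..3k`.
#' @param b Non-negative integer bound.
#' @return An object of class `ndm_instance`.
#' @export
ndm_instance <- function(wA, wB, wC, b) {
  k <- length(wA)
  stopifnot(length(wB) == k, length(wC) == k, k >= 1, b >= 0)
  structure(list(k = as.integer(k),
                 weights = as.integer(c(wA, wB, wC)),
                 classes = list(A = seq_len(k), B = k + seq_len(k),
                                C = 2L * k + seq_len(k)),
                 b = as.integer(b)),
            class = "ndm_instance")
}

#' @rdname ndm_instance
#' @param path JSON file with fields `classes` (three index lists),
#'   `weights` and `b`.
#' @export
read_ndm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE)
  cls <- lapply(x$classes, as.integer)
  k <- length(cls[[1]])
  w <- as.integer(x$weights)
  ndm_instance(w[cls[[1]]], w[cls[[2]]], w[cls[[3]]], x$b)
}

#' @rdname ndm_instance
#' @param inst An `ndm_instance` to write.
#' @export
write_ndm_json <- function(inst, path) {
  jsonlite::write_json(list(classes = unname(inst$classes),
                            weights = inst$weights, b = inst$b),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Degree sequence of the matching-to-realization reduction
#'
#' Maps a numerical 3-dimensional matching instance to a tripartite degree
#' sequence that is graphic exactly when the instance is solvable.  With
#' `w = 3a - b`, the prescribed degree vector is `1 + sum` of the indicator
#' vectors of all class-transversal triples whose `w`-weight is positive.
#' The necessary balance condition `3 * sum(a) = n * b` is checked first;
#' when it fails the instance is certified unsolvable and no sequence is
#' emitted.
#'
#' @param inst An `ndm_instance`.
#' @return A list with `w` (integer vector), `d` (degree vector over `[n]`)
#'   and `D` (the `tri_degseq` view), or an [infeasible()] result with
#'   reason `"weight_balance"`.
#' @examples
#' reduction_degree_sequence(ndm_instance(1:3, 1:3, 1:3, 6))$D
#' @export
reduction_degree_sequence <- function(inst) {
  stopifnot(inherits(inst, "ndm_instance"))
  k <- inst$k; n <- 3L * k
  a <- inst$weights; b <- inst$b
  if (3L * sum(a) != n * b)
    return(infeasible("weight_balance",
                      "3 * sum(weights) != n * b; instance has no solution"))
  w <- 3L * a - b
  d <- rep.int(1L, n)
  for (i in inst$classes$A)
    for (j in inst$classes$B)
      for (l in inst$classes$C)
        if (w[i] + w[j] + w[l] > 0L) {
          d[i] <- d[i] + 1L; d[j] <- d[j] + 1L; d[l] <- d[l] + 1L
        }
  list(w = w, d = d,
       D = tri_degseq(d[inst$classes$A], d[inst$classes$B], d[inst$classes$C]))
}

#' Brute-force solver for numerical 3-dimensional matching
#'
#' Searches over all pairings (permutations of B and C against A) and keeps
#' those whose triples all have weight sum `b`.
#'
#' @param inst An `ndm_instance`.
#' @param all_solutions If `TRUE` return every solution, else stop at one.
#' @param guard Refuse instances with `k` above this bound.
#' @return A list of solutions (each a `k x 3` matrix of element indices,
#'   rows are triples); empty when unsolvable.  With
#'   `all_solutions = FALSE` the list has at most one element.
#' @export
solve_3dm_brute_force <- function(inst, all_solutions = TRUE, guard = 5) {
  stopifnot(inherits(inst, "ndm_instance"))
  k <- inst$k
  if (k > guard) stop("instance exceeds the solver guard (k > ", guard, ")")
  a <- inst$weights; b <- inst$b
  A <- inst$classes$A; B <- inst$classes$B; C <- inst$classes$C
  perms <- all_permutations(k)
  sols <- list()
  for (p in seq_len(nrow(perms))) {
    sB <- B[perms[p, ]]
    need <- b - a[A] - a[sB]
    for (q in seq_len(nrow(perms))) {
      sC <- C[perms[q, ]]
      if (all(a[sC] == need)) {
        sols[[length(sols) + 1L]] <- cbind(A = A, B = sB, C = sC)
        if (!all_solutions) return(sols)
      }
    }
  }
  sols
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

#' Enumerate the fiber of contingency tables with fixed margins
#'
#' All non-negative integer matrices with the given row and column sums,
#' by row-wise recursive composition.  Desk scale only.
#'
#' @param row_sums,col_sums Non-negative integer margins with equal totals.
#' @param guard Refuse fibers with total count above this bound.
#' @return A list of integer matrices.
#' @export
enumerate_margin_tables <- function(row_sums, col_sums, guard = 1e6) {
  row_sums <- as.integer(row_sums); col_sums <- as.integer(col_sums)
  if (sum(row_sums) != sum(col_sums)) stop("margin totals differ")
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  tab <- matrix(0L, nr, nc)
  rec_row <- function(r, rem_cols) {
    if (r > nr) {
      out[[length(out) + 1L]] <<- tab
      if (length(out) > guard) stop("fiber enumeration guard exceeded")
      return()
    }
    rec_cell <- function(j, left) {
      if (j == nc) {
        if (left <= rem_cols[nc]) {
          tab[r, nc] <<- left
          rem2 <- rem_cols - tab[r, ]
          # remaining rows must be able to absorb what is left per column
          if (all(rem2 <= sum(row_sums[-seq_len(r)]))) rec_row(r + 1L, rem2)
        }
        return()
      }
      for (v in 0:min(left, rem_cols[j])) {
        tab[r, j] <<- v
        rec_cell(j + 1L, left - v)
      }
      tab[r, j] <<- 0L
    }
    rec_cell(1L, row_sums[r])
  }
  rec_row(1L, col_sums)
  out
}
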