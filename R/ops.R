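#' Edit operations on tripartite hypergraphs
#'
#' Three elementary moves drive every sampler in this package:
#'
#' * **switch** — remove hyperedges `e1 = (a1,b1,c1)` and `e2 = (a2,b2,c2)`
#'   and add the two edges obtained by exchanging their vertices in one
#'   chosen class (for class A: `(a2,b1,c1)` and `(a1,b2,c2)`).  A switch
#'   preserves every vertex degree.
#' * **hinge flip** — replace one vertex of one hyperedge by another vertex
#'   of the same class; exactly two degrees change, by -1 and +1.
#' * **toggle in / toggle out** — insert or delete a single hyperedge; one
#'   degree per class changes by +/-1.
#'
#' An operation is only *valid* against a hypergraph when all removed edges
#' are present and no added edge is already present (simplicity is never
#' violated).  `apply_op()` refuses invalid operations with an error whose
#' condition class is `"hypernull_invalid_op"`, which proposal layers treat
#' as a rejection, not a crash.
#'
#' @param remove,add Integer edge matrices (possibly 0 rows) of removed and
#'   added triples.
#' @param kind One of `"switch"`, `"hinge_flip"`, `"toggle_in"`,
#'   `"toggle_out"`.
#' @param class For switch/hinge flip, which class (1 = A, 2 = B, 3 = C) the
#'   exchanged vertex belongs to.
#' @return An object of class `edit_op`.
#' @export
edit_op <- function(kind, remove, add, class = NA_integer_) {
  kind <- match.arg(kind, c("switch", "hinge_flip", "toggle_in", "toggle_out"))
  as_em <- function(x) {
    if (is.null(x) || length(x) == 0L) matrix(integer(0), ncol = 3L)
    else matrix(as.integer(x), ncol = 3L)
  }
  remove <- as_em(remove); add <- as_em(add)
  counts <- switch(kind,
    switch     = c(2L, 2L),
    hinge_flip = c(1L, 1L),
    toggle_in  = c(0L, 1L),
    toggle_out = c(1L, 0L))
  if (nrow(remove) != counts[1L] || nrow(add) != counts[2L])
    stop("wrong number of removed/added edges for kind ", kind)
  structure(list(kind = kind, remove = remove, add = add,
                 class = as.integer(class)),
            class = "edit_op")
}

#' @export
print.edit_op <- function(x, ...) {
  fmt <- function(m) if (nrow(m)) paste(apply(m, 1L, paste, collapse = ","),
                                        collapse = " | ") else "-"
  cat(sprintf("edit_op %s: remove [%s] add [%s]\n", x$kind,
              fmt(x$remove), fmt(x$add)))
  invisible(x)
}

invalid_op <- function(msg) {
  structure(class = c("hypernull_invalid_op", "error", "condition"),
            list(message = msg, call = sys.call(-1L)))
}

#' Check whether an edit operation is valid against a hypergraph
#'
#' @param H A `tri_hypergraph`.
#' @param op An `edit_op`.
#' @return `TRUE` or `FALSE`.
#' @export
op_is_valid <- function(H, op) {
  keys <- edge_keys(H)
  rem <- edge_keys(H, op$remove)
  add <- edge_keys(H, op$add)
  all(rem %in% keys) && !any(add %in% keys) &&
    !anyDuplicated(rem) && !anyDuplicated(add) && !any(add %in% rem)
}

#' Apply an edit operation
#'
#' @inheritParams op_is_valid
#' @return The edited `tri_hypergraph`.
#' @export
apply_op <- function(H, op) {
  if (!op_is_valid(H, op))
    stop(invalid_op(paste0("invalid ", op$kind, " against current hypergraph")))
  keys <- edge_keys(H)
  keep <- !(keys %in% edge_keys(H, op$remove))
  edges <- rbind(H$edges[keep, , drop = FALSE], op$add)
  tri_hypergraph(H$n1, H$n2, H$n3, edges)
}

# Build the switch op of Def-1 type from two present edges and a class;
# returns an edit_op (validity checked separately at application time).
make_switch <- function(e1, e2, class) {
  new1 <- e1; new2 <- e2
  new1[class] <- e2[class]
  new2[class] <- e1[class]
  edit_op("switch", rbind(e1, e2), rbind(new1, new2), class = class)
}

make_hinge_flip <- function(e, class, x) {
  new <- e
  new[class] <- x
  edit_op("hinge_flip", rbind(e), rbind(new), class = class)
}
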