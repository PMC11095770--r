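#' Random hypergraph with independent edges
#'
#' Each of the `n1 * n2 * n3` potential hyperedges is included
#' independently with probability `p`.  At `p = 0.5` this is the uniform
#' distribution over all hypergraphs on the fixed classes — the
#' infinite-temperature Boltzmann distribution.
#'
#' @param n1,n2,n3 Class sizes.
#' @param p Inclusion probability in `[0, 1]`.
#' @return A `tri_hypergraph`.
#' @export
random_er_hypergraph <- function(n1, n2, n3, p) {
  stopifnot(p >= 0, p <= 1)
  N <- n1 * n2 * n3
  keys <- which(stats::runif(N) < p)
  H <- empty_hypergraph(n1, n2, n3)
  tri_hypergraph(n1, n2, n3, keys_to_edges(H, keys))
}

#' Regular tripartite degree sequences
#'
#' The degree sequence with `total_edges` hyperedges in which every vertex
#' of a class has the same degree; requires each class size to divide the
#' edge count.
#'
#' @param n1,n2,n3 Class sizes.
#' @param total_edges Number of hyperedges.
#' @return A `tri_degseq`.
#' @export
regular_degree_sequence <- function(n1, n2, n3, total_edges) {
  if (total_edges %% n1 || total_edges %% n2 || total_edges %% n3)
    stop("class sizes must divide the edge count for a regular sequence")
  tri_degseq(rep.int(total_edges %/% n1, n1),
             rep.int(total_edges %/% n2, n2),
             rep.int(total_edges %/% n3, n3))
}

#' Random degree sequence of a fixed number of edges
#'
#' Degree sequence of a uniformly random simple hypergraph with exactly
#' `m` edges on the given classes — graphic by construction.
#'
#' @param n1,n2,n3 Class sizes.
#' @param m Number of hyperedges (`<= n1 * n2 * n3`).
#' @return A `tri_degseq`.
#' @export
random_graphic_degseq <- function(n1, n2, n3, m) {
  N <- n1 * n2 * n3
  stopifnot(m <= N)
  H <- empty_hypergraph(n1, n2, n3)
  keys <- sample.int(N, m)
  degree_sequence_of(tri_hypergraph(n1, n2, n3, keys_to_edges(H, keys)))
}

#' Synthetic triplet tables with planted aggregation
#'
#' Emulates agents placing (event, time) records: agent `i` contributes
#' `activity[i]` records; each record's event type is uniform, and its time
#' point is the event's preferred time with probability
#' `theta / (1 + theta)` and uniform otherwise.  `theta = 0` gives
#' independent placement (no aggregation); larger `theta` concentrates
#' events on their preferred times.  Preferred times are assigned
#' cyclically to event types.  Duplicate records are possible and are kept
#' — collapsing them is the job of [to_hypergraph()], mirroring how
#' repeated observations collapse into a single hyperedge.
#'
#' @param n_agents,n_events,n_times Numbers of distinct labels per class.
#' @param activity Integer vector of records per agent (recycled to
#'   `n_agents`).
#' @param theta Non-negative aggregation strength.
#' @return A data frame of class `triplet_table` with character columns
#'   `agent`, `event`, `time`, one record per row.
#' @export
planted_aggregation_table <- function(n_agents, n_events, n_times,
                                      activity = 1L, theta = 0) {
  stopifnot(theta >= 0)
  activity <- rep_len(as.integer(activity), n_agents)
  pref <- ((seq_len(n_events) - 1L) %% n_times) + 1L
  agent <- rep.int(seq_len(n_agents), activity)
  n <- length(agent)
  event <- sample.int(n_events, n, replace = TRUE)
  time <- ifelse(stats::runif(n) < theta / (1 + theta),
                 pref[event],
                 sample.int(n_times, n, replace = TRUE))
  tbl <- data.frame(agent = sprintf("a%03d", agent),
                    event = sprintf("e%03d", event),
                    time = sprintf("t%03d", time),
                    stringsAsFactors = FALSE)
  class(tbl) <- c("triplet_table", class(tbl))
  attr(tbl, "params") <- list(n_agents = n_agents, n_events = n_events,
                              n_times = n_times, activity = activity,
                              theta = theta)
  tbl
}

#' Read and write triplet tables
#'
#' Tab-separated text with at least three columns (agent, event type, time
#' point); any further columns are ignored.  Values are opaque labels — any
#' time binning happens upstream.
#'
#' @param path File path.
#' @param header Whether the file has a header row.
#' @return `read_triplets` returns a `triplet_table` data frame with
#'   columns `agent`, `event`, `time`.
#' @export
read_triplets <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(df) < 3L) stop("triplet table needs at least 3 columns")
  if (nrow(df) == 0L) stop("empty triplet table")
  df <- df[, 1:3]
  names(df) <- c("agent", "event", "time")
  class(df) <- c("triplet_table", class(df))
  df
}

#' @rdname read_triplets
#' @param tbl A `triplet_table` (or any 3-column data frame) to write.
#' @export
write_triplets <- function(tbl, path) {
  utils::write.table(tbl[, c("agent", "event", "time")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a hypergraph from a triplet table
#'
#' Distinct labels of each column become the vertices of the three classes
#' (sorted order); each distinct record becomes one hyperedge.  Identical
#' records collapse into a single hyperedge.
#'
#' @param tbl A `triplet_table` or 3-column data frame (agent, event, time).
#' @return A list with `H` (the `tri_hypergraph`), the three label-to-index
#'   `maps` (named integer vectors), `n_raw` and `n_unique` record counts.
#' @export
to_hypergraph <- function(tbl) {
  agent <- as.character(tbl[[1L]]); event <- as.character(tbl[[2L]])
  time <- as.character(tbl[[3L]])
  la <- sort(unique(agent)); le <- sort(unique(event)); lt <- sort(unique(time))
  ia <- match(agent, la); ie <- match(event, le); it <- match(time, lt)
  rec <- cbind(ia, ie, it)
  uniq <- rec[!duplicated(rec), , drop = FALSE]
  list(H = tri_hypergraph(length(la), length(le), length(lt), uniq),
       maps = list(agent = stats::setNames(seq_along(la), la),
                   event = stats::setNames(seq_along(le), le),
                   time = stats::setNames(seq_along(lt), lt)),
       n_raw = nrow(tbl), n_unique = nrow(uniq))
}
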