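# shared test utilities

sig_of <- function(H) paste(sort(hypernull:::edge_keys(H)), collapse = ",")

# total-variation distance between an empirical state-visit vector (indexed
# by occupancy bitmask + 1, as returned by track_states) and the exact
# Boltzmann enumeration of the same classes
tv_to_boltzmann <- function(visits, n1, n2, n3, D, temperature) {
  ex <- boltzmann_enumeration(n1, n2, n3, D, temperature)
  N <- n1 * n2 * n3
  sigs <- vapply(seq_along(visits) - 1L, function(m) {
    keys <- which(bitwAnd(bitwShiftR(m, seq_len(N) - 1L), 1L) == 1L)
    paste0("|", paste(keys, collapse = ","))
  }, character(1))
  emp <- visits / sum(visits)
  0.5 * sum(abs(emp[match(ex$sig, sigs)] - ex$prob))
}

# random class-balanced third almost-regular degree sequence on small classes
random_tar_degseq <- function(max_n = 4, max_edges = 10) {
  repeat {
    n1 <- sample(2:max_n, 1); n2 <- sample(2:max_n, 1); n3 <- sample(2:max_n, 1)
    m <- sample(0:max_edges, 1)
    dA <- flat_target(n1, m)[sample.int(n1)]
    dB <- random_composition(m, n2)
    dC <- random_composition(m, n3)
    D <- try(tri_degseq(dA, dB, dC), silent = TRUE)
    if (!inherits(D, "try-error")) return(D)
  }
}

# random composition of m into k non-negative parts (uniform multinomial)
random_composition <- function(m, k) {
  if (m == 0) return(integer(k))
  tabulate(sample.int(k, m, replace = TRUE), nbins = k)
}

# all states reachable from H by one valid switch (for connectivity checks)
switch_neighbors <- function(H) {
  m <- n_edges(H)
  out <- character(0)
  if (m < 2) return(out)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) for (cls in 1:3) {
    op <- hypernull:::make_switch(H$edges[i, ], H$edges[j, ], cls)
    if (op_is_valid(H, op)) out <- c(out, sig_of(apply_op(H, op)))
  }
  unique(out)
}

hypergraph_from_sig <- function(sig, n1, n2, n3) {
  keys <- as.integer(strsplit(sig, ",")[[1]])
  H0 <- empty_hypergraph(n1, n2, n3)
  tri_hypergraph(n1, n2, n3, hypernull:::keys_to_edges(H0, keys))
}
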