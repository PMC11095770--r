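test_that("degree sequences count incidences per class", {
  expect_equal(degree_sequence_of(empty_hypergraph(3, 3, 3)),
               tri_degseq(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0)))
  expect_equal(degree_sequence_of(complete_hypergraph(2, 2, 2)),
               tri_degseq(c(4, 4), c(4, 4), c(4, 4)))
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(1, 2, 2)))
  expect_equal(degree_sequence_of(H), tri_degseq(c(2, 0), c(1, 1), c(1, 1)))
  d <- degree_sequence_of(H)
  expect_equal(sum(d$dA), n_edges(H))
  expect_equal(sum(d$dB), n_edges(H))
  expect_equal(sum(d$dC), n_edges(H))
})

test_that("hypergraphs reject duplicates and out-of-range vertices", {
  expect_error(tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(1, 1, 1))),
               "parallel")
  expect_error(tri_hypergraph(2, 2, 2, rbind(c(3, 1, 1))), "range")
})

test_that("energy is the L1 degree deviation and vanishes on realizations", {
  D <- tri_degseq(c(2, 4, 7), c(2, 4, 7), c(2, 4, 7))
  expect_equal(energy(empty_hypergraph(3, 3, 3), D), 39)
  # complete hypergraph on (4, 5, 164) against class sums 517
  H <- complete_hypergraph(4, 5, 164)
  D2 <- tri_degseq(c(517, 0, 0, 0), c(517, 0, 0, 0, 0),
                   c(rep(4, 25), rep(3, 139)))
  expect_equal(sum(D2$dC), 517)
  expect_equal(energy(H, D2), 3 * 4 * 5 * 164 - 3 * 517)
  expect_equal(energy(H, D2), 8289)
  # a realization has zero energy
  Hr <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(energy(Hr, degree_sequence_of(Hr)), 0)
  expect_error(energy(Hr, D), "dimension")
})

test_that("switch edits exchange one class and preserve all degrees", {
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(2, 2, 2)))
  op <- hypernull:::make_switch(c(1, 1, 1), c(2, 2, 2), 1)
  H2 <- apply_op(H, op)
  expect_setequal(apply(H2$edges, 1, paste, collapse = ","),
                  c("2,1,1", "1,2,2"))
  expect_equal(degree_sequence_of(H2), degree_sequence_of(H))
})

test_that("hinge flips move one endpoint; toggles change one edge", {
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1)))
  op <- hypernull:::make_hinge_flip(c(1, 1, 1), 1, 2)
  H2 <- apply_op(H, op)
  expect_equal(degree_sequence_of(H2)$dA, c(0, 1))
  expect_equal(degree_sequence_of(H2)$dB, degree_sequence_of(H)$dB)
  # toggling out of a realization raises the energy by 3
  D <- degree_sequence_of(H)
  H3 <- apply_op(H, edit_op("toggle_out", rbind(c(1, 1, 1)), NULL))
  expect_equal(energy(H3, D), 3)
})

test_that("invalid operations are refused with a typed condition", {
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(2, 2, 2)))
  bad <- edit_op("toggle_in", NULL, rbind(c(1, 1, 1)))  # already present
  expect_false(op_is_valid(H, bad))
  expect_error(apply_op(H, bad), class = "hypernull_invalid_op")
  gone <- edit_op("toggle_out", rbind(c(1, 2, 1)), NULL) # absent
  expect_error(apply_op(H, gone), class = "hypernull_invalid_op")
})

test_that("per-op energy increments match the move type", {
  # switch: 0; hinge flip: -2, 0, +2; toggle: -3, -1, +1, +3
  set.seed(42)
  for (rep in 1:40) {
    n <- c(sample(2:3, 1), sample(2:3, 1), sample(2:3, 1))
    H <- random_er_hypergraph(n[1], n[2], n[3], 0.5)
    D <- tri_degseq(flat_target(n[1], 4), random_composition(4, n[2]),
                    random_composition(4, n[3]))
    e0 <- energy(H, D)
    p <- propose_op(H)
    if (!p$valid) next
    dE <- energy(apply_op(H, p$op), D) - e0
    allowed <- switch(p$kind,
                      switch = 0,
                      hinge_flip = c(-2, 0, 2),
                      toggle = c(-3, -1, 1, 3))
    expect_true(dE %in% allowed,
                info = sprintf("kind=%s dE=%d", p$kind, dE))
  }
})

test_that("simplicity and incremental energy survive long op sequences", {
  set.seed(99)
  D <- tri_degseq(c(2, 2, 2), c(3, 2, 1), c(1, 2, 3))
  # check_every forces the compiled chain to compare its incremental energy
  # with a full recomputation throughout
  res <- run_chain(empty_hypergraph(3, 3, 3), D, 0.7, 1e5,
                   check_every = 1000)
  expect_false(anyDuplicated(hypernull:::edge_keys(res$H)) > 0)
  expect_equal(res$energy, energy(res$H, D))
})

test_that("projections, shadows and traces are mutually consistent", {
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(1, 1, 2)))
  P <- project(H, "AB")
  expect_equal(unclass(P), matrix(c(2L, 0L, 0L, 0L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(rowSums(P), degree_sequence_of(H)$dA)
  expect_equal(colSums(P), degree_sequence_of(H)$dB)
  expect_equal(sum(P), n_edges(H))
  # shadow pair-degrees equal the projection entries
  G <- shadow(H)
  pair_deg <- tabulate(G$edges[, 1], nbins = H$n1 * H$n2)
  expect_equal(pair_deg, as.vector(unclass(P)))
  # lifting the shadow reproduces the hypergraph
  expect_equal(sig_of(lift_shadow(G)), sig_of(H))
})

test_that("column balance detection and traces follow the ceiling rule", {
  expect_true(is_b_balanced(rbind(c(1, 2), c(2, 1))))
  expect_false(is_b_balanced(rbind(c(0, 3), c(2, 1))))
  expect_true(is_b_balanced(matrix(c(5, 0, 2), 1)))  # single row
  # balanced column (2,2,1): l = 2 marked 1, l - 1 = 1 marked 0
  P <- cbind(c(2, 2, 1))
  expect_equal(trace_of_projection(P), cbind(c(1L, 1L, 0L)))
  # all-equal column maps to all ones
  expect_equal(trace_of_projection(cbind(c(3, 3, 3))), cbind(c(1L, 1L, 1L)))
  expect_error(trace_of_projection(rbind(c(0, 1), c(2, 1))), "balanced")
})

test_that("edge lists and degree-sequence JSON round-trip through files", {
  H <- tri_hypergraph(3, 2, 2, rbind(c(1, 1, 1), c(3, 2, 1), c(2, 1, 2)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(H, f)
  expect_equal(sig_of(read_edge_list(f, 3, 2, 2)), sig_of(H))
  writeLines(c("# comment", "0 0 0", "0 0 0"), f)
  expect_error(read_edge_list(f, 2, 2, 2), "parallel")
  D <- tri_degseq(c(2, 1), c(1, 1, 1), c(3))
  g <- withr::local_tempfile(fileext = ".json")
  write_degseq_json(D, g)
  expect_equal(read_degseq_json(g), D)
})
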