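test_that("third almost-regularity is detected with its witness", {
  expect_true(is_third_almost_regular(c(3, 3, 2, 3))$ok)
  expect_equal(is_third_almost_regular(c(3, 3, 2, 3))$k, 3)
  expect_false(is_third_almost_regular(c(4, 2, 3))$ok)
  r <- is_third_almost_regular(c(5, 5, 5))
  expect_true(r$ok); expect_equal(r$k, 5)
})

test_that("north-west-corner filling realizes bipartite multigraph margins", {
  expect_equal(realize_bipartite_multigraph(c(2, 1), c(1, 1, 1)),
               rbind(c(1L, 1L, 0L), c(0L, 0L, 1L)))
  expect_equal(realize_bipartite_multigraph(c(0, 0), c(0, 0)),
               matrix(0L, 2, 2))
  expect_equal(realize_bipartite_multigraph(c(3), c(1, 2)),
               rbind(c(1L, 2L)))
  expect_true(is_infeasible(realize_bipartite_multigraph(c(2), c(1))))
})

test_that("balancing rewrites columns to ceiling/floor values, margins fixed", {
  P <- rbind(c(3, 0), c(1, 2))
  B <- balance_projection(P)
  expect_equal(B$P, rbind(c(2L, 1L), c(2L, 1L)))
  expect_true(is_b_balanced(B$P))
  # already balanced input is untouched, zero exchanges
  B2 <- balance_projection(rbind(c(2, 1), c(2, 1)))
  expect_equal(B2$exchanges, 0L)
  # single column: the rows are forced
  B3 <- balance_projection(cbind(c(2, 1)))
  expect_equal(B3$P, cbind(c(2L, 1L)))
  expect_error(balance_projection(rbind(c(4, 0), c(1, 1))), "almost-regular")
})

test_that("balancing preserves margins and stays within the L1/2 move bound", {
  set.seed(21)
  for (rep in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1); m <- sample(1:12, 1)
    dA <- flat_target(n1, m)[sample.int(n1)]
    dB <- random_composition(m, n2)
    P <- realize_bipartite_multigraph(dA, dB)
    dev0 <- sum(vapply(seq_len(n2), function(j) {
      q <- sum(P[, j]) %/% n1
      sum(abs(P[, j] - q)) # lower bound on deviation from any balanced column
    }, numeric(1)))
    B <- balance_projection(P)
    expect_equal(rowSums(B$P), rowSums(P))
    expect_equal(colSums(B$P), colSums(P))
    expect_true(is_b_balanced(B$P))
  }
})

test_that("bipartite Havel-Hakimi agrees with the Gale-Ryser oracle", {
  # tiny examples with forced structure
  G <- gale_ryser_realize(c(1, 1), c(2), n1 = 2, n2 = 1)
  expect_equal(nrow(G$edges), 2)
  expect_true(all(G$edges[, 2] == 1))
  G2 <- gale_ryser_realize(c(2), c(1, 1), n1 = 1, n2 = 1)
  expect_equal(sort(G2$edges[, 2]), c(1, 2))
  expect_true(is_infeasible(gale_ryser_realize(c(3), c(1, 1), 1, 1)))
  expect_equal(gale_ryser_realize(c(3), c(2, 1), 1, 1)$reason, "capacity")
  # randomized cross-check against igraph's bigraphical realization
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:80) {
    np <- sample(2:6, 1); n3 <- sample(2:5, 1); m <- sample(0:10, 1)
    dp <- pmin(random_composition(m, np), n3)
    dc <- pmin(random_composition(sum(dp), n3), np)
    if (sum(dp) != sum(dc)) next
    ours <- gale_ryser_realize(dp, dc, n1 = np, n2 = 1)
    ref <- tryCatch({
      igraph::realize_bipartite_degseq(dp, dc, method = "largest")
      TRUE
    }, error = function(e) FALSE)
    expect_equal(!is_infeasible(ours), ref,
                 info = sprintf("pairs=%s C=%s", toString(dp), toString(dc)))
    if (!is_infeasible(ours)) {
      expect_equal(tabulate(ours$edges[, 1], length(dp)), dp)
      expect_equal(tabulate(ours$edges[, 2], n3), dc)
      expect_false(anyDuplicated(paste(ours$edges[, 1], ours$edges[, 2])) > 0)
    }
  }
})

test_that("shadow lifting is a bijection", {
  H <- tri_hypergraph(2, 3, 2, rbind(c(1, 1, 1), c(2, 3, 2), c(1, 2, 2)))
  expect_equal(sig_of(lift_shadow(shadow(H))), sig_of(H))
  G <- gale_ryser_realize(c(1, 1, 0, 1), c(2, 1), n1 = 2, n2 = 2)
  G2 <- shadow(lift_shadow(G))
  ord <- function(g) g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
  expect_equal(unname(ord(G2)), unname(ord(G)))
})

test_that("the constructor realizes forced and tiny sequences", {
  H <- realize_third_almost_regular(tri_degseq(c(1, 1), c(1, 1), c(2, 0)))
  expect_false(is_infeasible(H))
  expect_equal(degree_sequence_of(H), tri_degseq(c(1, 1), c(1, 1), c(2, 0)))
  H2 <- realize_third_almost_regular(tri_degseq(1, 1, 1))
  expect_equal(sig_of(H2), "1")
  expect_true(is_infeasible(realize_third_almost_regular(tri_degseq(2, 1, 1))))
  expect_true(is_infeasible(
    realize_third_almost_regular(tri_degseq(c(1, 1), c(1, 1), c(1, 0)))))
  expect_error(realize_third_almost_regular(tri_degseq(c(4, 2, 3), c(3, 3, 3),
                                                       c(3, 3, 3))),
               "almost-regular")
})

test_that("construction decision agrees with the exhaustive oracle", {
  set.seed(17)
  n_cases <- 0
  while (n_cases < 200) {
    D <- random_tar_degseq(4, 10)
    n_cases <- n_cases + 1
    H <- realize_third_almost_regular(D)
    n_oracle <- enumerate_partite_realizations(D, count_only = TRUE,
                                               guard = 64)
    if (is_infeasible(H)) {
      expect_equal(n_oracle, 0L, info = paste(toString(D$dA), "|",
                                              toString(D$dB), "|",
                                              toString(D$dC)))
    } else {
      expect_gt(n_oracle, 0)
      expect_equal(degree_sequence_of(H), D)
    }
  }
})

test_that("B-balanced realizations are mutually reachable by switches", {
  # build the realization graph of a tiny sequence restricted to B-balanced
  # states, with switch moves as edges, and check it is connected
  set.seed(8)
  for (rep in 1:5) {
    D <- random_tar_degseq(3, 6)
    rs <- enumerate_partite_realizations(D, guard = 27)
    bal <- Filter(function(H) is_b_balanced(project(H, "AB")), rs)
    if (length(bal) < 2) next
    sigs <- vapply(bal, sig_of, character(1))
    adj <- lapply(bal, function(H) {
      nb <- switch_neighbors(H)
      which(sigs %in% nb)
    })
    # BFS over balanced states only
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_equal(sort(seen), seq_along(bal),
                 info = paste("D =", toString(D$dA), "|", toString(D$dB),
                              "|", toString(D$dC)))
  }
})

test_that("hinge-flip flattening reaches the almost-regular target", {
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(1, 2, 2)))
  out <- flatten_class_by_hinge_flips(H)          # dA = (2, 0) -> (1, 1)
  expect_equal(sort(degree_sequence_of(out$H)$dA), c(1, 1))
  expect_equal(out$flips, 1L)
  expect_equal(degree_sequence_of(out$H)$dB, degree_sequence_of(H)$dB)
  expect_equal(degree_sequence_of(out$H)$dC, degree_sequence_of(H)$dC)
  # already flat: zero flips
  out2 <- flatten_class_by_hinge_flips(out$H)
  expect_equal(out2$flips, 0L)
  # dA = (3, 1, 2) with 6 edges flattens to all-2 within the L1/2 bound
  set.seed(4)
  H3 <- tri_hypergraph(3, 3, 3,
                       rbind(c(1, 1, 1), c(1, 2, 2), c(1, 3, 3),
                             c(2, 1, 2), c(3, 2, 3), c(3, 3, 1)))
  out3 <- flatten_class_by_hinge_flips(H3, targetA = c(2, 2, 2))
  expect_equal(degree_sequence_of(out3$H)$dA, c(2, 2, 2))
  expect_lte(out3$flips, sum(abs(c(3, 1, 2) - c(2, 2, 2))) / 2)
  expect_error(flatten_class_by_hinge_flips(H, targetA = c(2, 0)),
               "almost-regular")
  expect_error(flatten_class_by_hinge_flips(H, targetA = c(2, 1)), "sum")
})
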