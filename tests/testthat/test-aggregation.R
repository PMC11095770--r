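test_that("expected counts follow the margin product", {
  expect_equal(expected_counts(rbind(c(2, 0), c(0, 2))),
               matrix(1, 2, 2))
  tab <- rbind(c(1, 2), c(2, 4))   # rank-1: equals its own expectation
  expect_equal(expected_counts(tab), tab, ignore_attr = TRUE)
  expect_equal(expected_counts(matrix(5)), matrix(5))
  expect_equal(sum(expected_counts(rbind(c(3, 1), c(0, 2)))), 6)
  expect_error(expected_counts(matrix(0)), "empty")
})

test_that("the aggregation index is zero exactly on rank-1 tables", {
  expect_equal(aggregation_index(rbind(c(2, 0), c(0, 2))), 4)
  expect_equal(aggregation_index(rbind(c(1, 0), c(0, 1))), 2)
  expect_equal(aggregation_index(rbind(c(1, 2), c(2, 4))), 0)
  expect_gt(aggregation_index(rbind(c(3, 1), c(1, 3))), 0)
  # invariant under simultaneous row/column permutations
  set.seed(1)
  tab <- matrix(rpois(12, 3), 3, 4)
  expect_equal(aggregation_index(tab[sample(3), sample(4)]),
               aggregation_index(tab))
  # zero-margin rows/columns contribute nothing
  tab0 <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 0))
  expect_equal(aggregation_index(tab0), aggregation_index(tab0[1:2, 1:2]))
})

test_that("the index of a hypergraph is that of its (B,C)-projection", {
  H <- tri_hypergraph(2, 2, 2, rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 2)))
  expect_equal(aggregation_index(H),
               aggregation_index(unclass(project(H, "BC"))))
})

test_that("the theoretical test refers to the chi-squared distribution", {
  expect_equal(theoretical_chi2_test(rbind(c(1, 2), c(2, 4)))$p_value, 1)
  # df = 1 quantile: statistic 3.841 sits near p = 0.05
  tab <- rbind(c(2, 0), c(0, 2))
  r <- theoretical_chi2_test(tab)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)
  # monotone: larger statistic, smaller p
  expect_lt(theoretical_chi2_test(rbind(c(4, 0), c(0, 4)))$p_value,
            r$p_value)
})

test_that("fixed-margin log-probabilities normalize over enumerated fibers", {
  expect_equal(hypergeometric_log_prob(diag(1, 2)), log(0.5))
  expect_equal(hypergeometric_log_prob(matrix(7)), 0)
  set.seed(2)
  for (rep in 1:6) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1); N <- sample(2:8, 1)
    rsum <- random_composition(N, nr); csum <- random_composition(N, nc)
    fib <- enumerate_margin_tables(rsum, csum)
    expect_gt(length(fib), 0)
    tot <- sum(exp(vapply(fib, hypergeometric_log_prob, numeric(1))))
    expect_equal(tot, 1, tolerance = 1e-10,
                 info = sprintf("R=%s C=%s", toString(rsum), toString(csum)))
  }
})

test_that("the table sampler matches the exact fiber distribution", {
  set.seed(3)
  # margins (2,2),(2,2): three tables with Eq-(1) masses 1/6, 4/6, 1/6
  fib <- enumerate_margin_tables(c(2, 2), c(2, 2))
  probs <- exp(vapply(fib, hypergeometric_log_prob, numeric(1)))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  smp <- sample_tables(c(2, 2), c(2, 2), n_samples = 20000, thin = 2,
                       burn_in = 200)
  key <- vapply(smp, function(t) paste(t, collapse = ","), character(1))
  fkey <- vapply(fib, function(t) paste(t, collapse = ","), character(1))
  emp <- as.numeric(table(factor(key, levels = fkey))) / length(smp)
  expect_lt(0.5 * sum(abs(emp - probs)), 0.02)
  # margins (1,1),(1,1): the two tables are equally likely
  smp2 <- sample_tables(c(1, 1), c(1, 1), n_samples = 8000, thin = 2)
  frac <- mean(vapply(smp2, function(t) t[1, 1] == 1, logical(1)))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 8000))
  # degenerate fiber: single possible table
  smp3 <- sample_tables(c(2, 0), c(1, 1), n_samples = 5)
  for (t in smp3) expect_equal(t, rbind(c(1L, 1L), c(0L, 0L)))
})

test_that("margins are invariant along the table chain", {
  set.seed(4)
  smp <- sample_tables(c(3, 1, 2), c(2, 2, 2), n_samples = 200, thin = 3)
  for (t in smp[c(1, 100, 200)]) {
    expect_equal(rowSums(t), c(3, 1, 2))
    expect_equal(colSums(t), c(2, 2, 2))
    expect_true(all(t >= 0))
  }
})

test_that("the exact test reports a normal upper tail and exceedance", {
  set.seed(5)
  tab <- rbind(c(6, 1), c(1, 6))
  r <- exact_chi2_test(tab, n_samples = 2000)
  expect_s3_class(r, "hypernull_test")
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_equal(r$n_null, 2000)
  # an aggregated table should look extreme against its fixed-margin null
  expect_lt(r$p_value, 0.2)
  # a balanced table should not
  r2 <- exact_chi2_test(rbind(c(4, 3), c(3, 4)), n_samples = 2000)
  expect_gt(r2$p_value, 0.2)
})

test_that("a unique-realization degree sequence gives a degenerate null", {
  set.seed(6)
  # D = ((1),(1),(1)) has exactly one realization: point-mass null
  H <- tri_hypergraph(1, 1, 1, rbind(c(1, 1, 1)))
  lad <- structure(list(temps = c(0.1, 1)), class = "temperature_ladder")
  r <- hypergraph_exact_chi2_test(H, n_samples = 30, ladder = lad,
                                  burn_in = 200, max_steps = 1e5)
  expect_true(r$degenerate)
  expect_equal(r$null_sd, 0)
  expect_equal(r$empirical_exceedance, 1)   # every null draw equals the obs
})

test_that("agent degree one makes the two exact tests agree (multinomial)", {
  # for D_A all ones of length N, the number of realizations projecting to
  # a table T with entries t_ij is the multinomial coefficient
  # N! / prod(t_ij!), so the projection of a uniform realization follows
  # the fixed-margin generalized hypergeometric law
  set.seed(7)
  for (case in list(list(B = c(2, 1), C = c(1, 2)),
                    list(B = c(3, 2), C = c(2, 3)),
                    list(B = c(2, 2), C = c(2, 2)))) {
    N <- sum(case$B)
    D <- tri_degseq(rep(1, N), case$B, case$C)
    rs <- enumerate_partite_realizations(D, guard = 4 * N)
    tabs <- vapply(rs, function(H) paste(unclass(project(H, "BC")),
                                         collapse = ","), character(1))
    fib <- enumerate_margin_tables(case$B, case$C)
    for (tb in fib) {
      n_real <- sum(tabs == paste(tb, collapse = ","))
      multinom <- exp(lgamma(N + 1) - sum(lgamma(tb + 1)))
      expect_equal(n_real, round(multinom),
                   info = paste("table", paste(tb, collapse = ",")))
    }
    # consequently: realization-projection law == Eq-(1) fiber law
    probs_fib <- exp(vapply(fib, hypergeometric_log_prob, numeric(1)))
    probs_hg <- vapply(fib, function(tb)
      sum(tabs == paste(tb, collapse = ",")) / length(rs), numeric(1))
    expect_equal(probs_hg, probs_fib, tolerance = 1e-12)
  }
})

test_that("contingency tables round-trip through CSV", {
  tab <- rbind(c(3, 1, 0), c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tab, f)
  expect_equal(unname(read_table_csv(f)), tab)
})

test_that("heavier agents shift the null aggregation index downwards", {
  # fixed 6-regular D_B, D_C on 4 vertices, 24 hyperedges; agents d-regular
  # on 24/d vertices: as agents place more entries each, the uniform-
  # realization null concentrates on more even tables
  set.seed(55)
  probe_args <- list(t_grid = exp(seq(log(0.05), log(30), length.out = 40)),
                     steps_per_t = 2000)
  means <- vapply(c(1, 2, 4), function(d) {
    D <- tri_degseq(rep(d, 24 / d), rep(6, 4), rep(6, 4))
    sr <- sample_realizations(D, n_samples = 250, spacing = 100,
                              probe_args = probe_args)
    mean(vapply(sr$samples, aggregation_index, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  # and the d = 1 null mean matches the table-based fixed-margin null
  tabs <- sample_tables(rep(6, 4), rep(6, 4), n_samples = 600, thin = 16)
  mean_fib <- mean(vapply(tabs, aggregation_index, numeric(1)))
  expect_lt(abs(means[1] - mean_fib) / mean_fib, 0.15)
})
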