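# hypernull

Degree-constrained tripartite hypergraph null models and aggregation tests.

## What problem this solves, and for whom

Triplet data — an *agent* places an *(event type, time point)* record; a user
tweets about a topic on a day; a species is observed at a site in a season —
collapses naturally into a simple tripartite 3-uniform hypergraph
`H = (A, B, C, E)`: one vertex class per variable, one hyperedge per
distinct triple.  Analysts usually ask whether the (B, C) margin of such
data (the contingency table `t_ij` of event-type-by-time counts) shows more
association — *aggregation* — than chance.  The catch is the null model.
Holding only the table margins fixed ignores the agents: because hyperedges
are simple, an agent placing many records necessarily spreads them over
distinct cells, flattening the table.  The honest null fixes the **entire
tripartite degree sequence**, agents included: uniform random simple
hypergraphs with the observed degrees.

`hypernull` is for data scientists, epidemiologists and ecologists who need
that null model.  It provides:

* the **aggregation index** `chi2_H = sum_ij (t_ij - e_ij)^2 / e_ij` with
  `e_ij = R_i C_j / N` computed on the (B, C)-projection of `H`, and three
  tests of it: *theoretical* (`chi2` with `(n_b-1)(n_c-1)` df), *exact*
  (fixed-margin generalized hypergeometric null,
  `P(t) = prod R_i! prod C_j! / (N! prod t_ij!)`, sampled by a
  fiber-walking Metropolis chain), and *hypergraph-based exact* (uniform
  realizations of the observed degree sequence);
* a polynomial **constructor/decider** for third almost-regular degree
  sequences (first class degrees all `k` or `k-1`): bipartite multigraph
  realization, column balancing by degree-preserving exchanges, bipartite
  Havel–Hakimi realization of the shadow sequence, and lifting;
* an energy-based **Metropolis chain** over all hypergraphs on fixed
  classes (energy = L1 deviation of the degree sequence from the target;
  moves: switches, hinge flips, toggles, one third each) and a **Parallel
  Tempering** sampler with a quartile-matched temperature ladder that
  harvests approximately uniform realizations from the coldest chain —
  needed because switches alone are not irreducible: the degree sequence
  `(2,4,7),(2,4,7),(2,4,7)` has exactly two realizations, six hyperedges
  apart;
* desk-scale **exhaustive oracles** (tripartite and non-partite 3-uniform
  enumeration, the numerical 3-dimensional-matching reduction and its
  brute-force solver) and **synthetic generators** for validation.

## Worked example

Synthetic triplet data with planted aggregation: 8 agents place 3 records
each on a 4 x 4 event-time grid; each event prefers one time point with odds
0.9 : 1.

```r
library(hypernull)
set.seed(9)
tbl  <- planted_aggregation_table(8, 4, 4, activity = 3, theta = 0.9)
conv <- to_hypergraph(tbl)        # 24 raw records, 23 after dedup
H    <- conv$H

project(H, "BC")                  # the event-by-time contingency table
#>      [,1] [,2] [,3] [,4]
#> [1,]    3    0    1    0
#> [2,]    0    4    2    0
#> [3,]    1    1    4    0
#> [4,]    1    1    4    1

theoretical_chi2_test(H)
#> theoretical chi-squared aggregation test
#>   statistic = 15.7399, df = 9, p = 0.07252 (upper tail)

exact_chi2_test(unclass(project(H, "BC")), n_samples = 2000)
#> exact chi-squared aggregation test
#>   statistic = 15.7399, p = 0.02862 (upper tail)
#>   null sample: n = 2000, mean = 9.399, sd = 3.335, empirical exceedance = 0.0465

hypergraph_exact_chi2_test(H, n_samples = 500,
  probe_args = list(t_grid = exp(seq(log(0.05), log(30), length.out = 40)),
                    steps_per_t = 2000))
#> hypergraph chi-squared aggregation test
#>   statistic = 15.7399, p = 0.007776 (upper tail)
#>   null sample: n = 500, mean = 8.639, sd = 2.935, empirical exceedance = 0.0180
```

All three tests see the same statistic, 15.74, but their nulls differ.  The
theoretical test does not reject at 5%.  The fixed-margin exact null has
mean 9.40; the hypergraph null — which also holds each agent's activity
fixed — sits lower, mean 8.64, so the same table is more surprising under
it (p = 0.008 vs 0.029): holding the agents fixed is what buys the extra
sensitivity.  The hypergraph test's machinery is visible along the way: a
temperature ladder built by quartile matching, Parallel Tempering with
swap diagnostics, and 500 harvested realizations of the observed degree
sequence.

Constructing and enumerating instead of sampling:

```r
D <- tri_degseq(c(2, 4, 7), c(2, 4, 7), c(2, 4, 7))
length(enumerate_partite_realizations(D))       # 2
H1 <- realize_third_almost_regular(
        tri_degseq(c(3, 3, 3), c(4, 3, 2), c(2, 3, 4)))  # polynomial path
energy(H1, tri_degseq(c(3, 3, 3), c(4, 3, 2), c(2, 3, 4)))  # 0
```

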