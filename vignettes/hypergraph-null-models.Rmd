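---
title: "Degree-constrained tripartite hypergraph null models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-constrained tripartite hypergraph null models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypernull)
```

## The problem

Many observational data sets are lists of triples: an *agent* places an
*(event type, time point)* record — a user tweets about a vaccine on a day, a
species is recorded at a site in a season.  Collapsing repeated triples gives
a simple **tripartite 3-uniform hypergraph** `H = (A, B, C, E)`: three
disjoint vertex classes, every hyperedge using exactly one vertex per class.
The practical question is whether the (B, C) margin of the data — the
contingency table `t_ij` counting hyperedges that join `b_i` and `c_j` — is
more *aggregated* (associated) than chance would allow.  The twist is what
"chance" should hold fixed.  Holding only the table margins fixed ignores
that a single agent placing many records spreads them over *distinct* cells
(hyperedges are simple), which evens out the table.  The right null model
fixes the entire tripartite degree sequence, agents included, and asks for a
uniform random simple hypergraph with those degrees.

This package provides that null model end to end: deciding and constructing
realizations where that is tractable, sampling them approximately uniformly
where it is not, and turning the samples into a significance test.

## Aggregation index and the three tests

For a table `t` with row sums `R_i`, column sums `C_j` and total `N`, the
expected counts under independence are `e_ij = R_i C_j / N` and the
aggregation index is the Pearson statistic
`chi2_H = sum (t_ij - e_ij)^2 / e_ij`, with cells whose expectation is zero
(an all-zero margin) excluded.  For a hypergraph the table is its
(B, C)-projection, so `N` equals the number of hyperedges and the margins are
the B- and C-degree sequences.  Three nulls give three tests:

* **theoretical** — `chi2` distribution with `(n_b - 1)(n_c - 1)` degrees of
  freedom;
* **exact** — uniform placement with fixed margins, i.e. the generalized
  hypergeometric law `P(t) = prod R_i! prod C_j! / (N! prod t_ij!)`, sampled
  by a Metropolis chain over the fixed-margin fiber;
* **hypergraph-based exact** — uniform simple hypergraphs with the observed
  degree sequence, sampled by Parallel Tempering.

When every agent has degree one the last two coincide: the number of
realizations projecting to a table `t` is the multinomial coefficient
`N! / prod t_ij!`, which is exactly the hypergeometric weighting (the test
suite verifies this by full enumeration).  With heavier agents the
hypergraph null shifts to *smaller* indices, so the hypergraph test is the
more sensitive one — the package checks this directionally with a one-sided
sign test on planted-aggregation data.

For both Monte Carlo tests the p-value is the upper tail of a normal
distribution fitted to the null sample (mean and unbiased standard
deviation).  This follows the usual practice of smoothing an empirical null
whose raw exceedance resolution is limited to `1 / n_samples`; the raw
exceedance frequency is always reported alongside.  We use the upper tail
only, since aggregation means a large index.  A degenerate null (zero
variance, e.g. a degree sequence with a unique realization) is flagged and
falls back to the empirical exceedance.

One ambiguity resolved deliberately: the expected-count denominator is the
table total `sum t_ij = |E|`.  (Adding the row-sum and column-sum totals
would give `2|E|`, but the expectation formula itself fixes the convention.)

## Constructing realizations: the third almost-regular case

Deciding whether an arbitrary tripartite degree sequence is graphic is
NP-complete; the package carries the reduction from the numerical
3-dimensional matching problem (`reduction_degree_sequence()`) both as a
hardness witness and as a generator of sharply structured instances.  But
when the first class is **almost-regular** (all degrees `k` or `k - 1`) the
decision and a construction are polynomial:

1. realize `(D_A, D_B)` as a bipartite *multigraph* (north-west-corner
   filling);
2. **balance** it column by column so each column of the multiplicity matrix
   takes only the values `ceiling(d(b)/n1)` and that value minus one, via
   margin-preserving unit exchanges, each cutting the column's L1 deviation
   by 2 (`balance_projection()`);
3. read the balanced multiplicities as the pair-vertex degrees of a *shadow*
   sequence and realize it as a simple bipartite graph with a
   largest-degree-first bipartite Havel–Hakimi construction
   (`gale_ryser_realize()`), which succeeds exactly under the Gale–Ryser
   conditions;
4. lift each shadow edge `((a_i, b_j), c_k)` to the hyperedge
   `(a_i, b_j, c_k)`.

Determinism choices (ascending column order, lowest-index tie-breaks,
stable sorts) are made once so that tests are reproducible; the underlying
arguments guarantee termination under any order.  `flatten_class_by_hinge_flips()`
implements the complementary fact that hinge flips connect arbitrary degree
sequences to almost-regular ones: the default target sorts the ceiling
degrees onto the currently highest-degree vertices, following the sorted
convention of the constructive argument (a permutation-free target would
change nothing essential, but the sorted one is what the argument fixes).

## The Markov chain and its energy

The sampler walks on *all* simple hypergraphs over the fixed classes, not
just realizations, because switches alone are not irreducible on
realizations: the degree sequence `(2,4,7)^3` — produced by the matching
reduction from weights `1:3` per class with bound 6 — has exactly two
realizations whose symmetric difference is six hyperedges, more than one
switch can bridge.  (The enumeration oracle certifies both counterexamples,
including the non-partite nine-vertex sequence `(4,8,10,12,13,16,17,19,24)`
with the same property.)

The energy of a state is the L1 deviation of its degree sequence from the
prescribed one; the Boltzmann distribution at temperature `T` weights states
by `exp(-energy / T)`.  One chain step draws a move kind with equal
probability one third each:

* **switch** — two edges drawn uniformly *with replacement* plus a uniform
  class (a literal reading of the kernel definition); degree-preserving;
* **hinge flip** — a uniform edge, a uniform class, a uniform replacement
  vertex among the other class members;
* **toggle** — a uniform cell, deleted if occupied else inserted.

Any proposal that would duplicate an edge, that drew the same edge twice, or
that has nothing to act on is an **invalid proposal** and the chain performs
a lazy self-loop that still advances the clock.  This keeps the kernel
symmetric — the probability of proposing `H'` from `H` equals the reverse —
so plain Metropolis acceptance `min(1, exp(-(dE)/T))` targets the Boltzmann
law; the acceptance comparison is done in log space for numerical safety at
tiny temperatures.  Energies are integers maintained incrementally, with an
optional full-recomputation cross-check (`check_every`), so no floating
tolerance enters the bookkeeping.  Invalid-proposal accounting makes the
identity "switch acceptance + invalid-switch fraction = 1" hold at every
temperature, since a valid switch never changes the energy.

A finite-size note on proposal statistics: on a uniform (ER `p = 0.5`)
hypergraph the invalid-hinge probability is 1/2, and the valid-switch
probability is 1/4 *in the limit of large classes*.  On classes of size `n`
the two drawn edges share the exchanged-class vertex with probability about
`1/n`, which forces the replacement edges to coincide with the removed ones
and invalidates the switch; on `(10, 10, 10)` the exact value is therefore
about 0.224 rather than 0.250.  The acceptance checks report the faithful
number.

## Parallel Tempering

`k` chains at temperatures `T_1 < ... < T_k` evolve jointly: each composite
step either advances one uniformly chosen chain by one Metropolis step
(probability 1/2) or attempts to swap the states of a uniformly chosen
adjacent pair, accepting with the Boltzmann ratio of the exchanged
assignment.  Swaps let the cold chain tunnel between energy minima — e.g.
between the two `(2,4,7)^3` realizations — while each marginal still targets
its own Boltzmann law.

**Ladder design.**  `probe_quartiles()` runs independent chains on a
log-spaced temperature grid (default 100 points) and records the post-burn-in
(default 20%) energy quartiles; isotonic regression in log-temperature
removes probe noise, the canonical choice for "make these curves monotone".
`build_ladder()` then walks a staircase: the next temperature is where the
lower quartile curve reaches the current temperature's upper quartile.  Two
endpoint rules are promoted from observations to defaults: the coldest rung
is the smallest probed temperature whose zero-energy occupancy exceeds 90%
(so realizations dominate there), and the hottest is the smallest whose
median energy is within 5% of the infinite-temperature estimate
`sum |d - d_max/2|` (so the hot chain mixes like the uniform distribution,
where toggles alone walk a hypercube rapidly).  Where the staircase equation
has a whole interval of solutions — both quartiles are zero over the cold
plateau, for instance — we take the *largest* temperature still satisfying
it, i.e. walk to the right-hand end of the stair tread; globally flat curves
thus degenerate to the two endpoints, with a warning.  Quartile matching
guarantees that with probability at least `(1/4)^2` the colder chain holds
the larger energy, in which case the swap is accepted outright, so adjacent
swap acceptance is at least 6.25%.

**Harvesting.**  Realizations are collected from the coldest chain whenever
its energy is zero and at least `spacing` of its own proposals have elapsed
since the previous harvest.  The default spacing is the edge count — one
expected proposal per hyperedge between samples.  The definition counts
*all* coldest-chain proposals, not only switches; the narrower reading
(switch proposals only) would simply triple the spacing.  The sampler doubles
as a stochastic search: no realization needs to be known up front, and a
budget exhausted without ever reaching zero energy raises a typed
`hypernull_timeout` condition carrying the best energy seen — on adversarial
inputs this is unavoidable, since graphicality itself is NP-complete.
`autocorrelation_diagnostics()` embeds harvests as 0–1 cell-indicator
vectors and reports the lag autocorrelation of the first two principal
coordinates, the practical convergence check for harvest independence.

## Synthetic data

`planted_aggregation_table()` emulates the triplet data the tests exercise:
agents with a prescribed activity profile place records whose event type is
uniform and whose time point is the event's (cyclically assigned) preferred
time with probability `theta / (1 + theta)`, uniform otherwise.  `theta = 0`
gives independent placement — under degree-one agents exactly the
fixed-margin null — and large `theta` concentrates each event on one time.
Duplicates are kept in the table and collapse only on conversion to a
hypergraph, reproducing the evening-out effect of simple hyperedges.  What
the generator does *not* emulate: heavy-tailed real-world activity is
available only through the explicit activity profile (e.g. Zipf-like counts
passed by the caller), and there is no temporal drift, bursty correlation
between agents, or label noise.  Tests passing on these tables therefore
validate the machinery — margins, nulls, sensitivity ordering — not any
claim about a specific empirical system.

## Problem sizes and numerical choices in the checks

The validation suite works at enumeration scale by design: Boltzmann
agreement is checked on `(1, 2, 2)` and `(2, 2, 2)` grids (16 and 256
states) at a million steps against total-variation 0.02–0.03;
construction-versus-oracle agreement on 200 random third almost-regular
sequences with classes up to 4; fiber normalization and the multinomial
equivalence on tables with totals up to 8; reduction soundness on 100 random
matching instances with `k <= 3`.  Mode-uniformity over the two `(2,4,7)^3`
realizations uses 400 harvests spaced 2000 coldest-chain proposals apart:
the three-standard-error binomial band presumes near-independent draws, and
tunneling between switch-disconnected modes is slower than single-edge
relaxation, so the check thins more aggressively than the default spacing
(which remains the package default).  The sensitivity comparison runs 30
planted replicates (8 agents of activity 3 on a 4 x 4 event-time grid,
`theta = 0.8`) and applies a one-sided sign test to "hypergraph p <= exact
p".  Temperature probes in the checks use 40–60 grid points of a few
thousand steps each; these are configuration knobs, not constants.

## Known limitations

* Graphicality for general (non-almost-regular) first classes is only ever
  decided stochastically, by the sampler finding a realization; a timeout is
  evidence, not proof, of infeasibility.
* The normal fit for p-values is a smoothing convenience; for very skewed
  nulls the reported empirical exceedance is the safer quantity.
* Uniformity of harvested realizations holds in the limit of long runs;
  diagnostics (swap acceptance, zero-energy occupancy, autocorrelation)
  must be consulted on new instances, exactly as one would for any MCMC.
* The enumeration oracles are deliberately guarded (default 60 cells, 9
  vertices, `k <= 5`); they refuse rather than truncate.
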