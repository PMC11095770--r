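#' Rough expected energy at infinite temperature
#'
#' At infinite temperature the Boltzmann distribution is uniform over all
#' hypergraphs, i.e. every cell is occupied with probability 1/2, so every
#' vertex degree concentrates near half its maximal value.  The sum of
#' absolute differences between the prescribed degrees and half the maximal
#' degrees is therefore a rough estimate of the expected energy there; it
#' anchors the hot end of the temperature ladder.
#'
#' @param D A `tri_degseq`.
#' @return Numeric estimate.
#' @export
infinite_temperature_energy <- function(D) {
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  sum(abs(D$dA - n2 * n3 / 2)) + sum(abs(D$dB - n1 * n3 / 2)) +
    sum(abs(D$dC - n1 * n2 / 2))
}

#' Probe Boltzmann energy quartiles along a temperature grid
#'
#' Runs an independent Metropolis chain at each probe temperature, records
#' the post-burn-in energy trace, and reports its lower/upper quartiles and
#' median together with the fraction of zero-energy visits.  The quartile
#' curves are then made monotone in temperature by pool-adjacent-violators
#' isotonic regression (probe noise removal); interpolation between probes
#' is done on the log-temperature axis.
#'
#' @param D Prescribed `tri_degseq`.
#' @param t_grid Ascending positive probe temperatures; default 100 points
#'   log-spaced between `t_range[1]` and `t_range[2]`.
#' @param t_range Range used when `t_grid` is `NULL`.
#' @param steps_per_t Chain length per probe temperature.
#' @param burn_in_frac Fraction of each probe run discarded as burn-in.
#' @param smooth Apply the isotonic smoothing (default `TRUE`).
#' @return An object of class `energy_quartiles`: a list with `temps`,
#'   `lower`, `upper`, `median`, `zero_frac`, the raw (pre-smoothing)
#'   curves, and probe metadata.
#' @export
probe_quartiles <- function(D, t_grid = NULL, t_range = c(0.05, 50),
                            steps_per_t = 4000, burn_in_frac = 0.2,
                            smooth = TRUE) {
  if (is.null(t_grid))
    t_grid <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = 100))
  stopifnot(all(t_grid > 0), !is.unsorted(t_grid))
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  H0 <- empty_hypergraph(n1, n2, n3)
  burn <- floor(steps_per_t * burn_in_frac)
  qs <- vapply(t_grid, function(tt) {
    res <- run_chain(H0, D, tt, steps_per_t, energy_every = 1)
    tr <- res$energy_trace[-seq_len(burn)]
    c(stats::quantile(tr, c(0.25, 0.5, 0.75), names = FALSE),
      mean(tr == 0))
  }, numeric(4))
  raw <- list(lower = qs[1, ], median = qs[2, ], upper = qs[3, ])
  out <- raw
  if (smooth && length(t_grid) > 1) {
    iso <- function(y) stats::isoreg(log(t_grid), y)$yf
    out <- lapply(raw, iso)
  }
  structure(list(temps = t_grid, lower = out$lower, upper = out$upper,
                 median = out$median, zero_frac = qs[4, ], raw = raw,
                 steps_per_t = steps_per_t, burn_in = burn),
            class = "energy_quartiles")
}

# interpolate a quartile curve at temperature tt (log-T axis, clamped)
interp_curve <- function(temps, values, tt) {
  stats::approx(log(temps), values, xout = log(tt), rule = 2)$y
}

# smallest probed temperature whose curve first crosses a level
first_temp_at <- function(temps, values, level, above = TRUE) {
  hit <- if (above) which(values >= level) else which(values <= level)
  if (!length(hit)) NA_real_ else temps[hit[1L]]
}

#' Build a quartile-matched temperature ladder
#'
#' Staircase construction: starting from the coldest temperature, the next
#' temperature is the one whose *lower* energy quartile equals the current
#' temperature's *upper* quartile (solved by interpolation on the smoothed
#' curves).  Adjacent chains then overlap enough that with probability at
#' least `(1/4)^2 = 6.25%` the colder chain holds the higher energy, in
#' which case a state swap is accepted with probability 1.
#'
#' Endpoints default to the probe-derived rules: the coldest temperature is
#' the smallest probed one whose zero-energy occupancy exceeds
#' `zero_occupancy` (so realizations dominate there), and the hottest is
#' the smallest probed one whose median energy is within 5% of the
#' infinite-temperature estimate (so the hot chain mixes like the uniform
#' distribution).  Degenerate (flat) curves fall back to geometric spacing
#' with a warning.
#'
#' @param quartiles An `energy_quartiles` probe.
#' @param D The probed `tri_degseq` (for the infinite-temperature anchor).
#' @param t_min,t_max Optional endpoint overrides.
#' @param zero_occupancy Zero-energy occupancy threshold for the cold end.
#' @param max_chains Safety cap on the ladder length.
#' @return An object of class `temperature_ladder`: list with `temps` and
#'   the per-rung interpolated `lower`/`upper` quartiles.
#' @export
build_ladder <- function(quartiles, D, t_min = NULL, t_max = NULL,
                         zero_occupancy = 0.9, max_chains = 128) {
  stopifnot(inherits(quartiles, "energy_quartiles"))
  temps <- quartiles$temps
  if (is.null(t_min)) {
    t_min <- first_temp_at(temps, -quartiles$zero_frac, -zero_occupancy,
                           above = FALSE)
    if (is.na(t_min)) t_min <- temps[1L]
  }
  if (is.null(t_max)) {
    e_inf <- infinite_temperature_energy(D)
    t_max <- first_temp_at(temps, quartiles$median, 0.95 * e_inf)
    if (is.na(t_max)) t_max <- temps[length(temps)]
  }
  if (t_max <= t_min) t_max <- temps[length(temps)]
  lower <- function(tt) interp_curve(temps, quartiles$lower, tt)
  upper <- function(tt) interp_curve(temps, quartiles$upper, tt)
  lo <- quartiles$lower
  ladder <- t_min
  repeat {
    cur <- ladder[length(ladder)]
    if (cur >= t_max || length(ladder) >= max_chains) break
    target <- upper(cur)
    # next T solves lower(T) = upper(cur); along flat stretches take the
    # largest such T (walk to the right end of the stair tread)
    ok <- which(lo <= target + 1e-9)
    i_last <- if (length(ok)) max(ok) else 0L
    if (i_last >= length(temps)) {
      # lower quartile never exceeds upper(cur): jump straight to the top
      if (lower(t_max) <= target + 1e-9 && upper(t_max) <= target + 1e-9 &&
          length(ladder) == 1L)
        warning("flat quartile curves; ladder degenerates to the endpoints")
      nxt <- t_max
    } else if (temps[i_last] <= cur || i_last == 0L) {
      nxt <- temps[min(which(temps > cur))]   # steep rise: next probe point
    } else {
      # crossing between probes i_last and i_last + 1 (log-T interpolation)
      x1 <- log(temps[i_last]); x2 <- log(temps[i_last + 1L])
      y1 <- lo[i_last]; y2 <- lo[i_last + 1L]
      nxt <- if (y2 > y1) exp(x1 + (target - y1) / (y2 - y1) * (x2 - x1))
             else temps[i_last + 1L]
    }
    if (nxt <= cur) break
    ladder <- c(ladder, min(nxt, t_max))
  }
  if (ladder[length(ladder)] < t_max) ladder <- c(ladder, t_max)
  if (length(ladder) < 2L) ladder <- c(t_min, t_max)
  structure(list(temps = ladder,
                 lower = vapply(ladder, lower, numeric(1)),
                 upper = vapply(ladder, upper, numeric(1)),
                 probe = quartiles),
            class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("temperature_ladder with %d rungs: %s\n", length(x$temps),
              paste(signif(x$temps, 3), collapse = ", ")))
  invisible(x)
}

#' Run the composite Parallel Tempering chain
#'
#' One composite step either performs a Metropolis step in a uniformly
#' chosen member chain (probability 1/2) or attempts a state swap between a
#' uniformly chosen adjacent temperature pair, accepted with the Boltzmann
#' ratio of the exchanged assignment.  Each coordinate converges to the
#' Boltzmann distribution at its own temperature; the swap moves let the
#' cold chain tunnel between energy minima that its own moves cannot
#' connect.
#'
#' @param states List of starting `tri_hypergraph` states, one per rung.
#' @param D Prescribed `tri_degseq`.
#' @param temps Ascending positive temperatures.
#' @param n_steps Number of composite steps.
#' @param weights Proposal mixture weights within member chains.
#' @param harvest If `TRUE`, collect coldest-chain states at zero energy.
#' @param spacing Minimum number of coldest-chain proposals between
#'   harvests; default `sum(D$dA)` (one expected touch per hyperedge).
#' @param max_samples Stop after this many harvested samples (0 = no cap).
#' @param cold_energy_every Record the coldest chain's energy every this
#'   many of its moves (0 = off).
#' @param track_states Count coldest-chain state visits per composite step
#'   (instances of at most 20 cells).
#' @return A list: final `states`, their `energies`, harvested `samples`
#'   (list of `tri_hypergraph`), `swap_attempts`/`swap_accepts` per
#'   adjacent pair, per-rung `op_stats`, `cold_steps`,
#'   `cold_zero_frac`, `best_cold_energy`, `steps_done`.
#' @export
pt_run <- function(states, D, temps, n_steps, weights = c(1, 1, 1) / 3,
                   harvest = FALSE, spacing = NULL, max_samples = 0,
                   cold_energy_every = 0, track_states = FALSE) {
  stopifnot(is.list(states), length(states) == length(temps),
            all(diff(temps) > 0), all(temps > 0))
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  for (s in states)
    stopifnot(inherits(s, "tri_hypergraph"),
              s$n1 == n1, s$n2 == n2, s$n3 == n3)
  if (is.null(spacing)) spacing <- sum(D$dA)
  weights <- weights / sum(weights)
  res <- cpp_pt_run(n1, n2, n3, lapply(states, function(s) s$edges - 1L),
                    D$dA, D$dB, D$dC, temps, n_steps, weights,
                    spacing, as.integer(max_samples), harvest,
                    as.integer(cold_energy_every), track_states)
  wrap <- function(em) tri_hypergraph(n1, n2, n3, em + 1L)
  list(states = lapply(res$states, wrap),
       energies = res$energies,
       samples = lapply(res$samples, wrap),
       swap_attempts = res$swap_attempts,
       swap_accepts = res$swap_accepts,
       op_stats = res$op_stats,
       cold_steps = res$cold_steps,
       cold_zero_frac = if (res$cold_steps > 0)
         res$cold_zero_steps / res$cold_steps else NA_real_,
       cold_energy_trace = res$cold_energy_trace,
       best_cold_energy = res$best_cold_energy,
       steps_done = res$steps_done,
       state_visits = if (track_states) res$state_visits)
}

#' Sample realizations of a degree sequence by Parallel Tempering
#'
#' Harvests approximately uniform realizations of `D`: states of the
#' coldest chain visited at zero energy, spaced by at least `spacing`
#' coldest-chain proposals (by default one expected proposal per hyperedge).
#' The sampler also serves as a stochastic search for a first realization —
#' no realization needs to be known up front.
#'
#' @param D Prescribed `tri_degseq`.
#' @param ladder A `temperature_ladder`, or `NULL` to build one from a
#'   fresh probe with default settings.
#' @param n_samples Number of realizations to harvest.
#' @param spacing Coldest-chain proposals between harvests (default
#'   `sum(D$dA)`).
#' @param burn_in Composite steps run before harvesting starts.
#' @param max_steps Composite-step budget for the harvesting phase; if the
#'   budget is exhausted before any zero-energy state is seen, a condition
#'   of class `hypernull_timeout` is signalled carrying the best energy
#'   reached.
#' @param weights Proposal mixture weights.
#' @param probe_args List of arguments passed to [probe_quartiles()] when
#'   `ladder` is `NULL`.
#' @return A list: `samples` (list of `tri_hypergraph`, each realizing
#'   `D`), `ladder`, and `diagnostics` (swap acceptance per pair, per-rung
#'   op stats, coldest-chain zero-energy occupancy, spacing, steps used).
#' @export
sample_realizations <- function(D, ladder = NULL, n_samples = 100,
                                spacing = NULL, burn_in = NULL,
                                max_steps = NULL, weights = c(1, 1, 1) / 3,
                                probe_args = list()) {
  if (is.null(ladder)) {
    q <- do.call(probe_quartiles, c(list(D = D), probe_args))
    ladder <- build_ladder(q, D)
  }
  temps <- ladder$temps
  k <- length(temps)
  n1 <- length(D$dA); n2 <- length(D$dB); n3 <- length(D$dC)
  if (is.null(spacing)) spacing <- max(1L, sum(D$dA))
  if (is.null(burn_in)) burn_in <- 200L * k * max(1L, sum(D$dA))
  if (is.null(max_steps))
    max_steps <- 2 * k * (spacing + 10) * (n_samples + 10) * 4
  states <- replicate(k, empty_hypergraph(n1, n2, n3), simplify = FALSE)
  warm <- pt_run(states, D, temps, burn_in, weights)
  res <- pt_run(warm$states, D, temps, max_steps, weights, harvest = TRUE,
                spacing = spacing, max_samples = n_samples)
  if (length(res$samples) == 0L) {
    cond <- structure(
      class = c("hypernull_timeout", "error", "condition"),
      list(message = sprintf(
        "no zero-energy state reached; best coldest-chain energy was %d",
        as.integer(min(warm$best_cold_energy, res$best_cold_energy))),
        call = sys.call(), best_energy = min(warm$best_cold_energy,
                                             res$best_cold_energy)))
    stop(cond)
  }
  if (length(res$samples) < n_samples)
    warning(sprintf("harvested %d of %d requested samples within budget",
                    length(res$samples), n_samples))
  for (s in res$samples) stopifnot(energy(s, D) == 0L)
  list(samples = res$samples, ladder = ladder,
       diagnostics = list(
         swap_attempts = res$swap_attempts,
         swap_accepts = res$swap_accepts,
         swap_acceptance = ifelse(res$swap_attempts > 0,
                                  res$swap_accepts / res$swap_attempts,
                                  NA_real_),
         op_stats = res$op_stats,
         cold_zero_frac = res$cold_zero_frac,
         spacing = spacing, burn_in = burn_in,
         steps_done = res$steps_done))
}

#' Sample-trajectory diagnostics via principal coordinates
#'
#' Embeds harvested hypergraphs as 0-1 indicator vectors over the
#' `n1*n2*n3` cells, projects on the first two principal components, and
#' reports the lag autocorrelation of both coordinate series — a practical
#' check that consecutive harvests are close to independent.
#'
#' @param samples List of `tri_hypergraph` on common classes (at least 10).
#' @param max_lag Largest lag in the autocorrelation report.
#' @return A list with `scores` (n x 2 matrix), `acf1`, `acf2` (numeric
#'   vectors, lag 0..max_lag) and `zero_variance` flag (all samples
#'   identical).
#' @export
autocorrelation_diagnostics <- function(samples, max_lag = 20) {
  stopifnot(length(samples) >= 10)
  H1 <- samples[[1L]]
  N <- H1$n1 * H1$n2 * H1$n3
  X <- t(vapply(samples, function(s) {
    v <- numeric(N); v[edge_keys(s)] <- 1; v
  }, numeric(N)))
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L)))
    return(list(scores = matrix(0, nrow(X), 2), acf1 = NA_real_,
                acf2 = NA_real_, zero_variance = TRUE))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)
  max_lag <- min(max_lag, nrow(sc) - 1L)
  ac <- function(v) {
    if (stats::sd(v) == 0) return(rep(NA_real_, max_lag + 1L))
    drop(stats::acf(v, lag.max = max_lag, plot = FALSE)$acf)
  }
  list(scores = sc[, 1:2], acf1 = ac(sc[, 1L]), acf2 = ac(sc[, 2L]),
       zero_variance = FALSE)
}
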