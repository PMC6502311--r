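#' Mean epistasis within and between two diverged populations
#'
#' Arithmetic means of the epistatic coefficient over all unordered pairs
#' of loci fixed within each population and over all between-population
#' pairs (each counted once). Pairs without a stored interaction
#' contribute exactly 0. A component whose pair set is empty is reported
#' as `NA` (absent).
#'
#' @param network an `epistasis_network`.
#' @param fixed_a,fixed_b locus labels (or indices) fixed in the two
#'   populations.
#' @return list with `within_a`, `within_b`, `between`.
#' @export
epistasis_components <- function(network, fixed_a, fixed_b) {
  ia <- locus_index(network, fixed_a)
  ib <- locus_index(network, fixed_b)
  within <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    sum(pair_values_within(network, idx)) / choose(length(idx), 2)
  }
  between <- if (length(ia) == 0L || length(ib) == 0L) NA_real_ else
    sum(pair_values_between(network, ia, ib)) / (length(ia) * length(ib))
  list(within_a = within(ia), within_b = within(ib), between = between)
}

#' Frequency of heterosis at a given divergence depth
#'
#' Fraction of replicates whose relative hybrid fitness strictly exceeds 1
#' at the point where each population has fixed `n_per_population`
#' mutations.
#'
#' @param trajectories stacked trajectory table (columns `replicate`,
#'   `n_a`, `n_b`, `w_h`) from [simulate_divergence()].
#' @param n_per_population queried depth (fixations in each population).
#' @return fraction in \[0, 1\].
#' @export
heterosis_frequency <- function(trajectories, n_per_population) {
  rows <- trajectories[trajectories$n_a == n_per_population &
                         trajectories$n_b == n_per_population, , drop = FALSE]
  reps <- unique(trajectories$replicate)
  missing <- setdiff(reps, rows$replicate)
  if (length(missing))
    stop("replicate(s) never reach n_a = n_b = ", n_per_population, ": ",
         paste(missing, collapse = ", "))
  mean(rows$w_h > 1)
}

#' Mean per-substitution decline of hybrid fitness
#'
#' For each replicate the geometric per-step decline rate
#' `1 - (w_H(n_final) / w_H(0))^(1/n_final)` is computed and averaged over
#' replicates; the arithmetic mean of per-step proportional declines is
#' reported alongside (the two differ when steps are heterogeneous).
#' Positive values are declines.
#'
#' @inheritParams heterosis_frequency
#' @return list with `geometric` and `arithmetic` mean decline rates.
#' @export
per_substitution_decline <- function(trajectories) {
  per_rep <- function(df) {
    df <- df[order(df$n), , drop = FALSE]
    if (nrow(df) < 2L) stop("need at least 2 trajectory steps per replicate")
    w0 <- df$w_h[1L]
    wf <- df$w_h[nrow(df)]
    nf <- df$n[nrow(df)] - df$n[1L]
    geo <- 1 - (wf / w0)^(1 / nf)
    steps <- diff(df$w_h) / df$w_h[-nrow(df)]
    c(geo = geo, arith = mean(-steps))
  }
  res <- vapply(split(trajectories, trajectories$replicate), per_rep,
                numeric(2))
  list(geometric = mean(res["geo", ]), arithmetic = mean(res["arith", ]))
}

#' Fraction of replicates with a large single-substitution fitness change
#'
#' A replicate counts when at least one fixation changes relative hybrid
#' fitness by more than `threshold` in proportion to its value before the
#' fixation, in either direction.
#'
#' @inheritParams heterosis_frequency
#' @param threshold proportional change cutoff (default 0.10).
#' @return fraction of replicates in \[0, 1\].
#' @export
large_effect_fraction <- function(trajectories, threshold = 0.10) {
  per_rep <- function(df) {
    df <- df[order(df$n), , drop = FALSE]
    any(abs(diff(df$w_h)) / df$w_h[-nrow(df)] > threshold)
  }
  mean(vapply(split(trajectories, trajectories$replicate), per_rep,
              logical(1)))
}

#' Fraction of substitutions positively selected in the other population
#'
#' For each locus fixed in population A, evaluates the sign of its
#' effective selection coefficient in population B's genetic background
#' (and vice versa). A positive sign means the allele could adaptively
#' introgress despite overall hybrid breakdown.
#'
#' @param network an `epistasis_network`.
#' @param fixed_a,fixed_b disjoint fixed sets of the two populations.
#' @param dom a [dominance_params()] object.
#' @return list with `a_in_b` and `b_in_a`, each the fraction of that
#'   population's substitutions with positive effective selection in the
#'   other background (`NaN` for an empty set).
#' @export
introgression_fraction <- function(network, fixed_a, fixed_b,
                                   dom = dominance_params()) {
  ia <- locus_index(network, fixed_a)
  ib <- locus_index(network, fixed_b)
  if (length(intersect(ia, ib)))
    stop("fixed_a and fixed_b must be disjoint")
  frac <- function(from, bg) {
    if (length(from) == 0L) return(NaN)
    mean(effective_all(network, from, bg, dom)$sigma > 0)
  }
  list(a_in_b = frac(ia, ib), b_in_a = frac(ib, ia))
}

#' Introgression potential as divergence deepens
#'
#' Reconstructs, from a simulation's event logs, each replicate's fixed
#' sets at the point where both populations hold `depth` substitutions and
#' evaluates [introgression_fraction()] there; results are averaged over
#' replicates and over the two cross directions.
#'
#' @param sim a `divergence_sim` from [simulate_divergence()].
#' @param network the network the simulation ran on.
#' @param depths integer vector of fixations-per-population at which to
#'   evaluate.
#' @param dom dominance parameters (defaults to the simulation's).
#' @return data frame with columns `depth` and `fraction`.
#' @export
introgression_summary <- function(sim, network, depths,
                                  dom = sim$config$dominance) {
  ev <- sim$events
  per_rep <- function(df, depth) {
    a <- df$locus[df$population == "A"][seq_len(depth)]
    b <- df$locus[df$population == "B"][seq_len(depth)]
    if (anyNA(a) || anyNA(b)) return(NA_real_)
    fr <- introgression_fraction(network, a, b, dom)
    (fr$a_in_b + fr$b_in_a) / 2
  }
  out <- vapply(depths, function(d) {
    vals <- vapply(split(ev, ev$replicate), per_rep, numeric(1), depth = d)
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  data.frame(depth = depths, fraction = out)
}

#' Cross-replicate percentile envelope
#'
#' Lower/upper percentile band across replicates at each column (e.g. each
#' substitution count). With `level = 0.95` these are the 2.5th and 97.5th
#' percentiles, the interpretation of the shaded bands around trajectory
#' means.
#'
#' @param values numeric matrix with one row per replicate and one column
#'   per evaluation point. At least 20 replicates are required.
#' @param level coverage level (default 0.95).
#' @return data frame with columns `lower` and `upper`, one row per
#'   column of `values`.
#' @export
band <- function(values, level = 0.95) {
  values <- as.matrix(values)
  if (nrow(values) < 20L)
    stop("need at least 20 replicates for a percentile band, got ",
         nrow(values))
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must be in (0, 1)")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- apply(values, 2L, stats::quantile, probs = probs, names = FALSE)
  data.frame(lower = q[1L, ], upper = q[2L, ])
}

#' Percentile band of a trajectory variable over replicates
#'
#' Convenience wrapper around [band()] that pivots a stacked trajectory
#' table to a replicate-by-n matrix first.
#'
#' @inheritParams heterosis_frequency
#' @param var trajectory column to band (default `"w_h"`).
#' @param level coverage level.
#' @return data frame with columns `n`, `lower`, `upper`.
#' @export
trajectory_band <- function(trajectories, var = "w_h", level = 0.95) {
  ns <- sort(unique(trajectories$n))
  reps <- sort(unique(trajectories$replicate))
  m <- matrix(NA_real_, length(reps), length(ns),
              dimnames = list(reps, ns))
  m[cbind(match(trajectories$replicate, reps),
          match(trajectories$n, ns))] <- trajectories[[var]]
  if (anyNA(m)) {
    keep <- colSums(is.na(m)) == 0L
    m <- m[, keep, drop = FALSE]
    ns <- ns[keep]
  }
  cbind(n = ns, band(m, level))
}
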