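#' Configuration for the sequential-fixation divergence simulation
#'
#' The simulation follows the mutation-limited (origin-fixation) regime:
#' two isolated populations alternately fix one mutation at a time, each
#' candidate locus weighted by its Kimura fixation probability given the
#' population's current genetic background. No locus may fix in both
#' populations.
#'
#' @param effective_size effective population size `N_e` (default `1e6`).
#' @param fixations_per_population substitutions to accumulate in each
#'   population (default 50).
#' @param dominance a [dominance_params()] object.
#' @param alternation `"strict"` (default; populations fix alternately
#'   A, B, A, B, ..., realizing symmetric divergence, v close to 1/4) or
#'   `"random"` (each fixation lands in population A with probability
#'   `rate_ratio / (1 + rate_ratio)`, for asymmetric divergence).
#' @param rate_ratio fixation-rate ratio A:B used by the `"random"` scheme.
#' @param seed integer master seed. Per-replicate streams are derived
#'   deterministically from it, keyed by replicate index, so increasing
#'   `replicate_count` never perturbs earlier replicates.
#' @param replicate_count number of stochastic replicates run by
#'   [simulate_divergence()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(effective_size = 1e6,
                              fixations_per_population = 50,
                              dominance = dominance_params(),
                              alternation = c("strict", "random"),
                              rate_ratio = 1,
                              seed = 1L,
                              replicate_count = 1L) {
  alternation <- match.arg(alternation)
  if (effective_size < 2) stop("effective_size must be >= 2")
  if (fixations_per_population < 1) stop("fixations_per_population must be >= 1")
  if (!inherits(dominance, "dominance_params"))
    stop("dominance must be a dominance_params object")
  if (!is.finite(rate_ratio) || rate_ratio <= 0)
    stop("rate_ratio must be positive")
  structure(list(effective_size = effective_size,
                 fixations_per_population = as.integer(fixations_per_population),
                 dominance = dominance,
                 alternation = alternation,
                 rate_ratio = rate_ratio,
                 seed = as.integer(seed),
                 replicate_count = as.integer(replicate_count)),
            class = "simulation_config")
}

#' Create an empty population state
#'
#' @param label population identifier, conventionally `"A"` or `"B"`.
#' @return object of class `population_state` with an empty ordered set of
#'   fixed loci.
#' @export
population_state <- function(label) {
  structure(list(fixed = integer(0), label = label),
            class = "population_state")
}

#' Fixation-probability weights over available loci
#'
#' For every locus not yet fixed in either population, computes the
#' effective selection coefficient and dominance against the focal
#' population's fixed background and converts them to a Kimura fixation
#' probability. The next substitution is drawn proportional to these
#' weights (they need not sum to 1).
#'
#' @param network an `epistasis_network`.
#' @param state_self the fixing population's `population_state`.
#' @param state_other the other population's state (its loci are excluded
#'   from the candidate set).
#' @param config a [simulation_config()].
#' @return named numeric vector of weights (one per available locus), with
#'   attributes `"sigma"`, `"omega"` and `"candidates"` (integer indices).
#' @export
candidate_weights <- function(network, state_self, state_other, config) {
  cand <- setdiff(seq_len(n_loci(network)),
                  c(state_self$fixed, state_other$fixed))
  eff <- effective_all(network, cand, state_self$fixed, config$dominance)
  w <- fixation_probability(eff$sigma, eff$omega, config$effective_size)
  names(w) <- network$locus_ids[cand]
  attr(w, "sigma") <- eff$sigma
  attr(w, "omega") <- eff$omega
  attr(w, "candidates") <- cand
  w
}

#' Fix the next mutation in one population
#'
#' Samples one available locus with probability proportional to its
#' fixation probability (using R's global RNG stream) and appends it to
#' the population's fixed set.
#'
#' @inheritParams candidate_weights
#' @param step step index recorded in the event.
#' @param weights optional precomputed result of [candidate_weights()]
#'   for this state (used by [run_divergence()], which maintains the
#'   weights incrementally); computed afresh when `NULL`.
#' @return list with the updated `state` and a one-row `event` data frame
#'   (`step`, `population`, `locus`, `sigma_at_fixation`,
#'   `fixation_probability`), or `NULL` when every candidate has weight 0
#'   (stuck population).
#' @export
fix_next <- function(network, state_self, state_other, config,
                     step = NA_integer_, weights = NULL) {
  w <- if (is.null(weights)) {
    candidate_weights(network, state_self, state_other, config)
  } else {
    weights
  }
  if (length(w) == 0L || all(w == 0)) return(NULL)
  pick <- sample.int(length(w), 1L, prob = w)
  idx <- attr(w, "candidates")[pick]
  state_self$fixed <- c(state_self$fixed, idx)
  event <- data.frame(step = step,
                      population = state_self$label,
                      locus = network$locus_ids[idx],
                      sigma_at_fixation = attr(w, "sigma")[pick],
                      fixation_probability = unname(w[pick]))
  list(state = state_self, event = event)
}

#' Run one replicate of divergence in allopatry
#'
#' Iterates [fix_next()] under the configured alternation scheme until
#' each population has fixed `fixations_per_population` mutations (or a
#' population gets stuck with no fixable mutation, in which case the
#' replicate is aborted and flagged rather than restarted). After every
#' fixation the relative hybrid fitness and the within/between epistasis
#' components are recorded.
#'
#' @param network an `epistasis_network` with at least
#'   `2 * fixations_per_population` loci.
#' @param config a [simulation_config()]. The caller controls the RNG
#'   (seed the global stream, or use [simulate_divergence()]).
#' @return list with `state_a`, `state_b`, `events` (data frame),
#'   `trajectory` (data frame with columns `n`, `n_a`, `n_b`, `w_h`,
#'   `eps_within_a`, `eps_within_b`, `eps_between`; the first row is the
#'   ancestral n = 0 state) and `stuck` (logical).
#' @export
run_divergence <- function(network, config) {
  k <- config$fixations_per_population
  nl <- n_loci(network)
  if (nl < 2L * k)
    stop("network must have at least 2 * fixations_per_population loci")
  dom <- config$dominance
  s <- network$s
  h <- network$h
  ## general CSC copy for fast column slices
  EG <- methods::as(methods::as(network$emat, "generalMatrix"), "CsparseMatrix")
  state_a <- population_state("A")
  state_b <- population_state("B")

  ## Incrementally maintained per-population quantities (avoids rebuilding
  ## growing submatrices every step): for every locus l, the running
  ## products over the population's fixed set
  ##   ps[l] = prod_j max(1 + eps_lj, 0)         (effective selection)
  ##   pq[l] = prod_j max(1 + alpha2 eps_lj, 0)  (effective dominance)
  ## and log-product accumulators for the parental and hybrid pair terms
  ## (log of positive factors plus a count of clamped-to-zero factors).
  pop <- list(
    A = list(ps = rep(1, nl), pq = rep(1, nl), pair_log = 0, pair_zero = 0L,
             eps_sum = 0),
    B = list(ps = rep(1, nl), pq = rep(1, nl), pair_log = 0, pair_zero = 0L,
             eps_sum = 0))
  hy_log <- 0; hy_zero <- 0L       # product of (1 + alpha1 eps) over hybrid pairs
  between_sum <- 0
  avail <- rep(TRUE, nl)

  total <- 2L * k
  events <- vector("list", total)
  traj <- matrix(NA_real_, total + 1L, 7L,
                 dimnames = list(NULL, c("n", "n_a", "n_b", "w_h",
                                         "eps_within_a", "eps_within_b",
                                         "eps_between")))
  traj[1L, 1:4] <- c(0, 0, 0, 1)
  stuck <- FALSE
  for (step in seq_len(total)) {
    fix_in_a <- if (config$alternation == "strict") {
      step %% 2L == 1L
    } else if (length(state_a$fixed) >= k) {
      FALSE
    } else if (length(state_b$fixed) >= k) {
      TRUE
    } else {
      stats::runif(1) < config$rate_ratio / (1 + config$rate_ratio)
    }
    self <- if (fix_in_a) "A" else "B"
    other <- if (fix_in_a) "B" else "A"
    st_self <- if (fix_in_a) state_a else state_b
    st_other <- if (fix_in_a) state_b else state_a

    cand <- which(avail)
    sigma <- pmax(1 + s[cand], 0) * pop[[self]]$ps[cand] - 1
    num <- pmax(1 + h[cand] * s[cand], 0) * pop[[self]]$pq[cand] - 1
    omega <- ifelse(sigma == 0, h[cand], num / sigma)
    w <- fixation_probability(sigma, omega, config$effective_size)
    names(w) <- network$locus_ids[cand]
    attr(w, "sigma") <- sigma
    attr(w, "omega") <- omega
    attr(w, "candidates") <- cand

    res <- fix_next(network, st_self, st_other, config, step = step,
                    weights = w)
    if (is.null(res)) {
      stuck <- TRUE
      break
    }
    idx <- res$state$fixed[length(res$state$fixed)]
    if (fix_in_a) state_a <- res$state else state_b <- res$state
    events[[step]] <- res$event

    ## update incremental state with the new locus's interaction column
    col <- as.numeric(EG[, idx])
    own <- setdiff(res$state$fixed, idx)
    v_own <- col[own]
    v_oth <- col[st_other$fixed]
    P <- pop[[self]]
    P$eps_sum <- P$eps_sum + sum(v_own)
    f <- 1 + v_own
    P$pair_zero <- P$pair_zero + sum(f <= 0)
    P$pair_log <- P$pair_log + sum(log(f[f > 0]))
    P$ps <- P$ps * pmax(1 + col, 0)
    P$pq <- P$pq * pmax(1 + dom$alpha2 * col, 0)
    pop[[self]] <- P
    between_sum <- between_sum + sum(v_oth)
    fh <- 1 + dom$alpha1 * c(v_own, v_oth)
    hy_zero <- hy_zero + sum(fh <= 0)
    hy_log <- hy_log + sum(log(fh[fh > 0]))
    avail[idx] <- FALSE

    ## trajectory record
    na <- length(state_a$fixed); nb <- length(state_b$fixed)
    w_hyb <- prod_clamped(1 + h[c(state_a$fixed, state_b$fixed)] *
                            s[c(state_a$fixed, state_b$fixed)]) *
      (if (hy_zero > 0L) 0 else exp(hy_log))
    w_par <- function(pn, fixed) {
      prod_clamped(1 + s[fixed]) *
        (if (pop[[pn]]$pair_zero > 0L) 0 else exp(pop[[pn]]$pair_log))
    }
    parent_mean <- (w_par("A", state_a$fixed) + w_par("B", state_b$fixed)) / 2
    traj[step + 1L, ] <- c(
      na + nb, na, nb,
      if (parent_mean > 0) w_hyb / parent_mean else NA_real_,
      if (na >= 2L) pop$A$eps_sum / choose(na, 2) else NA_real_,
      if (nb >= 2L) pop$B$eps_sum / choose(nb, 2) else NA_real_,
      if (na >= 1L && nb >= 1L) between_sum / (na * nb) else NA_real_)
  }
  traj <- as.data.frame(traj[!is.na(traj[, "n"]), , drop = FALSE])
  list(state_a = state_a, state_b = state_b,
       events = do.call(rbind, events[!vapply(events, is.null, logical(1))]),
       trajectory = traj,
       stuck = stuck)
}

## Deterministic per-replicate seed derived from the master seed, keyed by
## replicate index (kept below 2^31 - 1).
derive_seed <- function(seed, replicate) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 +
                replicate * 104729) %% 2147483647)
}

#' Run replicated divergence simulations
#'
#' Runs `config$replicate_count` independent replicates of
#' [run_divergence()], each on its own deterministic RNG stream derived
#' from the master seed, and stacks their trajectories and event logs.
#' Stuck replicates are excluded from the stacked tables but counted.
#'
#' @inheritParams run_divergence
#' @return object of class `divergence_sim`: list with `trajectories`
#'   (stacked data frame with a `replicate` column), `events` (likewise),
#'   `states` (per-replicate list of the two final fixed index sets),
#'   `n_stuck`, `config`.
#' @export
simulate_divergence <- function(network, config) {
  reps <- vector("list", config$replicate_count)
  for (r in seq_len(config$replicate_count)) {
    reps[[r]] <- withr::with_seed(derive_seed(config$seed, r),
                                  run_divergence(network, config))
  }
  ok <- !vapply(reps, `[[`, logical(1), "stuck")
  add_rep <- function(df, r) if (is.null(df)) NULL else cbind(replicate = r, df)
  trajectories <- do.call(rbind, Map(function(x, r) add_rep(x$trajectory, r),
                                     reps[ok], which(ok)))
  events <- do.call(rbind, Map(function(x, r) add_rep(x$events, r),
                               reps[ok], which(ok)))
  states <- lapply(reps, function(x)
    list(fixed_a = x$state_a$fixed, fixed_b = x$state_b$fixed,
         stuck = x$stuck))
  structure(list(trajectories = trajectories, events = events,
                 states = states, n_stuck = sum(!ok), config = config),
            class = "divergence_sim")
}

#' @export
print.divergence_sim <- function(x, ...) {
  cat("Divergence simulation: ", x$config$replicate_count, " replicate(s), ",
      x$config$fixations_per_population, " fixations/population\n", sep = "")
  if (x$n_stuck > 0) cat("  stuck replicates: ", x$n_stuck, "\n", sep = "")
  invisible(x)
}
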