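test_that("candidate weights are uniform on a neutral network", {
  net <- neutral_network(10)
  cfg <- simulation_config(fixations_per_population = 2)
  w <- candidate_weights(net, population_state("A"), population_state("B"),
                         cfg)
  expect_identical(length(w), 10L)
  expect_true(all(w == 1 / (2 * cfg$effective_size)))
})

test_that("loci fixed in either population leave the candidate set", {
  net <- neutral_network(6)
  cfg <- simulation_config(fixations_per_population = 2)
  a <- population_state("A"); a$fixed <- c(1L, 3L)
  b <- population_state("B"); b$fixed <- 5L
  w <- candidate_weights(net, a, b, cfg)
  expect_setequal(names(w), net$locus_ids[c(2, 4, 6)])
})

test_that("effectively lethal loci get zero weight", {
  net <- epistasis_network(c("x", "y", "z"), s = c(-1, 0.01, 0),
                           pairs = data.frame(locus_i = "x", locus_j = "y",
                                              epsilon = 0.3))
  cfg <- simulation_config(fixations_per_population = 1)
  w <- candidate_weights(net, population_state("A"), population_state("B"),
                         cfg)
  expect_identical(unname(w["x"]), 0)
  expect_gt(w["y"], 0)
})

test_that("weights chain the effective-selection and fixation formulas", {
  ## four-locus network with printed coefficients; population A already
  ## fixed for l1, l2
  net <- epistasis_network(
    c("l1", "l2", "l3", "l4"), s = c(0.02, 0.01, 5e-4, -2e-4),
    pairs = data.frame(locus_i = c("l1", "l1", "l2", "l2"),
                       locus_j = c("l3", "l4", "l3", "l4"),
                       epsilon = c(2e-3, -1e-3, 1e-3, 3e-3)))
  cfg <- simulation_config(effective_size = 1e4,
                           fixations_per_population = 1)
  a <- population_state("A"); a$fixed <- c(1L, 2L)
  w <- candidate_weights(net, a, population_state("B"), cfg)
  for (loc in c("l3", "l4")) {
    eff <- effective_selection(net, loc, c("l1", "l2"), cfg$dominance)
    expect_equal(unname(w[loc]),
                 fixation_probability(eff$sigma, eff$omega, 1e4),
                 tolerance = 1e-12)
  }
  ## hand-chained value for l3: sigma from the two background interactions
  sig3 <- (1 + 5e-4) * (1 + 2e-3) * (1 + 1e-3) - 1
  eff3 <- effective_selection(net, "l3", c("l1", "l2"), cfg$dominance)
  expect_equal(eff3$sigma, sig3, tolerance = 1e-12)
})

test_that("sampling respects fixation-probability weights", {
  net <- neutral_network(3)
  cfg <- simulation_config(fixations_per_population = 1, seed = 1)
  w <- structure(c(1, 2, 2), names = net$locus_ids,
                 sigma = c(0, 0, 0), omega = c(0.5, 0.5, 0.5),
                 candidates = 1:3)
  draws <- withr::with_seed(123, {
    vapply(1:20000, function(k) {
      fix_next(net, population_state("A"), population_state("B"), cfg,
               weights = w)$event$locus
    }, character(1))
  })
  freq <- table(factor(draws, levels = net$locus_ids)) / length(draws)
  expected <- c(0.2, 0.4, 0.4)
  tol <- 3 * sqrt(expected * (1 - expected) / length(draws))
  expect_true(all(abs(freq - expected) < tol))
})

test_that("a single positive-weight locus is the one fixed", {
  net <- epistasis_network(c("x", "y"), s = c(-1, 0.01))
  cfg <- simulation_config(fixations_per_population = 1)
  res <- fix_next(net, population_state("A"), population_state("B"), cfg,
                  step = 1L)
  expect_identical(res$event$locus, "y")
  expect_identical(res$state$fixed, 2L)
})

test_that("an all-lethal candidate set signals a stuck population", {
  net <- epistasis_network(c("x", "y"), s = c(-1, -1))
  cfg <- simulation_config(fixations_per_population = 1)
  expect_null(fix_next(net, population_state("A"), population_state("B"),
                       cfg))
  rep <- run_divergence(net, cfg)
  expect_true(rep$stuck)
})

test_that("replicates are deterministic given the master seed", {
  net <- generate_synthetic(synthetic_network_spec(n_loci = 40, seed = 2))
  cfg <- simulation_config(fixations_per_population = 5, seed = 17,
                           replicate_count = 2)
  s1 <- simulate_divergence(net, cfg)
  s2 <- simulate_divergence(net, cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$events, s2$events)
  ## different seeds give different event logs
  cfg2 <- simulation_config(fixations_per_population = 5, seed = 18,
                            replicate_count = 2)
  s3 <- simulate_divergence(net, cfg2)
  expect_false(identical(s1$events$locus, s3$events$locus))
  ## growing the replicate count never perturbs earlier replicates
  cfg3 <- simulation_config(fixations_per_population = 5, seed = 17,
                            replicate_count = 4)
  s4 <- simulate_divergence(net, cfg3)
  expect_identical(s4$trajectories[s4$trajectories$replicate <= 2, ],
                   s1$trajectories)
})

test_that("fixed sets stay disjoint and reach the configured size", {
  net <- generate_synthetic(synthetic_network_spec(n_loci = 60, seed = 3))
  cfg <- simulation_config(fixations_per_population = 8, seed = 4,
                           replicate_count = 3)
  sim <- simulate_divergence(net, cfg)
  expect_identical(sim$n_stuck, 0L)
  for (st in sim$states) {
    expect_identical(length(st$fixed_a), 8L)
    expect_identical(length(st$fixed_b), 8L)
    expect_identical(length(intersect(st$fixed_a, st$fixed_b)), 0L)
  }
})

test_that("the neutral network yields a flat unit hybrid-fitness trajectory", {
  net <- neutral_network(20)
  cfg <- simulation_config(fixations_per_population = 5, seed = 6,
                           replicate_count = 2)
  sim <- simulate_divergence(net, cfg)
  expect_true(all(sim$trajectories$w_h == 1))
})

test_that("trajectory rows agree with the stateless fitness and summary modules", {
  net <- generate_synthetic(synthetic_network_spec(n_loci = 50, seed = 8))
  cfg <- simulation_config(fixations_per_population = 6, seed = 9,
                           replicate_count = 2)
  sim <- simulate_divergence(net, cfg)
  for (r in unique(sim$events$replicate)) {
    ev <- sim$events[sim$events$replicate == r, ]
    tr <- sim$trajectories[sim$trajectories$replicate == r, ]
    for (k in seq_len(nrow(ev))) {
      a <- ev$locus[ev$population == "A"][seq_len(sum(ev$population[1:k] == "A"))]
      b <- ev$locus[ev$population == "B"][seq_len(sum(ev$population[1:k] == "B"))]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      expect_equal(tr$w_h[k + 1],
                   relative_hybrid_fitness(net, a, b, cfg$dominance),
                   tolerance = 1e-10)
      comps <- epistasis_components(net, a, b)
      expect_equal(tr$eps_between[k + 1], comps$between, tolerance = 1e-12)
    }
  }
})

test_that("strict alternation interleaves populations exactly", {
  net <- constant_network(30, eps = 1e-3)
  cfg <- simulation_config(fixations_per_population = 5, seed = 11)
  res <- withr::with_seed(1, run_divergence(net, cfg))
  expect_identical(res$events$population, rep(c("A", "B"), 5))
})

test_that("the constant-epistasis simulation matches the closed-form trajectory", {
  c0 <- 1e-3
  net <- constant_network(50, eps = c0)
  cfg <- simulation_config(fixations_per_population = 20, seed = 13)
  rep <- withr::with_seed(21, run_divergence(net, cfg))
  tr <- rep$trajectory
  even <- tr$n %% 2 == 0 & tr$n > 0
  pred <- analytic_relative_fitness(tr$n[even], eps_w = c0, eps_b = c0,
                                    v = 0.25, alpha1 = 0.25)
  ## second-order pair-count bound on the log scale
  bound <- 2 * c0^2 * choose(tr$n[even], 2)
  expect_true(all(abs(log(tr$w_h[even]) - log(pred)) <= bound))
})
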