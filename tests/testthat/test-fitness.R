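test_that("ancestral and hand-computed genotype fitnesses are exact", {
  net <- two_locus_network(0.05, s = c(0.1, 0.1))
  expect_identical(genotype_fitness(net), 1)
  expect_equal(genotype_fitness(net, hom = c("i", "j")), 1.1 * 1.1 * 1.05)
  expect_equal(genotype_fitness(net, het = c("i", "j"),
                                dom = dominance_params(alpha1 = 0.25)),
               1.05^2 * (1 + 0.0125))
})

test_that("genotype fitness equals brute-force factor enumeration", {
  for (seed in 1:8) {
    net <- random_network(6, seed = 400 + seed)
    dom <- withr::with_seed(500 + seed,
                            dominance_params(alpha1 = runif(1),
                                             alpha2 = runif(1)))
    withr::with_seed(600 + seed, {
      for (rep in 1:6) {
        z <- sample(c("none", "het", "hom"), 6, replace = TRUE)
        het <- net$locus_ids[z == "het"]
        hom <- net$locus_ids[z == "hom"]
        expect_equal(genotype_fitness(net, het, hom, dom),
                     oracle_fitness(net, het, hom, dom$alpha1, dom$alpha2),
                     tolerance = 1e-12)
      }
    })
  }
})

test_that("clamped factors make genotypes lethal, never negative", {
  net <- epistasis_network(c("i", "j"), s = c(0, 0),
                           pairs = data.frame(locus_i = "i", locus_j = "j",
                                              epsilon = -1))
  expect_identical(genotype_fitness(net, hom = c("i", "j")), 0)
  lethal <- epistasis_network("k", s = -1)
  expect_identical(genotype_fitness(lethal, hom = "k"), 0)
})

test_that("hybrid fitness reproduces the canonical two-locus scenarios", {
  ## one mutation fixed in each population, strong negative interaction
  ## expressed fully in the heterozygous hybrid
  net <- two_locus_network(-0.5)
  expect_identical(
    relative_hybrid_fitness(net, "i", "j", dominance_params(alpha1 = 1)),
    0.5)
  ## both mutations in one parent: the hybrid escapes the deleterious
  ## interaction and shows heterosis
  expect_equal(
    relative_hybrid_fitness(net, c("i", "j"), character(0),
                            dominance_params(alpha1 = 0)),
    4 / 3)
  expect_identical(relative_hybrid_fitness(net, character(0), character(0)),
                   1)
})

test_that("neutral networks give unit fitness for every genotype", {
  net <- neutral_network(6)
  withr::with_seed(42, {
    for (rep in 1:5) {
      z <- sample(c("none", "het", "hom"), 6, replace = TRUE)
      expect_identical(genotype_fitness(net, net$locus_ids[z == "het"],
                                        net$locus_ids[z == "hom"]), 1)
    }
  })
  expect_identical(relative_hybrid_fitness(net, net$locus_ids[1:2],
                                           net$locus_ids[3:4]), 1)
})

test_that("hybrid fitness is symmetric under population swap", {
  net <- random_network(6, seed = 11)
  a <- net$locus_ids[1:3]
  b <- net$locus_ids[4:6]
  dom <- dominance_params(alpha1 = 0.3, alpha2 = 0.7)
  expect_identical(relative_hybrid_fitness(net, a, b, dom),
                   relative_hybrid_fitness(net, b, a, dom))
})

test_that("raising a between-population epsilon weakly raises hybrid fitness", {
  for (e in list(c(-0.4, -0.2), c(-0.2, 0), c(0, 0.3))) {
    lo <- epistasis_network(c("i", "j", "k"), s = c(0.05, -0.05, 0.1),
                            pairs = data.frame(locus_i = "i", locus_j = "j",
                                               epsilon = e[1]))
    hi <- epistasis_network(c("i", "j", "k"), s = c(0.05, -0.05, 0.1),
                            pairs = data.frame(locus_i = "i", locus_j = "j",
                                               epsilon = e[2]))
    dom <- dominance_params(alpha1 = 0.25)
    expect_lte(relative_hybrid_fitness(lo, c("i", "k"), "j", dom),
               relative_hybrid_fitness(hi, c("i", "k"), "j", dom))
  }
})

test_that("with recessive epistasis in hybrids only parental terms matter", {
  ## alpha1 = 0: no between-population pair can affect w_H
  base <- random_network(6, seed = 77)
  dom <- dominance_params(alpha1 = 0)
  a <- base$locus_ids[1:3]
  b <- base$locus_ids[4:6]
  w1 <- relative_hybrid_fitness(base, a, b, dom)
  ## perturb every between-population epsilon; w_H must not move
  p <- base$pairs
  ia <- match(a, base$locus_ids); ib <- match(b, base$locus_ids)
  between <- (p$i %in% ia & p$j %in% ib) | (p$i %in% ib & p$j %in% ia)
  p$epsilon[between] <- pmin(p$epsilon[between] + 0.3, 1)
  pert <- epistasis_network(base$locus_ids, base$s, base$h, pairs = p)
  expect_equal(relative_hybrid_fitness(pert, a, b, dom), w1,
               tolerance = 1e-12)
})

test_that("effective coefficients follow the background-product formula", {
  net <- epistasis_network(c("i", "j"), s = c(0.1, 0),
                           pairs = data.frame(locus_i = "i", locus_j = "j",
                                              epsilon = -0.2))
  ## empty background: sigma = s, omega = h
  e0 <- effective_selection(net, "i")
  expect_identical(e0$sigma, 0.1)
  expect_identical(e0$omega, 0.5)
  ## one-locus background
  e1 <- effective_selection(net, "i", "j",
                            dom = dominance_params(alpha2 = 0.5))
  expect_equal(e1$sigma, 1.1 * 0.8 - 1)
  expect_equal(e1$omega, (1.05 * 0.9 - 1) / (1.1 * 0.8 - 1))
})

test_that("effective selection matches an enumeration oracle on random networks", {
  for (seed in 1:5) {
    net <- random_network(6, seed = 700 + seed)
    E <- dense_eps(net)
    dom <- dominance_params(alpha2 = 0.35)
    for (l in 1:6) {
      bg <- setdiff(1:6, l)[1:3]
      got <- effective_selection(net, net$locus_ids[l], net$locus_ids[bg], dom)
      sig <- prod(pmax(c(1 + net$s[l], 1 + E[l, bg]), 0)) - 1
      expect_equal(got$sigma, sig, tolerance = 1e-12)
      if (sig != 0) {
        om <- (prod(pmax(c(1 + net$h[l] * net$s[l],
                           1 + dom$alpha2 * E[l, bg]), 0)) - 1) / sig
        expect_equal(got$omega, om, tolerance = 1e-12)
      }
    }
  }
})
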