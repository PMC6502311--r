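# epidiverge

Hybrid fitness on pairwise epistatic networks: from double-knockout
fitness data (or synthetic networks with the same statistical structure)
to the evolution of heterosis and postzygotic isolation between two
populations diverging in allopatry.

## Who this is for

Speciation geneticists and modelers who want to ask, on an empirically
parameterizable gene-interaction network: when do F1 hybrids between two
diverging populations do *better* than their parents, when do they break
down, and which interactions are responsible? Unlike classical
Dobzhansky–Muller models, both positive and negative epistasis enter, and
the substitution process itself (selection + drift) decides which
interactions each population accumulates.

## The model in brief

An individual heterozygous for mutations in set G1 and homozygous in G2
has multiplicative fitness

    W = prod (1 + h_i s_i)        over i in G1
      * prod (1 + s_i)            over i in G2
      * prod (1 + a1 * eps_ij)    over het x het pairs
      * prod (1 + a2 * eps_ij)    over het x hom pairs
      * prod (1 + eps_ij)         over hom x hom pairs

with `s_i` the independent selection coefficient, `h_i` its dominance,
`eps_ij` the pairwise epistatic coefficient, and `a1`, `a2` the
*epistatic dominance* parameters. Relative hybrid fitness `w_H` divides
the F1 fitness (heterozygous everywhere) by the arithmetic mean of the
two parents; `w_H > 1` is heterosis. A closed form describes its
trajectory in the number of substitutions `n`:

    w_H ~ exp{ eps_b * a1 * v * n^2
               - eps_w * (1/2 - a1) * [ (1/2 - v) n^2 - n/2 ] }

where `eps_w`/`eps_b` are mean within/between-population epistasis and
`v = F(1-F)` measures divergence symmetry. Stochastic divergence is
simulated in the origin–fixation regime, weighting every candidate locus
by Kimura's diffusion fixation probability evaluated on its
background-dependent effective selection coefficient and dominance.

## Worked example

```r
library(epidiverge)

## one deleterious interaction (eps = -0.5), two neutral loci
net <- epistasis_network(c("i", "j"), s = c(0, 0),
                         pairs = data.frame(locus_i = "i", locus_j = "j",
                                            epsilon = -0.5))

## split across the two populations: a classical incompatibility
relative_hybrid_fitness(net, "i", "j", dominance_params(alpha1 = 1))
#> [1] 0.5

## both inside one parent: the hybrid escapes it -> heterosis
relative_hybrid_fitness(net, c("i", "j"), character(0),
                        dominance_params(alpha1 = 0))
#> [1] 1.333333

## closed-form trajectory: heterosis for the first four substitutions
analytic_trajectory(eps_w = 0.02, eps_b = 0.01, n_max = 5)
#>   n       w_h
#> 1 0 1.0000000
#> 2 1 1.0018768
#> 3 2 1.0025031
#> 4 3 1.0018768
#> 5 4 1.0000000
#> 6 5 0.9968799
heterosis_window(eps_w = 0.02, eps_b = 0.01)$n_star
#> [1] 4

## synthetic network + stochastic divergence
syn <- generate_synthetic(synthetic_network_spec(n_loci = 200, seed = 1))
sim <- simulate_divergence(syn, simulation_config(
  fixations_per_population = 10, seed = 1, replicate_count = 30))
per_substitution_decline(sim$trajectories)$geometric
#> [1] 0.009297354
introgression_summary(sim, syn, depths = c(2, 10))
#>   depth  fraction
#> 1     2 0.9083333
#> 2    10 0.6966667
```

Reading: on this 200-locus synthetic network, relative hybrid fitness
declines by ~0.9% per substitution, and while 91% of early substitutions
would still be favored in the other population's background, only 70%
are after ten fixations each — hybrid breakdown and adaptive
introgression potential coexist.

A thin command-line wrapper (`inst/cli/epidiverge.R`) exposes the
pipeline as subcommands `fit-network`, `synth-network`, `simulate`,
`summarize` and `analytic`, driven by a YAML configuration; every output
directory carries a manifest (config, seed, input digests) sufficient to
reproduce the run bit-identically.

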