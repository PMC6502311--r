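---
title: "Modeling hybrid fitness evolution on pairwise epistatic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hybrid fitness evolution on pairwise epistatic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidiverge)
```

## The problem

Two populations that diverge in complete isolation accumulate different
substitutions. When they meet again, F1 hybrids combine alleles that were
never tested together by selection. Classical incompatibility models treat
every such new combination as (at best) neutral and focus on the negative
interactions — Dobzhansky–Muller incompatibilities — that accumulate as
divergence proceeds. But empirical crosses often show the opposite early
on: hybrids *fitter* than either parent (heterosis), which later gives way
to postzygotic isolation. `epidiverge` implements a model in which both
phases arise from one mechanism: pairwise epistasis, positive or negative,
between the substitutions carried by the two genomes.

Two classes of interaction matter in an F1:

* **between-population pairs** — combinations first created in the hybrid;
  their mean coefficient is written `eps_b`;
* **within-population pairs** — co-adapted combinations built up inside
  each parent, which the hybrid only experiences at heterozygous strength;
  their mean is `eps_w`. Losing their full benefit is a cost of
  hybridization that most incompatibility models ignore.

## The fitness model

A locus carries an ancestral allele or a derived mutation with independent
selection coefficient $s_i$ and dominance $h_i$. An unordered pair of
mutated loci may carry an epistatic coefficient $\varepsilon_{ij}$ (absent
pairs are exactly 0; the ancestor's interactions define the zero point).
For an individual heterozygous at the loci in $G_1$ and homozygous at
those in $G_2$,

$$W_{G_1,G_2} = \prod_{i\in G_1}(1+h_i s_i)\prod_{i\in G_2}(1+s_i)
 \prod_{\substack{i<j\\ i,j\in G_1}}(1+\alpha_1\varepsilon_{ij})
 \prod_{\substack{i\in G_1, j\in G_2}}(1+\alpha_2\varepsilon_{ij})
 \prod_{\substack{i<j\\ i,j\in G_2}}(1+\varepsilon_{ij}),$$

where $\alpha_1, \alpha_2 \in [0,1]$ are the *epistatic dominance*
parameters scaling an interaction when both or one of its loci are
heterozygous (both homozygous: full strength). Each unordered pair
contributes exactly one factor; `genotype_fitness()` iterates unordered
pairs directly rather than double-counting and taking a square root. Any
factor that would drop below zero is clamped to zero — the genotype is
lethal — since composite coefficients below $-1$ have no fitness
interpretation.

Relative hybrid fitness compares the F1 (heterozygous at every locus fixed
in either population, set $A$ or $B$) with the arithmetic mean of the two
parents:

$$w_H = \frac{W_{A\cup B,\,\varnothing}}
{\tfrac12\left(W_{\varnothing,A}+W_{\varnothing,B}\right)}.$$

$w_H > 1$ is heterosis; $w_H < 1$ is postzygotic isolation.

```{r}
net <- epistasis_network(c("i", "j"), s = c(0, 0),
                         pairs = data.frame(locus_i = "i", locus_j = "j",
                                            epsilon = -0.5))
## the same -0.5 interaction, split across parents vs inside one parent
relative_hybrid_fitness(net, "i", "j", dominance_params(alpha1 = 1))
relative_hybrid_fitness(net, c("i", "j"), character(0),
                        dominance_params(alpha1 = 0))
```

The first case is the classical incompatibility (hybrid breakdown to 0.5);
the second shows heterosis at 4/3 — the hybrid escapes a deleterious
interaction that one parent is stuck with.

## The closed-form trajectory

Under simplifying assumptions — `eps_w` and `eps_b` constant in time,
additive dominance of independent effects ($h = 1/2$), weak effects — the
trajectory of $w_H$ after $n$ total substitutions, a fraction $F$ of them
in population 1, is

$$w_H \simeq \exp\left\{\bar\varepsilon_b\,\alpha_1 v\, n^2
 - \bar\varepsilon_w\left(\tfrac12-\alpha_1\right)
   \left[\left(\tfrac12 - v\right)n^2 - \tfrac n2\right]\right\},
 \qquad v = F(1-F).$$

`analytic_relative_fitness()` evaluates this; `heterosis_window()` finds
the smallest positive $n$ at which $\log w_H$ returns to zero, by
numerical root-finding on the log scale (the log-trajectory is a quadratic
in $n$, so the crossing is unique when it exists).

```{r}
analytic_trajectory(eps_w = 0.02, eps_b = 0.01, v = 0.25, alpha1 = 0.25,
                    n_max = 6)
heterosis_window(eps_w = 0.02, eps_b = 0.01, v = 0.25, alpha1 = 0.25)
```

With both means positive and within-population epistasis the stronger
($0 < \bar\varepsilon_b < \bar\varepsilon_w$), heterosis is transient; at
$v = 1/4,\ \alpha_1 = 1/4$ the crossing sits at
$2\bar\varepsilon_w/(\bar\varepsilon_w - \bar\varepsilon_b)$ — four
substitutions for the parameters above. With
$\bar\varepsilon_b = \bar\varepsilon_w$ and symmetric divergence the
$n^2$ terms cancel exactly and $\log w_H$ is linear in $n$: the quadratic
growth in new hybrid interactions is offset by the quadratic growth in
disrupted co-adapted ones, a "missing snowball". One caveat worth
recording: the bracketed term of the trajectory is typographically
ambiguous in some renderings; the implementation reads it as above, which
is the reading consistent both with the reference crossing at $n = 4$ and
with a first-principles count of pair types, and the heterosis window is
therefore always computed from the trajectory itself rather than from any
pre-printed closed-form threshold.

## Estimating networks from knockout data

`load_interaction_table()` ingests tab-delimited double-knockout fitness
tables (plain or gzipped) in the dialect of genome-scale genetic
interaction screens; the column mapping is configurable and defaults to
the 2016 genome-wide yeast SGA release. `filter_complete()` keeps records
with all three fitnesses present — deliberately with **no** p-value
filtering, since discarding "insignificant" interactions would bias the
estimated distribution against the weak effects that dominate hybrid
fitness in aggregate.

With $W_i$ the single-knockout and $W_{ij}$ the double-knockout relative
fitness, `estimate_effects()` fits $s_i = W_i - 1$ and, under the default
multiplicative measure, $\varepsilon_{ij} = W_{ij}/(W_iW_j) - 1$, so that
$W_{ij} = (1+s_i)(1+s_j)(1+\varepsilon_{ij})$ reconstructs the input
exactly. Two alternative measures are provided for sensitivity analyses:
`additive` ($W_{ij}-W_i-W_j+1$) and `costanzo` ($W_{ij}-W_iW_j$, the
score the screens themselves report, optionally taken verbatim from the
published column). Choices the data do not dictate, made once and exposed
as arguments: strains sharing an allele label can be collapsed by an
`id_fun`, with discordant single-mutant fitnesses averaged (the screens'
replicate structure gives no principled winner; averaging is unbiased
under symmetric measurement error); pairs measured in both orientations
are symmetrized by the arithmetic mean; and pairs whose single-mutant
fitness product is zero are dropped under the multiplicative measure
(undefined ratio) and counted in the returned diagnostics — such loci are
lethal knockouts and can never fix anyway.

## The synthetic generator

`generate_synthetic()` produces networks with the qualitative statistical
structure of genome-scale knockout screens, for use when the (multi-GB)
empirical release is not at hand and as a first-class simulation substrate:

* **independent effects** from a three-component normal mixture — by
  default 15% strongly deleterious ($\mu=-0.35,\ \sigma=0.15$), 75%
  mildly deleterious ($-0.05,\ 0.04$) and 10% mildly beneficial
  ($0.02,\ 0.02$), truncated below at $-1$ — mostly-deleterious with a
  beneficial tail;
* **pairwise epistasis** on a random `pair_density = 0.4` fraction of
  pairs (the empirical screens measure roughly 40% of all pairs), drawn
  about a conditional mean `coupling * (s_i + s_j)` with Laplace
  (heavy-tailed) residuals of sd `epsilon_noise_sd = 0.03` — near-zero
  centred with a slight deleterious skew;
* **coupling** of 0.1 links a mutation's direct effect to its mean
  interaction profile, reproducing the empirical pattern that strongly
  deleterious mutations also interact badly.

These defaults were fixed from the qualitative shape of the empirical
distributions; they are deliberately not calibrated to reproduce any
particular published summary number, and quantitative results on
synthetic networks (heterosis frequencies, decline rates) should be read
as properties of these conditions, not of yeast. The default 1,000 loci
keep the candidate pool large relative to the 100 substitutions of a
default run — as in the empirical network, where ~10,000 loci stand
behind 100 substitutions — so late fixations are not forced into an
exhausted tail. What the generator does *not* emulate: the discrete
replicate structure of real screens, measurement error on single-mutant
fitnesses, correlated interaction blocks (pathways), or higher-order
epistasis. Passing tests on synthetic networks therefore validate the
machinery and the qualitative selection-sieve logic, not yeast-specific
magnitudes.

## Divergence in allopatry

The simulator works in the mutation-limited (origin–fixation) regime: no
polymorphism, one substitution at a time, no gene flow, and no locus may
fix in both populations. A candidate mutation at locus $i$ in a population
already fixed for the set $A$ feels the *effective* coefficients

$$\sigma_{i|A} = (1+s_i)\prod_{j\in A}(1+\varepsilon_{ij}) - 1,\qquad
\omega_{i|A} = \frac{(1+h_i s_i)\prod_{j\in A}(1+\alpha_2\varepsilon_{ij})-1}
{\sigma_{i|A}},$$

(with $\omega = h_i$ when $\sigma = 0$, the continuity limit). Its
fixation probability from initial frequency $p = 1/(2N_e)$ is Kimura's

$$u = \frac{\int_0^{p} G(x)\,dx}{\int_0^1 G(x)\,dx},\qquad
G(x) = e^{-2N_e\sigma x\,[2\omega + (1-2\omega)x]},$$

and the next substitution is drawn with probability proportional to $u$
across available loci. Populations alternate strictly by default
(realizing $v \approx 1/4$); a random scheme with a configurable rate
ratio covers asymmetric divergence. A population in which every candidate
has $u = 0$ aborts the replicate with a `stuck` flag — restarting would
bias summaries toward networks that happen to stay fixable.

Numerical choices. At $\omega = 1/2$ the integral has the exact genic
closed form $(1-e^{-\sigma})/(1-e^{-2N_e\sigma})$, used directly. The
general case is integrated on the log scale: the quadratic exponent is
rescaled by its maximum over $[0,1]$, integration is restricted to the
region where the integrand exceeds $e^{-60}$ of its peak (the neglected
mass is bounded well below the quadrature tolerance), and each window is
covered by panelled Gauss–Legendre rules — the integrand is the
exponential of a quadratic, which this resolves to ~$10^{-10}$ relative
error while vectorizing across all candidate loci at once. The window
boundaries come from the stable form of the quadratic formula; the naive
form loses all precision exactly where it matters most, when $\omega$
lands within rounding error of $1/2$ (as it generically does, being a
ratio of near-identical products). Strong negative selection underflows
cleanly to $u = 0$ at $2N_e|\sigma| \gtrsim 1700$; with $N_e = 10^6$
(the default) even $\sigma = -10^{-3}$ is effectively unfixable, which is
the selective sieve at the heart of the model.

Defaults follow the simulation conditions of the study this model
operationalizes: $N_e = 10^6$, 50 fixations per population, $h = 1/2$,
$\alpha_1 = 1/4$, $\alpha_2 = 1/2$ — all sweepable through
`dominance_params()` and `simulation_config()`. One global seed derives a
deterministic per-replicate stream (keyed by replicate index), so raising
`replicate_count` never perturbs earlier replicates.

```{r}
net <- generate_synthetic(synthetic_network_spec(n_loci = 200, seed = 1))
sim <- simulate_divergence(net, simulation_config(
  fixations_per_population = 10, seed = 1, replicate_count = 30))
head(sim$trajectories[sim$trajectories$replicate == 1, ], 4)
```

## Summaries

`epistasis_components()` averages $\varepsilon$ over all within- and
between-population pairs of fixed loci (absent pairs count as zero);
`heterosis_frequency()`, `per_substitution_decline()` and
`large_effect_fraction()` summarize replicate trajectories;
`introgression_fraction()` asks, for each substitution, whether it would
be positively selected in the *other* population's background — the
signature of adaptive introgression surviving overall hybrid breakdown;
`band()` computes cross-replicate percentile envelopes (the 95% band is
the 2.5th/97.5th percentile across replicates, chosen over a standard
error because published trajectory bands contain individual replicates).
Two readings of "per-substitution decline" are both reported: the
geometric rate $1-(w_H(n)/w_H(0))^{1/n}$ and the arithmetic mean of
per-step proportional changes; heterosis uses strict inequality
$w_H > 1$.

```{r}
heterosis_frequency(sim$trajectories, 10)
per_substitution_decline(sim$trajectories)
introgression_summary(sim, net, depths = c(2, 10))
```

## What the simulations show under the default conditions

On default synthetic networks the characteristic qualitative results
reproduce: the within-population mean epistasis among fixed pairs is
sieved upward — above both the network-wide mean and the
between-population mean, which stays close to a random draw; making
epistasis nearly recessive during fixation ($\alpha_2 = 0.01$) removes
the sieve, the two components converge, and mean log hybrid fitness
declines approximately linearly; and a substantial fraction of each
population's substitutions remains positively selected in the other
background even late in divergence, declining with depth. Each of these
is computed, not asserted, by the test suite and by
`scripts/acceptance.R` (see the README for how to re-run it).

## Scale and limitations

Default problem sizes were chosen to make the full pipeline comfortably
reproducible on a single core: 1,000-locus networks, 300 replicates of
2×50 substitutions in the acceptance script, 500 replicates of 2×20 in
the heaviest test. Quantities defined against the *empirical* yeast
release — the 18.7M-interaction count after completeness filtering, the
0.103 adjusted R² of the effect-correlation regression, and the
percentage-level heterosis/decline figures — require downloading that
release (several GB, thecellmap.org) and placing its tables under
`data-raw/costanzo2016/`; the corresponding test is red without it.
Beyond data availability, the model itself excludes: three-way and
higher-order epistasis, F2/backcross generations and recombination, sex
chromosomes and cytoplasmic factors, gene flow during divergence, and
standing polymorphism.
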