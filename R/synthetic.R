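#' Specification for a synthetic epistasis network
#'
#' Defines the statistical structure of a generated network: independent
#' selection coefficients drawn from a finite normal mixture (mostly
#' deleterious, with a lethal-leaning tail and a small beneficial
#' component, the qualitative shape of genome-wide knockout effects), and
#' pairwise epistatic coefficients that are near-zero-centred and
#' heavy-tailed, with a conditional mean coupled to the interacting loci's
#' independent effects. A positive `coupling` reproduces the empirical
#' pattern that individually deleterious mutations also tend to have
#' deleterious interactions.
#'
#' @param n_loci number of loci (>= 2).
#' @param s_mixture list with numeric vectors `weights` (summing to 1),
#'   `means` and `sds` of the mixture components for `s`. The default has
#'   three components: strongly deleterious, mildly deleterious and mildly
#'   beneficial.
#' @param coupling slope linking the conditional mean of `epsilon_ij` to
#'   `s_i + s_j` (dimensionless).
#' @param epsilon_noise_sd residual standard deviation of `epsilon` about
#'   its conditional mean.
#' @param pair_density fraction of locus pairs with a stored (nonzero)
#'   interaction, in \[0, 1\].
#' @param epsilon_family residual distribution: `"laplace"` (default,
#'   heavy-tailed) or `"gaussian"`.
#' @param seed integer seed; identical specs generate identical networks.
#' @return object of class `synthetic_network_spec`.
#' @export
synthetic_network_spec <- function(n_loci = 1000,
                                   s_mixture = list(
                                     weights = c(0.15, 0.75, 0.10),
                                     means = c(-0.35, -0.05, 0.02),
                                     sds = c(0.15, 0.04, 0.02)),
                                   coupling = 0.1,
                                   epsilon_noise_sd = 0.03,
                                   pair_density = 0.4,
                                   epsilon_family = c("laplace", "gaussian"),
                                   seed = 1L) {
  epsilon_family <- match.arg(epsilon_family)
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 2L) stop("n_loci must be >= 2")
  w <- s_mixture$weights; m <- s_mixture$means; sd <- s_mixture$sds
  if (length(w) < 1L || length(w) != length(m) || length(w) != length(sd))
    stop("s_mixture components weights/means/sds must have equal length")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(w < 0) || any(sd < 0)) stop("mixture weights and sds must be nonnegative")
  if (!is.finite(pair_density) || pair_density < 0 || pair_density > 1)
    stop("pair_density must be in [0, 1]")
  if (!is.finite(epsilon_noise_sd) || epsilon_noise_sd < 0)
    stop("epsilon_noise_sd must be nonnegative")
  if (!is.finite(coupling)) stop("coupling must be finite")
  structure(list(n_loci = n_loci, s_mixture = s_mixture, coupling = coupling,
                 epsilon_noise_sd = epsilon_noise_sd,
                 pair_density = pair_density,
                 epsilon_family = epsilon_family,
                 seed = as.integer(seed)),
            class = "synthetic_network_spec")
}

## Decode linear upper-triangle pair index k (1..n(n-1)/2, pairs ordered
## (1,2),(1,3),(2,3),(1,4),...) into (i, j) with i < j.
decode_pair_index <- function(k) {
  j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  ## guard against floating-point edge error
  j <- j - (k <= (j - 1) * (j - 2) / 2)
  j <- j + (k > j * (j - 1) / 2)
  i <- k - (j - 1) * (j - 2) / 2
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Generate a synthetic epistasis network
#'
#' Draws independent selection coefficients from the spec's mixture and,
#' for a random `pair_density` fraction of locus pairs, an epistatic
#' coefficient with mean `coupling * (s_i + s_j)` and scale
#' `epsilon_noise_sd`. Both `s` and `epsilon` are truncated below at -1
#' (a fitness factor cannot be negative). The generator is fully
#' deterministic given the spec (including its seed) and does not disturb
#' the caller's RNG state.
#'
#' @param spec a [synthetic_network_spec()].
#' @return an `epistasis_network` (multiplicative measure) with attribute
#'   `"spec"`.
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_network_spec"))
    stop("spec must be a synthetic_network_spec")
  n <- spec$n_loci
  withr::with_seed(spec$seed, {
    comp <- sample.int(length(spec$s_mixture$weights), n, replace = TRUE,
                       prob = spec$s_mixture$weights)
    s <- stats::rnorm(n, spec$s_mixture$means[comp], spec$s_mixture$sds[comp])
    s <- pmax(s, -1)

    total <- n * (n - 1) / 2
    m <- round(spec$pair_density * total)
    if (m > 0) {
      ks <- if (m == total) seq_len(total) else sort(sample(total, m))
      ij <- decode_pair_index(ks)
      mu <- spec$coupling * (s[ij[, "i"]] + s[ij[, "j"]])
      noise <- if (spec$epsilon_family == "gaussian") {
        stats::rnorm(m, 0, spec$epsilon_noise_sd)
      } else {
        b <- spec$epsilon_noise_sd / sqrt(2)
        b * stats::rexp(m) * sample(c(-1, 1), m, replace = TRUE)
      }
      eps <- pmax(mu + noise, -1)
      pairs <- data.frame(i = ij[, "i"], j = ij[, "j"], epsilon = eps)
    } else {
      pairs <- NULL
    }
    net <- epistasis_network(sprintf("L%04d", seq_len(n)), s, h = 0.5,
                             pairs = pairs, measure = "multiplicative")
  })
  attr(net, "spec") <- spec
  net
}
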