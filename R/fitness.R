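#' Dominance parameters for independent and epistatic effects
#'
#' `h_default` scales a mutation's independent effect when heterozygous.
#' Epistatic dominance scales a pairwise interaction by the zygosity of the
#' interacting loci: `alpha1` applies between two heterozygous loci,
#' `alpha2` between a heterozygous and a homozygous locus, and an
#' interaction between two homozygous loci always has full strength.
#'
#' @param h_default dominance of independent effects (default 1/2:
#'   additive, no dominance).
#' @param alpha1 epistatic dominance for het x het pairs, in \[0, 1\]
#'   (default 1/4: additive epistasis).
#' @param alpha2 epistatic dominance for het x hom pairs, in \[0, 1\]
#'   (default 1/2: additive epistasis).
#' @return object of class `dominance_params`.
#' @export
dominance_params <- function(h_default = 0.5, alpha1 = 0.25, alpha2 = 0.5) {
  if (!is.finite(alpha1) || alpha1 < 0 || alpha1 > 1)
    stop("alpha1 must be in [0, 1]")
  if (!is.finite(alpha2) || alpha2 < 0 || alpha2 > 1)
    stop("alpha2 must be in [0, 1]")
  if (!is.finite(h_default)) stop("h_default must be finite")
  structure(list(h_default = h_default, alpha1 = alpha1, alpha2 = alpha2),
            class = "dominance_params")
}

## Multiply a vector of fitness factors with clamping: any factor that
## falls below 0 is clamped to 0, making the genotype lethal.
prod_clamped <- function(factors) {
  if (any(factors <= 0)) return(0)
  prod(factors)
}

#' Diploid multiplicative fitness of a genotype with epistatic dominance
#'
#' The absolute fitness of an individual heterozygous for derived mutations
#' at the loci in `het` and homozygous at the loci in `hom` is the product
#' of `(1 + h_i s_i)` over heterozygous loci, `(1 + s_i)` over homozygous
#' loci, and one epistatic factor per unordered pair of mutated loci:
#' `(1 + alpha1 * eps_ij)` for het x het pairs, `(1 + alpha2 * eps_ij)` for
#' het x hom pairs and `(1 + eps_ij)` for hom x hom pairs. The ancestor
#' (empty genotype) has fitness 1. Any individual factor below 0 is clamped
#' to 0, so such genotypes are lethal.
#'
#' @param network an `epistasis_network`.
#' @param het,hom locus labels (or indices) heterozygous / homozygous for
#'   the derived allele; must be disjoint.
#' @param dom a [dominance_params()] object.
#' @return absolute fitness (nonnegative scalar).
#' @export
genotype_fitness <- function(network, het = character(0), hom = character(0),
                             dom = dominance_params()) {
  ih <- locus_index(network, het)
  io <- locus_index(network, hom)
  if (length(intersect(ih, io)))
    stop("a locus cannot be both heterozygous and homozygous")
  factors <- c(1 + network$h[ih] * network$s[ih],
               1 + network$s[io],
               1 + dom$alpha1 * pair_values_within(network, ih),
               1 + dom$alpha2 * pair_values_between(network, ih, io),
               1 + pair_values_within(network, io))
  prod_clamped(factors)
}

#' Relative F1 hybrid fitness
#'
#' An F1 between a population fixed for the mutations in `fixed_a` and one
#' fixed for those in `fixed_b` is heterozygous at every mutated locus.
#' Its absolute fitness is divided by the arithmetic mean of the two
#' parental absolute fitnesses (each parent homozygous for its own fixed
#' set). Values above 1 indicate heterosis; below 1, postzygotic
#' isolation.
#'
#' @param network an `epistasis_network`.
#' @param fixed_a,fixed_b disjoint sets of locus labels (or indices) fixed
#'   in the two populations.
#' @param dom a [dominance_params()] object.
#' @return relative hybrid fitness `w_H` (nonnegative scalar).
#' @export
relative_hybrid_fitness <- function(network, fixed_a, fixed_b,
                                    dom = dominance_params()) {
  ia <- locus_index(network, fixed_a)
  ib <- locus_index(network, fixed_b)
  if (length(intersect(ia, ib)))
    stop("fixed_a and fixed_b must be disjoint")
  hybrid <- genotype_fitness(network, het = c(ia, ib), dom = dom)
  parent_mean <- (genotype_fitness(network, hom = ia, dom = dom) +
                    genotype_fitness(network, hom = ib, dom = dom)) / 2
  if (parent_mean == 0)
    stop("both parental genotypes are lethal; relative hybrid fitness undefined")
  hybrid / parent_mean
}

#' Background-dependent effective selection coefficient and dominance
#'
#' A new mutation at locus i arising in a population already fixed for the
#' mutations in `background` experiences the effective selection
#' coefficient `sigma = (1 + s_i) * prod_j (1 + eps_ij) - 1` (product over
#' the background, factors clamped at 0) and effective dominance
#' `omega = [(1 + h_i s_i) * prod_j (1 + alpha2 * eps_ij) - 1] / sigma`.
#' With an empty background, `sigma = s_i` and `omega = h_i`; when
#' `sigma = 0`, `omega` is set to `h_i` (continuity convention).
#'
#' @param network an `epistasis_network`.
#' @param locus single locus label (or index), not in `background`.
#' @param background locus labels (or indices) already fixed.
#' @param dom a [dominance_params()] object.
#' @return list with elements `sigma` and `omega`, class
#'   `effective_coefficients`.
#' @export
effective_selection <- function(network, locus, background = character(0),
                                dom = dominance_params()) {
  i <- locus_index(network, locus)
  if (length(i) != 1L) stop("locus must be a single locus")
  bg <- locus_index(network, background)
  if (i %in% bg) stop("locus must not be part of its own background")
  if (length(bg) == 0L) {
    ## no epistatic modification: exactly the raw coefficients
    return(structure(list(sigma = network$s[i], omega = network$h[i]),
                     class = "effective_coefficients"))
  }
  eps <- as.numeric(network$emat[i, bg])
  sigma <- prod_clamped(c(1 + network$s[i], 1 + eps)) - 1
  if (sigma == 0) {
    omega <- network$h[i]
  } else {
    num <- prod_clamped(c(1 + network$h[i] * network$s[i],
                          1 + dom$alpha2 * eps)) - 1
    omega <- num / sigma
  }
  structure(list(sigma = sigma, omega = omega),
            class = "effective_coefficients")
}

## Vectorized effective coefficients for all `cand` loci against a common
## background, exploiting sparsity: implicit epsilon entries contribute a
## factor of exactly 1.
effective_all <- function(network, cand, bg, dom) {
  s <- network$s[cand]
  h <- network$h[cand]
  if (length(bg) == 0L) {
    sigma <- s
    omega <- h
    return(list(sigma = sigma, omega = omega))
  }
  B <- network$emat[cand, bg, drop = FALSE]
  B <- methods::as(methods::as(B, "generalMatrix"), "TsparseMatrix")
  rows <- B@i + 1L
  x <- B@x
  rowprod <- function(f) {
    out <- rep(1, length(cand))
    fx <- f(x)
    pos <- fx > 0
    if (any(pos)) {
      lg <- rowsum(log(fx[pos]), rows[pos])
      at <- as.integer(rownames(lg))
      out[at] <- exp(lg[, 1L])
    }
    if (any(!pos)) out[unique(rows[!pos])] <- 0
    out
  }
  ps <- rowprod(function(e) pmax(1 + e, 0))
  pq <- rowprod(function(e) pmax(1 + dom$alpha2 * e, 0))
  sigma <- pmax(1 + s, 0) * ps - 1
  num <- pmax(1 + h * s, 0) * pq - 1
  omega <- ifelse(sigma == 0, h, num / sigma)
  list(sigma = sigma, omega = omega)
}
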