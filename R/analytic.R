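#' Divergence symmetry parameter
#'
#' With a fraction `F` of all substitutions occurring in the first
#' population, `v = F (1 - F)` measures how evenly divergence is split:
#' `v = 1/4` when the two populations substitute at equal rates, `v = 0`
#' when only one population evolves.
#'
#' @param F fraction of substitutions in population 1, in \[0, 1\].
#' @return `v = F (1 - F)`, in \[0, 1/4\]. Vectorized.
#' @export
symmetry_v <- function(F) {
  if (any(!is.finite(F)) || any(F < 0 | F > 1))
    stop("F must be in [0, 1]")
  F * (1 - F)
}

#' Closed-form trajectory of relative hybrid fitness
#'
#' Under the diffusion-era approximations (mean within-population epistasis
#' `eps_w` and between-population epistasis `eps_b` constant in time,
#' additive dominance of independent effects, weak effects), the relative
#' F1 hybrid fitness after a total of `n` substitutions is
#' \deqn{w_H = \exp\{\bar\varepsilon_b \alpha_1 v n^2 -
#'   \bar\varepsilon_w (1/2 - \alpha_1)[(1/2 - v) n^2 - n/2]\}.}
#' The first term collects the interactions first created in hybrids; the
#' second, the within-population interactions disrupted in hybrids. With
#' `alpha1 = 0` or `v = 0` the between-population term vanishes entirely.
#'
#' @param n total number of substitutions across both populations
#'   (nonnegative; treated as real). Vectorized.
#' @param eps_w mean within-population epistatic coefficient.
#' @param eps_b mean between-population epistatic coefficient.
#' @param v divergence symmetry parameter in \[0, 1/4\]; see
#'   [symmetry_v()].
#' @param alpha1 epistatic dominance between heterozygous loci, in
#'   \[0, 1\].
#' @return relative hybrid fitness `w_H` (positive), same length as `n`.
#' @export
analytic_relative_fitness <- function(n, eps_w, eps_b, v = 0.25, alpha1 = 0.25) {
  if (any(n < 0)) stop("n must be nonnegative")
  if (!is.finite(v) || v < 0 || v > 0.25) stop("v must be in [0, 1/4]")
  if (!is.finite(alpha1) || alpha1 < 0 || alpha1 > 1)
    stop("alpha1 must be in [0, 1]")
  exp(analytic_log_fitness(n, eps_w, eps_b, v, alpha1))
}

analytic_log_fitness <- function(n, eps_w, eps_b, v, alpha1) {
  eps_b * alpha1 * v * n^2 -
    eps_w * (0.5 - alpha1) * ((0.5 - v) * n^2 - n / 2)
}

#' Heterosis window: where hybrid advantage ends
#'
#' Finds the smallest `n > 0` at which the log of
#' [analytic_relative_fitness()] returns to 0, i.e. where transient
#' heterosis (or transient breakdown) gives way to the opposite regime.
#' The root is located numerically on the trajectory's log scale. When the
#' log-fitness never changes sign for `n > 0` (for example when
#' `0 < eps_w <= eps_b` at `v = 1/4`, `alpha1 = 1/4`, so hybrid advantage
#' persists indefinitely), no finite crossing is reported.
#'
#' @inheritParams analytic_relative_fitness
#' @param n_max upper bound for the root search (default `1e6`
#'   substitutions).
#' @return list with `n_star` (the crossing, `NA` if none) and `crossing`
#'   (logical).
#' @export
heterosis_window <- function(eps_w, eps_b, v = 0.25, alpha1 = 0.25,
                             n_max = 1e6) {
  ## log w_H = n * g(n); the nontrivial crossing is the root of g.
  analytic_relative_fitness(1, eps_w, eps_b, v, alpha1)  # validate arguments
  g <- function(n) analytic_log_fitness(n, eps_w, eps_b, v, alpha1) / n
  n_lo <- 1e-8
  g_lo <- g(n_lo)
  g_hi <- g(n_max)
  if (!is.finite(g_lo) || !is.finite(g_hi) ||
      g_lo == 0 || sign(g_lo) == sign(g_hi))
    return(list(n_star = NA_real_, crossing = FALSE))
  root <- stats::uniroot(g, c(n_lo, n_max), tol = 1e-12)
  list(n_star = root$root, crossing = TRUE)
}

#' Tabulate the analytic hybrid-fitness trajectory
#'
#' @inheritParams analytic_relative_fitness
#' @param n_max largest substitution count to tabulate.
#' @param by step between tabulated `n` values (default 1, the integer
#'   interpretation of substitution counts).
#' @return data frame with columns `n` and `w_h`.
#' @export
analytic_trajectory <- function(eps_w, eps_b, v = 0.25, alpha1 = 0.25,
                                n_max = 50, by = 1) {
  n <- seq(0, n_max, by = by)
  data.frame(n = n,
             w_h = analytic_relative_fitness(n, eps_w, eps_b, v, alpha1))
}
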