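#' Kimura diffusion fixation probability of a new mutation
#'
#' Probability that a mutation present as a single copy (initial frequency
#' `p = 1/(2 N_e)`) ultimately fixes, given its selection coefficient
#' `sigma` and dominance `omega`, from the diffusion approximation:
#' \deqn{u = \int_0^p G(x)\,dx \Big/ \int_0^1 G(x)\,dx, \qquad
#'   G(x) = \exp\{-2 N_e \sigma x [2\omega + (1 - 2\omega) x]\}.}
#' Special cases: `sigma = 0` returns exactly `p`; at `omega = 1/2`
#' (genic selection) the closed form
#' `(1 - exp(-sigma)) / (1 - exp(-2 N_e sigma))` is used; `sigma <= -1`
#' (lethal) returns 0. The general case is integrated in log space: the
#' quadratic exponent is rescaled by its maximum and integration is
#' restricted to the region where the integrand is non-negligible, so that
#' strong selection (`|2 N_e sigma|` of order `1e6`) underflows cleanly to
#' 0 instead of overflowing. Within that window the integrand is the
#' exponential of a quadratic, which panelled Gauss-Legendre quadrature
#' resolves to near machine precision; the whole computation is vectorized
#' over loci.
#'
#' @param sigma selection coefficient(s) of the homozygote (`>= -1`;
#'   smaller values are treated as lethal).
#' @param omega dominance coefficient(s); recycled against `sigma`.
#' @param effective_size effective population size `N_e` (default `1e6`).
#' @param method `"auto"` (closed form where exact, quadrature otherwise),
#'   `"quadrature"` (force numerical integration; useful for
#'   cross-checking against the closed form) or `"closed"` (force the
#'   `omega = 1/2` closed form).
#' @return fixation probabilities in \[0, 1\], same length as the longer
#'   of `sigma`/`omega`.
#' @export
fixation_probability <- function(sigma, omega = 0.5, effective_size = 1e6,
                                 method = c("auto", "quadrature", "closed")) {
  method <- match.arg(method)
  if (effective_size < 2) stop("effective_size must be >= 2")
  m <- max(length(sigma), length(omega))
  sigma <- rep_len(as.numeric(sigma), m)
  omega <- rep_len(as.numeric(omega), m)
  N <- effective_size
  p <- 1 / (2 * N)

  u <- numeric(m)
  u[sigma <= -1] <- 0
  u[sigma == 0] <- p
  todo <- which(sigma > -1 & sigma != 0 & !is.na(sigma))

  if (method == "closed") {
    u[todo] <- genic_closed_form(sigma[todo], N)
    return(clamp01(u, is.na(sigma)))
  }
  if (method == "auto") {
    cf <- todo[omega[todo] == 0.5]
    u[cf] <- genic_closed_form(sigma[cf], N)
    todo <- setdiff(todo, cf)
  }
  if (length(todo))
    u[todo] <- kimura_quadrature(sigma[todo], omega[todo], N)
  clamp01(u, is.na(sigma))
}

clamp01 <- function(u, na) {
  u <- pmin(pmax(u, 0), 1)
  u[na] <- NA_real_
  u
}

## u = (1 - e^{-sigma}) / (1 - e^{-2 N sigma}); stable via expm1, with the
## deleterious branch underflowing to 0 through the Inf denominator.
genic_closed_form <- function(sigma, N) {
  num <- -expm1(-sigma)
  den <- -expm1(-2 * N * sigma)
  out <- num / den
  bad <- is.nan(out)
  if (any(bad)) {
    s <- sigma[bad]
    out[bad] <- exp(log(abs(num[bad])) + 2 * N * s)
  }
  out
}

## Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch), cached.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  res <- list(x = (e$values[ord] + 1) / 2, w = e$vectors[1L, ord]^2)
  .gl_cache[[key]] <- res
  res
}

## Vectorized general-dominance quadrature. The exponent
## phi(x) = c2 x^2 + c1 x with a = 2 N sigma, c1 = -2 a omega,
## c2 = -a (1 - 2 omega).
kimura_quadrature <- function(sigma, omega, N, drop = 60, n_nodes = 25,
                              n_panels = 4) {
  m <- length(sigma)
  a <- 2 * N * sigma
  p <- 1 / (2 * N)
  c1 <- -2 * a * omega
  c2 <- -a * (1 - 2 * omega)
  gl <- gauss_legendre01(n_nodes)

  ## numerator over [0, p]: exponent there is O(sigma), never extreme
  xn <- matrix(p * gl$x, n_nodes, m)        # nodes x loci
  phin <- (xn * rep(c2, each = n_nodes) + rep(c1, each = n_nodes)) * xn
  log_num <- log(p * colSums(gl$w * exp(phin)))

  ## maximum of phi over [0, 1]
  M <- pmax(0, c2 + c1)                      # phi(0) = 0, phi(1) = c2 + c1
  xv <- ifelse(c2 != 0, -c1 / (2 * c2), NA_real_)
  int <- !is.na(xv) & xv > 0 & xv < 1
  M[int] <- pmax(M[int], (c2[int] * xv[int] + c1[int]) * xv[int])

  ## windows of [0, 1] where phi >= M - drop; a downward parabola gives
  ## one window, an upward one up to two (near each endpoint)
  thr <- M - drop
  lo1 <- numeric(m); hi1 <- rep(1, m)
  lo2 <- rep(NA_real_, m); hi2 <- rep(NA_real_, m)
  quad <- which(c2 != 0)
  disc <- c1[quad]^2 + 4 * c2[quad] * thr[quad]
  real <- disc > 0
  qi <- quad[real]
  ## stable quadratic roots (avoids cancellation when |c2| << |c1|,
  ## which arises whenever omega is within rounding of 1/2)
  sgn <- ifelse(c1[qi] >= 0, 1, -1)
  qq <- -(c1[qi] + sgn * sqrt(disc[real])) / 2
  r1 <- qq / c2[qi]
  r2 <- -thr[qi] / qq
  rlo <- pmin(r1, r2); rhi <- pmax(r1, r2)
  down <- c2[qi] < 0
  di <- qi[down]
  lo1[di] <- pmax(0, rlo[down]); hi1[di] <- pmin(1, rhi[down])
  ui <- qi[!down]
  lo1[ui] <- 0; hi1[ui] <- pmin(1, pmax(0, rlo[!down]))
  lo2[ui] <- pmax(0, pmin(1, rhi[!down])); hi2[ui] <- 1
  lin <- which(c2 == 0 & c1 != 0)
  r <- thr[lin] / c1[lin]
  pos <- c1[lin] > 0
  lo1[lin[pos]] <- pmax(0, pmin(1, r[pos]))
  hi1[lin[!pos]] <- pmax(0, pmin(1, r[!pos]))

  ## panelled Gauss-Legendre on each window, rescaled by M
  panel_sum <- function(lo, hi, keep) {
    total <- numeric(m)
    idx <- which(keep & hi > lo)
    if (!length(idx)) return(total)
    width <- (hi[idx] - lo[idx]) / n_panels
    acc <- numeric(length(idx))
    rc2 <- rep(c2[idx], each = n_nodes)
    rc1 <- rep(c1[idx], each = n_nodes)
    rM <- rep(M[idx], each = n_nodes)
    rw <- rep(width, each = n_nodes)
    for (panel in seq_len(n_panels) - 1L) {
      x <- gl$x * rw + rep(lo[idx] + panel * width, each = n_nodes)
      dim(x) <- c(n_nodes, length(idx))
      phi <- (x * rc2 + rc1) * x - rM
      acc <- acc + colSums(gl$w * exp(phi))
    }
    total[idx] <- acc * width
    total
  }
  den <- panel_sum(lo1, hi1, rep(TRUE, m)) + panel_sum(lo2, hi2, !is.na(lo2))
  log_den <- M + log(den)
  lo_u <- log_num - log_den
  ifelse(lo_u < -745, 0, exp(lo_u))
}
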