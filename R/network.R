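#' Construct a pairwise epistatic fitness network
#'
#' An `epistasis_network` holds, for a set of loci, the independent selection
#' coefficient `s` and dominance `h` of the derived (mutant) allele at each
#' locus, together with a sparse symmetric map of pairwise epistatic
#' coefficients `epsilon`. A pair absent from the map has epistatic
#' coefficient exactly 0, consistent with defining all interactions in the
#' common ancestor to be zero.
#'
#' @param locus_ids character vector of unique locus labels.
#' @param s numeric vector of independent selection coefficients, one per
#'   locus (dimensionless; `s = -1` is a lethal knockout, wild type has
#'   fitness 1). Must be `>= -1`.
#' @param h numeric vector (or scalar, recycled) of dominance coefficients
#'   for the independent effects; default 1/2 (no dominance).
#' @param pairs data frame of stored epistatic interactions with columns
#'   `locus_i`, `locus_j` (labels) and `epsilon`. Each unordered pair may
#'   appear at most once; self-pairs are not allowed. `NULL` means no
#'   stored interactions.
#' @param measure epistasis measure the coefficients were estimated under:
#'   `"multiplicative"`, `"additive"` or `"costanzo"`.
#'
#' @return An object of class `epistasis_network` with elements
#'   `locus_ids`, `s`, `h`, `pairs` (integer-indexed, `i < j`), `measure`
#'   and `emat`, a symmetric sparse [Matrix::sparseMatrix()] used for fast
#'   pair lookups.
#' @export
epistasis_network <- function(locus_ids, s, h = 0.5, pairs = NULL,
                              measure = c("multiplicative", "additive", "costanzo")) {
  measure <- match.arg(measure)
  locus_ids <- as.character(locus_ids)
  n <- length(locus_ids)
  if (n < 1L) stop("network needs at least one locus")
  if (anyDuplicated(locus_ids)) stop("locus_ids must be unique")
  s <- as.numeric(s)
  if (length(s) != n) stop("length of s must equal length of locus_ids")
  if (anyNA(s)) stop("s must not contain NA")
  if (any(s < -1)) stop("independent selection coefficients must be >= -1")
  if (length(h) == 1L) h <- rep(as.numeric(h), n)
  h <- as.numeric(h)
  if (length(h) != n) stop("length of h must equal length of locus_ids")

  if (is.null(pairs) || nrow(pairs) == 0L) {
    pdf <- data.frame(i = integer(0), j = integer(0), epsilon = numeric(0))
  } else {
    pairs <- as.data.frame(pairs)
    if (all(c("locus_i", "locus_j") %in% names(pairs))) {
      i <- match(as.character(pairs$locus_i), locus_ids)
      j <- match(as.character(pairs$locus_j), locus_ids)
      if (anyNA(i) || anyNA(j)) stop("pair table refers to unknown loci")
    } else if (all(c("i", "j") %in% names(pairs))) {
      i <- as.integer(pairs$i)
      j <- as.integer(pairs$j)
      if (any(i < 1L | i > n | j < 1L | j > n)) stop("pair indices out of range")
    } else {
      stop("pairs must have columns locus_i/locus_j or i/j")
    }
    eps <- as.numeric(pairs$epsilon)
    if (anyNA(eps)) stop("epsilon must not contain NA")
    if (any(eps < -1)) stop("epistatic coefficients must be >= -1")
    if (any(i == j)) stop("self-pairs are not allowed")
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * n + hi
    if (anyDuplicated(key)) stop("each unordered locus pair may be stored only once")
    ord <- order(lo, hi)
    pdf <- data.frame(i = lo[ord], j = hi[ord], epsilon = eps[ord])
  }

  emat <- Matrix::sparseMatrix(i = pdf$i, j = pdf$j, x = pdf$epsilon,
                               dims = c(n, n), symmetric = TRUE)
  structure(list(locus_ids = locus_ids, s = s, h = h, pairs = pdf,
                 measure = measure, emat = emat),
            class = "epistasis_network")
}

#' @export
print.epistasis_network <- function(x, ...) {
  cat("Epistatic fitness network (", x$measure, " measure)\n", sep = "")
  cat("  loci:  ", length(x$locus_ids), "\n", sep = "")
  cat("  pairs: ", nrow(x$pairs), " stored (absent pairs have epsilon = 0)\n", sep = "")
  cat("  s:     mean ", signif(mean(x$s), 4), ", range [",
      signif(min(x$s), 4), ", ", signif(max(x$s), 4), "]\n", sep = "")
  if (nrow(x$pairs) > 0L)
    cat("  eps:   mean ", signif(mean(x$pairs$epsilon), 4), ", range [",
        signif(min(x$pairs$epsilon), 4), ", ", signif(max(x$pairs$epsilon), 4),
        "]\n", sep = "")
  invisible(x)
}

#' Number of loci in a network
#' @param network an `epistasis_network`.
#' @return integer count of loci.
#' @export
n_loci <- function(network) length(network$locus_ids)

## Map locus labels (or indices) to integer indices, failing on unknowns.
locus_index <- function(network, loci) {
  if (length(loci) == 0L) return(integer(0))
  if (is.numeric(loci)) {
    idx <- as.integer(loci)
    if (any(idx < 1L | idx > n_loci(network)))
      stop("unknown locus index")
    return(idx)
  }
  idx <- match(as.character(loci), network$locus_ids)
  if (anyNA(idx))
    stop("unknown locus: ", paste(loci[is.na(idx)], collapse = ", "))
  idx
}

#' Look up the epistatic coefficient of a locus pair
#'
#' Symmetric lookup: `epsilon_of(net, i, j)` equals `epsilon_of(net, j, i)`.
#' Pairs that are not stored return exactly 0.
#'
#' @param network an `epistasis_network`.
#' @param i,j locus labels (or integer indices); vectors are paired
#'   elementwise.
#' @return numeric vector of epistatic coefficients.
#' @export
epsilon_of <- function(network, i, j) {
  ii <- locus_index(network, i)
  jj <- locus_index(network, j)
  if (any(ii == jj)) stop("self-pairs have no epistatic coefficient")
  as.numeric(network$emat[cbind(ii, jj)])
}

## Stored epsilon values among unordered pairs within one index set,
## each pair contributing once. Implicit (absent) pairs are not returned.
pair_values_within <- function(network, idx) {
  if (length(idx) < 2L) return(numeric(0))
  E <- network$emat[idx, idx, drop = FALSE]
  E <- methods::as(methods::as(E, "generalMatrix"), "TsparseMatrix")
  keep <- E@i < E@j
  E@x[keep]
}

## Stored epsilon values between two disjoint index sets, each ordered
## pair (a in A, b in B) counted once.
pair_values_between <- function(network, idx_a, idx_b) {
  if (length(idx_a) == 0L || length(idx_b) == 0L) return(numeric(0))
  E <- network$emat[idx_a, idx_b, drop = FALSE]
  E <- methods::as(methods::as(E, "generalMatrix"), "TsparseMatrix")
  E@x
}

#' Per-locus mean epistatic interaction profile
#'
#' For every locus, the arithmetic mean of all *stored* epistatic
#' coefficients involving that locus. Loci with no stored pairs report a
#' mean of 0 and are flagged.
#'
#' @param network an `epistasis_network` with at least one locus.
#' @return data frame with columns `locus_id`, `mean_epsilon`, `n_pairs`
#'   and `no_pairs` (logical flag).
#' @export
mean_interaction_profile <- function(network) {
  n <- n_loci(network)
  if (n == 0L) stop("network is empty")
  p <- network$pairs
  sums <- numeric(n)
  cnts <- integer(n)
  if (nrow(p) > 0L) {
    at <- c(p$i, p$j)
    v <- c(p$epsilon, p$epsilon)
    agg <- rowsum(v, at)
    where <- as.integer(rownames(agg))
    sums[where] <- agg[, 1L]
    cnts <- tabulate(at, nbins = n)
  }
  mean_eps <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), 0)
  data.frame(locus_id = network$locus_ids, mean_epsilon = mean_eps,
             n_pairs = cnts, no_pairs = cnts == 0L)
}

#' Regression of mean epistatic profile on independent effect
#'
#' Ordinary least-squares fit of the per-locus mean interaction profile on
#' the independent selection coefficient `s`, over loci that have at least
#' one stored pair. Quantifies the coupling between a mutation's direct
#' fitness effect and its average epistatic effect.
#'
#' @param network an `epistasis_network`.
#' @return list with `slope`, `intercept` and `adjusted_R2` (the
#'   single-predictor adjusted coefficient of determination).
#' @export
effect_correlation <- function(network) {
  prof <- mean_interaction_profile(network)
  use <- !prof$no_pairs
  if (sum(use) < 3L)
    stop("need at least 3 loci with stored interactions to fit the regression")
  fit <- stats::lm(prof$mean_epsilon[use] ~ network$s[use])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adjusted_R2 = sm$adj.r.squared)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Serialize a network to tab-delimited tables
#'
#' Writes a locus table (`<prefix>_loci.tsv`: `locus_id`, `s`, `h`), a pair
#' table (`<prefix>_pairs.tsv`: `locus_i`, `locus_j`, `epsilon`) and a
#' metadata sidecar (`<prefix>_meta.yaml` carrying the measure and
#' provenance). Numeric columns are written with 17 significant digits so
#' that [read_network()] round-trips bit-identically.
#'
#' @param network an `epistasis_network`.
#' @param prefix path prefix for the three output files.
#' @param provenance optional named list stored verbatim in the sidecar
#'   (e.g. generator seed or input file names).
#' @return invisibly, the three file paths.
#' @export
write_network <- function(network, prefix, provenance = NULL) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  loci_path <- paste0(prefix, "_loci.tsv")
  pairs_path <- paste0(prefix, "_pairs.tsv")
  meta_path <- paste0(prefix, "_meta.yaml")
  loci <- data.frame(locus_id = network$locus_ids,
                     s = fmt_full(network$s), h = fmt_full(network$h))
  utils::write.table(loci, loci_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- data.frame(locus_i = network$locus_ids[network$pairs$i],
                   locus_j = network$locus_ids[network$pairs$j],
                   epsilon = fmt_full(network$pairs$epsilon))
  utils::write.table(pt, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(format = "epidiverge_network", version = 1L,
               measure = network$measure,
               n_loci = n_loci(network), n_pairs = nrow(network$pairs))
  if (!is.null(provenance)) meta$provenance <- provenance
  yaml::write_yaml(meta, meta_path)
  invisible(c(loci = loci_path, pairs = pairs_path, meta = meta_path))
}

#' Read a network serialized by [write_network()]
#'
#' @param prefix path prefix used when writing.
#' @return an `epistasis_network`.
#' @export
read_network <- function(prefix) {
  loci_path <- paste0(prefix, "_loci.tsv")
  pairs_path <- paste0(prefix, "_pairs.tsv")
  meta_path <- paste0(prefix, "_meta.yaml")
  for (p in c(loci_path, pairs_path, meta_path))
    if (!file.exists(p)) stop("missing network file: ", p)
  meta <- yaml::read_yaml(meta_path)
  loci <- utils::read.delim(loci_path, colClasses = c("character", "numeric", "numeric"))
  pt <- utils::read.delim(pairs_path,
                          colClasses = c("character", "character", "numeric"))
  epistasis_network(loci$locus_id, loci$s, loci$h,
                    pairs = if (nrow(pt)) pt else NULL,
                    measure = meta$measure)
}
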