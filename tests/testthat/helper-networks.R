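# Shared fixtures and independent oracles, built in code.

## fully connected network with every pair at the same epsilon
constant_network <- function(n, eps, s = 0) {
  pr <- t(utils::combn(n, 2))
  epistasis_network(sprintf("L%03d", seq_len(n)), s = rep(s, n),
                    pairs = data.frame(i = pr[, 1], j = pr[, 2], epsilon = eps))
}

neutral_network <- function(n) {
  epistasis_network(sprintf("L%03d", seq_len(n)), s = rep(0, n))
}

## random small network with dense epsilon for oracle comparisons
random_network <- function(n, seed) {
  withr::with_seed(seed, {
    s <- stats::runif(n, -0.5, 0.3)
    h <- stats::runif(n, 0, 1)
    pr <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pr)) < 0.8
    pairs <- data.frame(i = pr[keep, 1], j = pr[keep, 2],
                        epsilon = stats::runif(sum(keep), -0.6, 0.6))
    epistasis_network(sprintf("L%03d", seq_len(n)), s = s, h = h,
                      pairs = pairs)
  })
}

## dense symmetric epsilon matrix straight from the pair table, so the
## oracle below never touches the package's sparse-matrix helpers
dense_eps <- function(net) {
  n <- length(net$locus_ids)
  E <- matrix(0, n, n)
  p <- net$pairs
  for (r in seq_len(nrow(p))) {
    E[p$i[r], p$j[r]] <- p$epsilon[r]
    E[p$j[r], p$i[r]] <- p$epsilon[r]
  }
  E
}

## brute-force fitness: explicit loop over loci and unordered pairs,
## one factor per pair, factors below zero clamped to zero
oracle_fitness <- function(net, het, hom, alpha1, alpha2) {
  E <- dense_eps(net)
  het <- match(het, net$locus_ids)
  hom <- match(hom, net$locus_ids)
  f <- numeric(0)
  for (l in het) f <- c(f, 1 + net$h[l] * net$s[l])
  for (l in hom) f <- c(f, 1 + net$s[l])
  all_loci <- c(het, hom)
  zyg <- c(rep("het", length(het)), rep("hom", length(hom)))
  if (length(all_loci) >= 2) {
    for (a in 1:(length(all_loci) - 1)) for (b in (a + 1):length(all_loci)) {
      e <- E[all_loci[a], all_loci[b]]
      sc <- if (zyg[a] == "het" && zyg[b] == "het") alpha1
            else if (zyg[a] == "hom" && zyg[b] == "hom") 1
            else alpha2
      f <- c(f, 1 + sc * e)
    }
  }
  f <- pmax(f, 0)
  prod(f)
}

oracle_hybrid <- function(net, a, b, alpha1, alpha2) {
  num <- oracle_fitness(net, c(a, b), character(0), alpha1, alpha2)
  den <- (oracle_fitness(net, character(0), a, alpha1, alpha2) +
            oracle_fitness(net, character(0), b, alpha1, alpha2)) / 2
  num / den
}

## two-locus scenario builder: independent effects s, one interaction
two_locus_network <- function(eps, s = c(0, 0)) {
  epistasis_network(c("i", "j"), s = s,
                    pairs = data.frame(locus_i = "i", locus_j = "j",
                                       epsilon = eps))
}

## write a small interaction table to a temp file; returns path
write_interaction_fixture <- function(rows,
                                      header = c("q", "a", "wq", "wa", "wd")) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

toy_column_map <- function() {
  list(query_id = "q", array_id = "a", w_query = "wq", w_array = "wa",
       w_double = "wd", reported_epsilon = NA_character_,
       p_value = NA_character_)
}
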