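#' Default column mapping for SGA-style genetic-interaction tables
#'
#' Matches the header of the Costanzo et al. (2016) SGA release distributed
#' at thecellmap.org. Override any entry to ingest other dialects.
#'
#' @return named list mapping record fields to column names; entries set to
#'   `NA` (here `reported_epsilon` and `p_value` have real defaults) may be
#'   set to `NA_character_` when a file lacks the column.
#' @export
sga_column_map <- function() {
  list(query_id = "Query Strain ID",
       array_id = "Array Strain ID",
       w_query = "Query single mutant fitness (SMF)",
       w_array = "Array SMF",
       w_double = "Double mutant fitness",
       reported_epsilon = "Genetic interaction score (epsilon)",
       p_value = "P-value")
}

required_fields <- c("query_id", "array_id", "w_query", "w_array", "w_double")

#' Load and concatenate double-knockout fitness tables
#'
#' Reads one or more tab-delimited genetic-interaction tables (plain or
#' gzip-compressed) and concatenates them, in input order, into a single
#' knockout-record table. Fitness cells that cannot be parsed as numbers
#' (including empty cells) are recorded as missing; no rows are dropped at
#' this stage except self-pairs (query and array naming the same strain),
#' which violate the record contract and are removed with a warning.
#'
#' @param paths character vector of file paths.
#' @param column_map named list mapping the fields `query_id`, `array_id`,
#'   `w_query`, `w_array`, `w_double` (required) and `reported_epsilon`,
#'   `p_value` (optional; `NA_character_` to omit) to column names in the
#'   input header. Default [sga_column_map()].
#' @return data frame of knockout records with columns `query_id`,
#'   `array_id`, `w_query`, `w_array`, `w_double`, `reported_epsilon`,
#'   `p_value`. Missing values are `NA`.
#' @export
load_interaction_table <- function(paths, column_map = sga_column_map()) {
  if (length(paths) == 0L) stop("no input files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file not found: ", paste(missing, collapse = ", "))
  if (!all(required_fields %in% names(column_map)))
    stop("column_map must name columns for: ",
         paste(required_fields, collapse = ", "))

  one <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", showProgress = FALSE)
    mapped <- unlist(column_map[!vapply(column_map, function(x)
      is.null(x) || is.na(x), logical(1))])
    absent <- setdiff(mapped, names(dt))
    if (length(absent))
      stop("file ", path, " lacks mapped column(s) ",
           paste(absent, collapse = ", "), "; available columns: ",
           paste(names(dt), collapse = ", "))
    get_col <- function(field, numeric = FALSE) {
      cn <- column_map[[field]]
      if (is.null(cn) || is.na(cn)) return(rep(NA_real_, nrow(dt)))
      v <- dt[[cn]]
      if (numeric) suppressWarnings(as.numeric(v)) else v
    }
    data.frame(query_id = get_col("query_id"),
               array_id = get_col("array_id"),
               w_query = get_col("w_query", TRUE),
               w_array = get_col("w_array", TRUE),
               w_double = get_col("w_double", TRUE),
               reported_epsilon = get_col("reported_epsilon", TRUE),
               p_value = get_col("p_value", TRUE))
  }
  rec <- do.call(rbind, lapply(paths, one))

  neg <- (!is.na(rec$w_query) & rec$w_query < 0) |
    (!is.na(rec$w_array) & rec$w_array < 0) |
    (!is.na(rec$w_double) & rec$w_double < 0)
  if (any(neg)) {
    warning(sum(neg), " record(s) with negative fitness; values set to missing")
    rec$w_query[!is.na(rec$w_query) & rec$w_query < 0] <- NA_real_
    rec$w_array[!is.na(rec$w_array) & rec$w_array < 0] <- NA_real_
    rec$w_double[!is.na(rec$w_double) & rec$w_double < 0] <- NA_real_
  }
  self <- rec$query_id == rec$array_id
  if (any(self)) {
    warning(sum(self), " self-pair record(s) removed")
    rec <- rec[!self, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Retain records with complete fitness measurements
#'
#' Keeps exactly the records for which both single-mutant fitnesses and the
#' double-mutant fitness are present. No significance filtering is applied:
#' interactions are kept regardless of their p-value, so that weak and
#' absent interactions contribute to the estimated distribution.
#'
#' @param records knockout-record data frame from
#'   [load_interaction_table()].
#' @return the complete subset, original order preserved. Idempotent.
#' @export
filter_complete <- function(records) {
  keep <- !is.na(records$w_query) & !is.na(records$w_array) &
    !is.na(records$w_double)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate independent and epistatic selection coefficients
#'
#' Decomposes haploid knockout fitnesses into per-locus independent
#' selection coefficients and per-pair epistatic coefficients. Writing
#' `W_i` for the single-knockout fitness at locus i and `W_ij` for the
#' double knockout, the independent coefficient is `s_i = W_i - 1` and the
#' epistatic coefficient under each measure is
#' \describe{
#'   \item{multiplicative}{`eps = W_ij / (W_i * W_j) - 1` (the model's
#'     native decomposition `W_ij = (1+s_i)(1+s_j)(1+eps)`); pairs with
#'     `W_i * W_j = 0` are undefined, dropped, and counted in the returned
#'     diagnostics.}
#'   \item{additive}{`eps = W_ij - W_i - W_j + 1`.}
#'   \item{costanzo}{`eps = W_ij - W_i * W_j` (the score used by the SGA
#'     release); with `use_reported = TRUE` the published interaction score
#'     column is used verbatim instead.}
#' }
#' A locus measured with different single-mutant fitnesses across records
#' (beyond `single_fitness_tol`) triggers a warning and is resolved by the
#' `dedup` strategy. Pairs measured in both orientations (or replicated)
#' are symmetrized by arithmetic averaging.
#'
#' @param records complete knockout records (pass through
#'   [filter_complete()] first).
#' @param measure `"multiplicative"` (default), `"additive"` or
#'   `"costanzo"`.
#' @param dedup how to resolve inconsistent single-mutant fitnesses per
#'   locus: `"average"` (default), `"first"` (first occurrence wins) or
#'   `"strict"` (error).
#' @param id_fun optional function applied to strain identifiers before
#'   grouping, e.g. `function(x) sub("_.*$", "", x)` to collapse strains
#'   sharing an allele name into one locus.
#' @param h_default dominance assigned to every locus (default 1/2; haploid
#'   assays carry no dominance information).
#' @param use_reported under `measure = "costanzo"`, use the published
#'   interaction-score column instead of recomputing from fitnesses.
#' @param single_fitness_tol tolerance on the spread of single-mutant
#'   fitness per locus before the inconsistency warning fires.
#' @return an `epistasis_network` (multiplicative-clamped so that every
#'   `epsilon >= -1`), with attribute `"diagnostics"`: a list with
#'   `n_records`, `n_dropped_zero_fitness`, `n_inconsistent_loci`,
#'   `n_clamped_epsilon`.
#' @export
estimate_effects <- function(records,
                             measure = c("multiplicative", "additive", "costanzo"),
                             dedup = c("average", "first", "strict"),
                             id_fun = NULL, h_default = 0.5,
                             use_reported = FALSE,
                             single_fitness_tol = 1e-6) {
  measure <- match.arg(measure)
  dedup <- match.arg(dedup)
  if (nrow(records) == 0L) stop("no records to estimate from")
  if (anyNA(records$w_query) || anyNA(records$w_array) || anyNA(records$w_double))
    stop("records contain missing fitness values; apply filter_complete() first")

  dt <- data.table::as.data.table(records)
  if (!is.null(id_fun)) {
    dt[, query_id := id_fun(query_id)]
    dt[, array_id := id_fun(array_id)]
    self <- dt$query_id == dt$array_id
    if (any(self)) {
      warning(sum(self), " record(s) became self-pairs after id_fun; removed")
      dt <- dt[!self]
    }
  }

  ## Independent effects: pool both roles of every locus.
  singles <- data.table::rbindlist(list(
    dt[, list(id = query_id, w = w_query)],
    dt[, list(id = array_id, w = w_array)]))
  rng <- singles[, list(w_min = min(w), w_max = max(w), w_mean = mean(w),
                        w_first = w[1L]), by = "id"]
  inconsistent <- rng$w_max - rng$w_min > single_fitness_tol
  if (any(inconsistent)) {
    if (dedup == "strict")
      stop(sum(inconsistent), " locus/loci with inconsistent single-mutant fitness")
    warning(sum(inconsistent),
            " locus/loci with inconsistent single-mutant fitness; resolved by '",
            dedup, "'")
  }
  rng[, w := if (dedup == "first") w_first else w_mean]
  data.table::setorder(rng, id)
  locus_ids <- rng$id
  s <- rng$w - 1

  ## Pairwise effects under the chosen measure.
  n_zero <- 0L
  if (measure == "multiplicative") {
    denom <- dt$w_query * dt$w_array
    zero <- denom == 0
    n_zero <- sum(zero)
    dt <- dt[!zero]
    dt[, eps := w_double / (w_query * w_array) - 1]
  } else if (measure == "additive") {
    dt[, eps := w_double - w_query - w_array + 1]
  } else {
    if (use_reported) {
      if (anyNA(dt$reported_epsilon))
        stop("use_reported = TRUE but reported interaction scores are missing")
      dt[, eps := reported_epsilon]
    } else {
      dt[, eps := w_double - w_query * w_array]
    }
  }
  qi <- match(dt$query_id, locus_ids)
  ai <- match(dt$array_id, locus_ids)
  dt[, `:=`(i = pmin(qi, ai), j = pmax(qi, ai))]
  pairs <- dt[, list(epsilon = mean(eps)), by = c("i", "j")]

  n_clamped <- sum(pairs$epsilon < -1)
  if (n_clamped > 0L) pairs[, epsilon := pmax(epsilon, -1)]

  net <- epistasis_network(locus_ids, s, h = h_default,
                           pairs = as.data.frame(pairs), measure = measure)
  attr(net, "diagnostics") <- list(
    n_records = nrow(records),
    n_dropped_zero_fitness = n_zero,
    n_inconsistent_loci = sum(inconsistent),
    n_clamped_epsilon = n_clamped)
  net
}
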