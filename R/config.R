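#' Default configuration
#'
#' The full default configuration used by [parse_config()] and
#' [dispatch()]. Simulation defaults are an effective size of `1e6`,
#' 50 fixations per population, additive dominance of independent effects
#' (`h = 1/2`) and additive epistatic dominance (`alpha1 = 1/4`,
#' `alpha2 = 1/2`), the multiplicative epistasis measure, and strict
#' alternation of fixations between the populations.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    effective_size = 1e6,
    fixations_per_population = 50L,
    replicates = 1L,
    measure = "multiplicative",
    alternation = "strict",
    rate_ratio = 1,
    dominance = list(h = 0.5, alpha1 = 0.25, alpha2 = 0.5),
    network = list(path = NULL),
    synthetic = list(
      n_loci = 1000L,
      weights = c(0.15, 0.75, 0.10),
      means = c(-0.35, -0.05, 0.02),
      sds = c(0.15, 0.04, 0.02),
      coupling = 0.1,
      epsilon_noise_sd = 0.03,
      pair_density = 0.4,
      epsilon_family = "laplace"),
    analytic = list(eps_w = 0.02, eps_b = 0.01, v = 0.25, n_max = 50L),
    input = list(paths = NULL, column_map = NULL),
    summarize = list(trajectories = NULL, n_per_population = 10L,
                     large_effect_threshold = 0.10))
}

check_keys <- function(supplied, template, path = "") {
  unknown <- setdiff(names(supplied), names(template))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(supplied)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(supplied[[k]]))
        stop("configuration section '", path, k, "' must be a mapping")
      check_keys(supplied[[k]], template[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(supplied, template) {
  for (k in names(supplied)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(supplied[[k]])) {
      template[[k]] <- merge_config(supplied[[k]], template[[k]])
    } else {
      template[k] <- list(supplied[[k]])   # keeps NULL-valued keys
    }
  }
  template
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= 0 && x <= 1
  if (!in01(cfg$dominance$alpha1)) stop("dominance.alpha1 must be in [0, 1]")
  if (!in01(cfg$dominance$alpha2)) stop("dominance.alpha2 must be in [0, 1]")
  if (!is.numeric(cfg$dominance$h) || !is.finite(cfg$dominance$h))
    stop("dominance.h must be a finite number")
  if (!cfg$measure %in% c("multiplicative", "additive", "costanzo"))
    stop("measure must be multiplicative, additive or costanzo")
  if (!cfg$alternation %in% c("strict", "random"))
    stop("alternation must be strict or random")
  if (cfg$effective_size < 2) stop("effective_size must be >= 2")
  if (cfg$fixations_per_population < 1)
    stop("fixations_per_population must be >= 1")
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  if (!in01(cfg$synthetic$pair_density))
    stop("synthetic.pair_density must be in [0, 1]")
  if (!is.null(cfg$analytic$v) &&
      (cfg$analytic$v < 0 || cfg$analytic$v > 0.25))
    stop("analytic.v must be in [0, 1/4]")
  cfg
}

#' Parse and validate a YAML configuration file
#'
#' Reads a (possibly empty) YAML file, applies all defaults from
#' [default_config()], rejects unknown keys with their key path, and
#' validates parameter ranges.
#'
#' @param path YAML file path.
#' @return validated configuration list (class `epidiverge_config`).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  supplied <- yaml::read_yaml(path)
  if (is.null(supplied)) supplied <- list()
  if (!is.list(supplied)) stop("configuration must be a YAML mapping")
  template <- default_config()
  check_keys(supplied, template)
  cfg <- validate_config(merge_config(supplied, template))
  structure(cfg, class = c("epidiverge_config", "list"))
}

#' Serialize a configuration to YAML
#'
#' A configuration written with `write_config()` and re-read with
#' [parse_config()] is identical.
#'
#' @param config configuration list.
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_to_sim <- function(cfg) {
  simulation_config(
    effective_size = cfg$effective_size,
    fixations_per_population = cfg$fixations_per_population,
    dominance = dominance_params(cfg$dominance$h, cfg$dominance$alpha1,
                                 cfg$dominance$alpha2),
    alternation = cfg$alternation,
    rate_ratio = cfg$rate_ratio,
    seed = cfg$seed,
    replicate_count = cfg$replicates)
}

config_to_spec <- function(cfg) {
  synthetic_network_spec(
    n_loci = cfg$synthetic$n_loci,
    s_mixture = list(weights = cfg$synthetic$weights,
                     means = cfg$synthetic$means,
                     sds = cfg$synthetic$sds),
    coupling = cfg$synthetic$coupling,
    epsilon_noise_sd = cfg$synthetic$epsilon_noise_sd,
    pair_density = cfg$synthetic$pair_density,
    epsilon_family = cfg$synthetic$epsilon_family,
    seed = cfg$seed)
}
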