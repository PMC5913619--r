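#' Read a scenario configuration file
#'
#' Parses a YAML or JSON scenario description into validated parameter
#' objects. Recognised top-level keys, mirroring the parameter types:
#'
#' * `structural`: `beta1`, `beta2`, `gamma`, `sigma_eps`
#' * `confounding`: `rho_UE`, `rho_UC`
#' * `error`: `type` (`"continuous"` or `"binary"`) plus `icc_E`/`icc_C`
#'   or `p_E`/`p_C`/`quantile_cut`
#' * `simulation`: `n`, `reps`, `seed`
#'
#' Missing fields fall back to the constructors' defaults. The file format
#' is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the configuration file.
#' @return A list with components `sp`, `conf`, `err`, `n`, `reps`, `seed`
#'   and the raw parsed `config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_list(cfg)
}

#' Build a scenario from a plain list
#'
#' Programmatic counterpart of [read_scenario_config()]: takes an
#' already-parsed list with the same keys.
#'
#' @param cfg A named list (see [read_scenario_config()] for keys).
#' @return A list with components `sp`, `conf`, `err`, `n`, `reps`, `seed`
#'   and the raw `config`.
#' @export
scenario_from_list <- function(cfg) {
  pick <- function(block, key, default) {
    v <- cfg[[block]][[key]]
    if (is.null(v)) default else v
  }
  sp <- structural_params(
    beta1 = pick("structural", "beta1", 0),
    beta2 = pick("structural", "beta2", 0),
    gamma = pick("structural", "gamma", 0),
    sigma_eps = pick("structural", "sigma_eps", 1)
  )
  conf <- confounding_structure(
    rho_UE = pick("confounding", "rho_UE", 0.4),
    rho_UC = pick("confounding", "rho_UC", 0.4)
  )
  type <- pick("error", "type", "continuous")
  err <- switch(
    type,
    continuous = continuous_error(
      icc_E = pick("error", "icc_E", 1),
      icc_C = pick("error", "icc_C", 1)
    ),
    binary = binary_error(
      p_E = pick("error", "p_E", 0),
      p_C = pick("error", "p_C", 0),
      quantile_cut = pick("error", "quantile_cut", 0.8)
    ),
    stop("unknown error type: ", type, call. = FALSE)
  )
  list(
    sp = sp, conf = conf, err = err,
    n = pick("simulation", "n", 10000),
    reps = pick("simulation", "reps", 10000),
    seed = pick("simulation", "seed", 1),
    config = cfg
  )
}

#' Flatten a scenario into a one-row provenance record
#'
#' Produces a one-row data frame with every parameter of a scenario, for
#' echoing into output tables so that each result row carries its full
#' configuration.
#'
#' @param sp A [structural_params()].
#' @param conf A [confounding_structure()].
#' @param err An error spec.
#' @return A one-row data frame.
#' @export
scenario_provenance <- function(sp, conf, err) {
  base <- data.frame(
    beta1 = sp$beta1, beta2 = sp$beta2, gamma = sp$gamma,
    sigma_eps = sp$sigma_eps,
    rho_UE = conf$rho_UE, rho_UC = conf$rho_UC, rho_EC = conf$rho_EC
  )
  if (inherits(err, "continuous_error_spec")) {
    cbind(base, data.frame(design = "continuous", icc_E = err$icc_E,
                           icc_C = err$icc_C, sigma2_vE = err$sigma2_vE,
                           sigma2_vC = err$sigma2_vC))
  } else {
    cbind(base, data.frame(design = "binary", p_E = err$p_E, p_C = err$p_C,
                           quantile_cut = err$quantile_cut))
  }
}
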