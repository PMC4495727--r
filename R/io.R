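#' Read and write trial tables
#'
#' Trial tables round-trip through CSV with the header
#' `index,category,signal,response,outcome,payoff`. `read_trials()` validates
#' the schema and rejects any row whose `(category, response, outcome)`
#' triple violates the outcome taxonomy (e.g. a target/target row labeled
#' FA), reporting the first offending row number. A header-only file reads
#' as an empty trial set.
#'
#' @param trials A trial tibble as from [simulate_trials()].
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `path` invisibly.
#' @name trials_io
NULL

trial_cols <- c("index", "category", "signal", "response", "outcome", "payoff")

#' @rdname trials_io
#' @export
write_trials <- function(trials, path) {
  if (!is.data.frame(trials) || !all(trial_cols %in% names(trials))) {
    abort("`trials` must have columns index, category, signal, response, outcome, payoff")
  }
  readr::write_csv(trials[trial_cols], path)
  invisible(path)
}

#' @rdname trials_io
#' @export
read_trials <- function(path) {
  dat <- readr::read_csv(
    path,
    col_types = readr::cols(
      index = readr::col_integer(),
      category = readr::col_character(),
      signal = readr::col_double(),
      response = readr::col_character(),
      outcome = readr::col_character(),
      payoff = readr::col_double()
    )
  )
  if (!identical(names(dat), trial_cols)) {
    abort(sprintf("trial file must have exactly the columns: %s",
                  paste(trial_cols, collapse = ", ")),
          class = "sdtvalue_parse_error")
  }
  if (nrow(dat) == 0L) return(as_tibble(dat))
  bad_cat <- which(!dat$category %in% c("target", "foil") |
                     !dat$response %in% c("target", "foil"))
  if (length(bad_cat)) {
    abort(sprintf("row %d: category/response must be \"target\" or \"foil\"",
                  bad_cat[1]), class = "sdtvalue_parse_error")
  }
  expected <- classify_outcome(dat$category, dat$response)
  bad <- which(dat$outcome != expected)
  if (length(bad)) {
    abort(sprintf(
      "row %d: outcome \"%s\" inconsistent with category \"%s\" / response \"%s\" (expected %s)",
      bad[1], dat$outcome[bad[1]], dat$category[bad[1]], dat$response[bad[1]],
      expected[bad[1]]
    ), class = "sdtvalue_parse_error")
  }
  as_tibble(dat)
}

env_to_list <- function(env) {
  list(
    mu_target = env$mu_target, mu_foil = env$mu_foil,
    sigma_target = env$sigma_target, sigma_foil = env$sigma_foil,
    base_rate = env$base_rate,
    domain_bounds = env$domain_bounds,
    units = env$units
  )
}

payoffs_to_list <- function(p) list(h = p$h, m = p$m, a = p$a, j = p$j)

scheme_to_list <- function(scheme) {
  if (is.null(scheme)) return(NULL)
  lapply(unclass(scheme), unclass)
}

check_keys <- function(x, allowed, required, what) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("unknown key(s) in %s: %s", what, paste(extra, collapse = ", ")),
          class = "sdtvalue_parse_error")
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("missing key(s) in %s: %s", what, paste(missing, collapse = ", ")),
          class = "sdtvalue_parse_error")
  }
  invisible(x)
}

#' Build model objects from configuration lists
#'
#' Converters between the plain-list representation used in YAML/JSON config
#' files and the package's model objects. Parsing is strict: unknown keys are
#' rejected with the offending field named.
#'
#' The environment mapping uses keys `mu_target`, `mu_foil`, `sigma_target`,
#' `sigma_foil`, `base_rate`, and optionally `domain_bounds` and `units`;
#' payoffs use `h`, `m`, `a`, `j`; a scheme is a mapping of `value_fn`,
#' `prob_weight_fn`, `base_rate_weight_fn`, `signal_prob_weight_fn`, each a
#' mapping with a `family` field and that family's parameters.
#'
#' @param x A named list, e.g. from [yaml::read_yaml()].
#' @return The corresponding model object.
#' @name config_parsers
NULL

#' @rdname config_parsers
#' @export
as_perceptual_environment <- function(x) {
  if (is_environment(x)) return(x)
  check_keys(x, c("mu_target", "mu_foil", "sigma_target", "sigma_foil",
                  "base_rate", "domain_bounds", "units"),
             c("mu_target", "mu_foil", "sigma_target", "base_rate"),
             "environment")
  perceptual_environment(
    mu_target = x$mu_target, mu_foil = x$mu_foil,
    sigma_target = x$sigma_target,
    sigma_foil = x$sigma_foil %||% x$sigma_target,
    base_rate = x$base_rate,
    domain_bounds = if (!is.null(x$domain_bounds)) unlist(x$domain_bounds),
    units = x$units %||% "signal"
  )
}

#' @rdname config_parsers
#' @export
as_payoff_matrix <- function(x) {
  if (inherits(x, "payoff_matrix")) return(x)
  check_keys(x, c("h", "m", "a", "j"), c("h", "m", "a", "j"), "payoffs")
  payoff_matrix(h = x$h, m = x$m, a = x$a, j = x$j)
}

parse_value_fn <- function(x) {
  if (inherits(x, "value_fn")) return(x)
  check_keys(x, c("family", "exponent", "gain_exponent", "loss_exponent",
                  "loss_aversion", "reference"), "family", "value_fn")
  switch(x$family,
    identity = value_identity(),
    power = value_power(exponent = x$exponent %||% 0.88),
    prospect = value_prospect(
      gain_exponent = x$gain_exponent %||% 0.88,
      loss_exponent = x$loss_exponent %||% 0.88,
      loss_aversion = x$loss_aversion %||% 2.25,
      reference = x$reference %||% 0
    ),
    abort(sprintf("unknown value_fn family \"%s\"", x$family),
          class = "sdtvalue_parse_error")
  )
}

parse_weight_fn <- function(x, what) {
  if (inherits(x, "prob_weight_fn")) return(x)
  check_keys(x, c("family", "delta"), "family", what)
  switch(x$family,
    identity = weight_identity(),
    tk1992 = weight_tk1992(delta = x$delta %||% 0.61),
    abort(sprintf("unknown %s family \"%s\"", what, x$family),
          class = "sdtvalue_parse_error")
  )
}

#' @rdname config_parsers
#' @export
as_weighting_scheme <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "weighting_scheme")) return(x)
  check_keys(x, c("value_fn", "prob_weight_fn", "base_rate_weight_fn",
                  "signal_prob_weight_fn"), character(), "scheme")
  idw <- list(family = "identity")
  weighting_scheme(
    value_fn = parse_value_fn(x$value_fn %||% idw),
    prob_weight_fn = parse_weight_fn(x$prob_weight_fn %||% idw, "prob_weight_fn"),
    base_rate_weight_fn = parse_weight_fn(x$base_rate_weight_fn %||% idw,
                                          "base_rate_weight_fn"),
    signal_prob_weight_fn = parse_weight_fn(x$signal_prob_weight_fn %||% idw,
                                            "signal_prob_weight_fn")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration file
#'
#' Reads a YAML (or JSON; YAML is a superset) configuration describing an
#' analysis run. Recognized top-level keys: `environment` (required for
#' curve/optimize/envelope/simulate runs), `payoffs`, `payoff_variants` (list
#' of payoff mappings), `scheme`, `mode`, `gamble` (outcome list with
#' `probability`/`value` fields, or a `"p:v,..."` string), `grid` (`bounds`,
#' `n`), `simulation` (`n`, `seed`, `criterion`). Unknown keys anywhere are
#' rejected.
#'
#' @param path Path to the configuration file.
#' @return A list with parsed model objects (fields `environment`, `payoffs`,
#'   `payoff_variants`, `scheme`, `mode`, `gamble`, `grid`, `simulation`),
#'   plus `resolved`: the fully-resolved plain-list form suitable for
#'   re-serialization alongside results.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("environment", "payoffs", "payoff_variants", "scheme",
                    "mode", "gamble", "grid", "simulation", "label"),
             character(), "config")
  env <- if (!is.null(raw$environment)) as_perceptual_environment(raw$environment)
  payoffs <- if (!is.null(raw$payoffs)) as_payoff_matrix(raw$payoffs)
  variants <- if (!is.null(raw$payoff_variants)) {
    lapply(raw$payoff_variants, as_payoff_matrix)
  }
  scheme <- as_weighting_scheme(raw$scheme)
  g <- raw$gamble
  gmb <- if (!is.null(g)) {
    if (is.character(g)) parse_gamble(g, label = raw$label)
    else gamble(vapply(g, `[[`, numeric(1), "probability"),
                vapply(g, `[[`, numeric(1), "value"),
                label = raw$label)
  }
  grid <- raw$grid
  if (!is.null(grid)) check_keys(grid, c("bounds", "n"), character(), "grid")
  sim <- raw$simulation
  if (!is.null(sim)) check_keys(sim, c("n", "seed", "criterion"), character(), "simulation")
  mode <- raw$mode %||% "ev"
  if (!mode %in% c("ev", "value_weighted", "fully_weighted")) {
    abort(sprintf("unknown mode \"%s\"", mode), class = "sdtvalue_parse_error")
  }
  resolved <- list(
    environment = if (!is.null(env)) env_to_list(env),
    payoffs = if (!is.null(payoffs)) payoffs_to_list(payoffs),
    payoff_variants = if (!is.null(variants)) lapply(variants, payoffs_to_list),
    scheme = scheme_to_list(scheme),
    mode = mode,
    gamble = if (!is.null(gmb)) {
      list(label = attr(gmb, "label"),
           outcomes = purrr::map2(gmb$probability, gmb$value,
                                  ~list(probability = .x, value = .y)))
    },
    grid = grid, simulation = sim
  )
  list(environment = env, payoffs = payoffs, payoff_variants = variants,
       scheme = scheme, mode = mode, gamble = gmb, grid = grid,
       simulation = sim, resolved = resolved[!vapply(resolved, is.null, logical(1))])
}

#' Write a value curve with its provenance sidecar
#'
#' Writes an [ev_curve()] as CSV (columns `x`, `p_cd`, `p_md`, `p_fa`,
#' `p_cr`, `value`) and, by default, a JSON sidecar (`<path>.json`) recording
#' the environment, payoffs, scheme, mode, and the refined optimal criterion,
#' so every curve file is self-describing.
#'
#' @param curve An [ev_curve()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, sidecar = TRUE) {
  if (!inherits(curve, "ev_curve")) abort("`curve` must be an ev_curve()")
  readr::write_csv(as_tibble(curve)[c("x", "p_cd", "p_md", "p_fa", "p_cr", "value")],
                   path)
  if (sidecar) {
    env <- attr(curve, "environment")
    payoffs <- attr(curve, "payoffs")
    scheme <- attr(curve, "scheme")
    mode <- attr(curve, "mode")
    opt <- optimal_criterion(env, payoffs, scheme, mode = mode,
                             bounds = range(curve$x), n = nrow(curve))
    jsonlite::write_json(list(
      environment = env_to_list(env),
      payoffs = payoffs_to_list(payoffs),
      scheme = scheme_to_list(scheme),
      mode = mode,
      x_star = opt$x_star,
      value_at_star = opt$value
    ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
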