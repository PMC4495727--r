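#' Write the worked-example configurations
#'
#' Emits ready-to-run configuration files for the package's running example
#' -- the decision to bike or drive to work under uncertain weather -- plus a
#' machine-readable record of the values each configuration should
#' reproduce:
#'
#' * `bike.yaml`, `drive.yaml`: the two commute gambles (bike: 0.5 chance of
#'   +100 points, 0.25 of -10, 0.25 of -90; drive: 0.5 of +100, 0.5 of -50);
#'   both have expected value 25.
#' * `rain_decision.yaml`: the signal-detection form of the same decision --
#'   target (rain) mean 60, foil mean 40, sd 15 (% chance of rain), base rate
#'   0.5, payoffs h=100, m=-50, a=-50, j=100 -- whose optimal criterion is a
#'   50% chance of rain.
#' * `rain_envelope.yaml`: the same environment with the false-alarm cost
#'   varying between heavy rain (a=-90) and light rain (a=-10) about the
#'   mean (a=-50), defining the expected-value envelope.
#' * `expectations.json`: the quantities the suite should reproduce from
#'   these files (gamble expected values of 25, Option-B-style 45-point
#'   no-uncertainty constant, optimal criterion 50), each with a note saying
#'   what it is.
#'
#' Output is deterministic: re-running produces byte-identical files.
#'
#' @param dir Output directory (created if missing).
#' @param compute Also write `results.json` with the values recomputed by
#'   the package from the emitted configurations.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, compute = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character()
  emit <- function(name, obj) {
    p <- file.path(dir, name)
    yaml::write_yaml(obj, p, precision = 12)
    out <<- c(out, p)
    p
  }

  emit("bike.yaml", list(
    label = "bike",
    gamble = list(
      list(probability = 0.5, value = 100),
      list(probability = 0.25, value = -10),
      list(probability = 0.25, value = -90)
    )
  ))
  emit("drive.yaml", list(
    label = "drive",
    gamble = list(
      list(probability = 0.5, value = 100),
      list(probability = 0.5, value = -50)
    )
  ))

  env_spec <- list(
    mu_target = 60, mu_foil = 40, sigma_target = 15, sigma_foil = 15,
    base_rate = 0.5, units = "% chance of rain"
  )
  pay_mean <- list(h = 100, m = -50, a = -50, j = 100)
  emit("rain_decision.yaml", list(environment = env_spec, payoffs = pay_mean))
  emit("rain_envelope.yaml", list(
    environment = env_spec,
    payoffs = pay_mean,
    payoff_variants = list(
      list(h = 100, m = -50, a = -90, j = 100),
      list(h = 100, m = -50, a = -10, j = 100)
    )
  ))

  expectations <- list(
    ev_bike = list(value = 25,
                   note = "expected value of the bike gamble, in points"),
    ev_drive = list(value = 25,
                    note = "expected value of the drive gamble, in points"),
    ev_option_b = list(value = 50,
                       note = "expected value of a 50/50 gamble over $25 and $75"),
    ev_no_uncertainty = list(value = 45,
                             note = "constant expected value when a 0.5:$35/0.5:$55 target option and a sure-$45 foil option are perceptually distinct"),
    optimal_criterion = list(value = 50,
                             note = "optimal criterion for rain_decision.yaml, % chance of rain")
  )
  pexp <- file.path(dir, "expectations.json")
  jsonlite::write_json(expectations, pexp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out <- c(out, pexp)

  if (compute) {
    cfg_rain <- read_run_config(file.path(dir, "rain_decision.yaml"))
    results <- list(
      ev_bike = expected_value(read_run_config(file.path(dir, "bike.yaml"))$gamble),
      ev_drive = expected_value(read_run_config(file.path(dir, "drive.yaml"))$gamble),
      ev_option_b = expected_value(gamble(c(0.5, 0.5), c(25, 75))),
      ev_no_uncertainty = no_uncertainty_value(
        0.5, expected_value(gamble(c(0.5, 0.5), c(35, 55))), 45),
      optimal_criterion = optimal_criterion(cfg_rain$environment,
                                            cfg_rain$payoffs)$x_star
    )
    pres <- file.path(dir, "results.json")
    jsonlite::write_json(results, pres, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out <- c(out, pres)
  }
  invisible(out)
}
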