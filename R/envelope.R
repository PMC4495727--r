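#' Expected-value envelope under payoff variability
#'
#' Economic risk -- variability in the outcome payoffs themselves -- turns the
#' single criterion expected-value function into a band. Given a mean payoff
#' matrix and a set of payoff variants (e.g. the false-alarm cost under heavy
#' vs. light rain), the envelope is bounded by the pointwise minimum and
#' maximum of the variants' expected-value curves, with the mean curve
#' computed from the mean payoffs.
#'
#' The optimal criteria of the three curves expose an asymmetry: even for
#' payoff perturbations symmetric about the mean, the optimum of the mean
#' curve is generally *not* the mean of the variant optima, because the
#' criterion responds to the logarithm of the critical likelihood ratio, a
#' nonlinear function of the payoffs. Symmetric economic variation therefore
#' produces asymmetric shifts in optimal behavior whenever perceptual
#' uncertainty is present.
#'
#' @inheritParams ev_curve
#' @param payoffs_mean A [payoff_matrix()] of mean payoffs.
#' @param payoff_variants A list of [payoff_matrix()] objects (at least one)
#'   describing the payoff states the decision maker may encounter.
#' @return An object of class `ev_envelope`: a list with
#'   * `curves`: long tibble with columns `x`, `curve`
#'     (`"min"`/`"mean"`/`"max"`), `value`;
#'   * `optima`: tibble with columns `curve`, `x_star`, `value`;
#'   * `variant_curves`: long tibble of the individual variant curves;
#'   * the environment, payoffs, scheme and mode used.
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15)
#' mean_pay <- payoff_matrix(100, -50, -50, 100)
#' variants <- list(
#'   payoff_matrix(100, -50, -90, 100),  # heavy rain: costly false alarm
#'   payoff_matrix(100, -50, -10, 100)   # light rain: mild false alarm
#' )
#' envp <- ev_envelope(env, mean_pay, variants)
#' envp$optima
#' @export
ev_envelope <- function(env, payoffs_mean, payoff_variants, scheme = NULL,
                        mode = c("ev", "value_weighted", "fully_weighted"),
                        bounds = NULL, n = 2001, complementary = FALSE) {
  mode <- match.arg(mode)
  assert_environment(env)
  assert_payoffs(payoffs_mean)
  if (!is.list(payoff_variants) || length(payoff_variants) < 1L) {
    abort("`payoff_variants` must be a non-empty list of payoff matrices",
          class = "sdtvalue_config_error")
  }
  purrr::walk(payoff_variants, assert_payoffs)
  if (is.null(bounds)) bounds <- env$domain_bounds

  if (is.null(names(payoff_variants))) {
    names(payoff_variants) <- paste0("variant_", seq_along(payoff_variants))
  }
  variant_vals <- purrr::imap(payoff_variants, function(p, nm) {
    cv <- ev_curve(env, p, scheme, mode = mode, bounds = bounds, n = n,
                   complementary = complementary)
    tibble(x = cv$x, curve = nm, value = cv$value)
  })
  variant_long <- dplyr::bind_rows(variant_vals)
  mean_curve <- ev_curve(env, payoffs_mean, scheme, mode = mode,
                         bounds = bounds, n = n, complementary = complementary)

  wide <- vapply(variant_vals, function(d) d$value, numeric(nrow(mean_curve)))
  wide <- matrix(wide, nrow = nrow(mean_curve))
  min_val <- apply(wide, 1L, min)
  max_val <- apply(wide, 1L, max)

  curves <- dplyr::bind_rows(
    tibble(x = mean_curve$x, curve = "min", value = min_val),
    tibble(x = mean_curve$x, curve = "mean", value = mean_curve$value),
    tibble(x = mean_curve$x, curve = "max", value = max_val)
  )

  # refine each bound's optimum against the pointwise-extreme function itself
  opt_extreme <- function(which) {
    f0 <- purrr::map(payoff_variants, function(p) {
      criterion_value_fn(env, p, scheme, mode, complementary)
    })
    f <- function(x) {
      vals <- vapply(f0, function(g) g(x), numeric(length(x)))
      vals <- matrix(vals, nrow = length(x))
      if (which == "min") apply(vals, 1L, min) else apply(vals, 1L, max)
    }
    grid_x <- mean_curve$x
    v <- if (which == "min") min_val else max_val
    i <- which.max(v)
    opt <- optimize(f, lower = grid_x[max(i - 1L, 1L)],
                    upper = grid_x[min(i + 1L, length(grid_x))],
                    maximum = TRUE, tol = 1e-6)
    if (opt$objective >= v[i]) c(opt$maximum, opt$objective) else c(grid_x[i], v[i])
  }
  o_min <- opt_extreme("min")
  o_max <- opt_extreme("max")
  o_mean <- optimal_criterion(env, payoffs_mean, scheme, mode = mode,
                              bounds = bounds, n = n,
                              complementary = complementary)

  structure(list(
    curves = curves,
    optima = tibble(
      curve = c("min", "mean", "max"),
      x_star = c(o_min[1], o_mean$x_star, o_max[1]),
      value = c(o_min[2], o_mean$value, o_max[2])
    ),
    variant_curves = variant_long,
    environment = env, payoffs_mean = payoffs_mean,
    payoff_variants = payoff_variants, scheme = scheme, mode = mode
  ), class = "ev_envelope")
}

#' @export
print.ev_envelope <- function(x, ...) {
  cat(sprintf("<ev_envelope>  %d variants, mode \"%s\"\n",
              length(x$payoff_variants), x$mode))
  print(x$optima)
  invisible(x)
}
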