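#' Define a payoff matrix for the four decision outcomes
#'
#' The four payoffs attached to the outcomes of a binary detection decision:
#' `h`, the benefit of a correct detection; `m`, the cost of a missed
#' detection; `a`, the cost of a false alarm; and `j`, the benefit of a
#' correct rejection. Costs may be negative or simply less positive than
#' benefits; a well-posed detection problem has `h > m` and `j > a` (being
#' right about each category pays better than being wrong about it).
#' Equality is tolerated at construction so that degenerate diagnostic cases
#' (e.g. a flat payoff matrix, under which every criterion is equally good)
#' can be expressed; the closed-form optimal-criterion solution rejects it
#' because the critical likelihood ratio is then undefined.
#'
#' @param h,m,a,j Payoffs for correct detection, missed detection, false
#'   alarm, and correct rejection.
#' @return An object of class `payoff_matrix` (a named list).
#'
#' @examples
#' payoff_matrix(h = 100, m = -50, a = -50, j = 100)
#' @export
payoff_matrix <- function(h, m, a, j) {
  for (v in list(h, m, a, j)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort("payoffs must be finite numeric scalars",
            class = "sdtvalue_invalid_payoffs")
    }
  }
  if (h < m || j < a) {
    abort("require h >= m and j >= a (a correct outcome cannot pay worse)",
          class = "sdtvalue_invalid_payoffs")
  }
  structure(list(h = h, m = m, a = a, j = j), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("<payoff_matrix>  h=%g  m=%g  a=%g  j=%g\n", x$h, x$m, x$a, x$j))
  invisible(x)
}

assert_payoffs <- function(payoffs) {
  if (!inherits(payoffs, "payoff_matrix")) {
    abort("`payoffs` must be a payoff_matrix()", class = "sdtvalue_invalid_payoffs")
  }
  invisible(payoffs)
}

#' Expected value of placing a criterion
#'
#' The signal-detection expected-value function: for a criterion at `x`, the
#' long-run average payoff per decision is
#'
#' `EV(x) = alpha*h*p[CD] + alpha*m*p[MD] + (1-alpha)*a*p[FA] + (1-alpha)*j*p[CR]`
#'
#' with outcome probabilities from [outcome_probabilities()] and base rate
#' `alpha` from the environment. The criterion with the highest expected
#' value is the optimal criterion on average over a series of decisions
#' (see [optimal_criterion()]).
#'
#' @inheritParams outcome_probabilities
#' @param payoffs A [payoff_matrix()].
#' @param criterion Numeric vector of criterion locations.
#' @return Numeric vector of expected values, in payoff units.
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15, base_rate = 0.5)
#' pay <- payoff_matrix(100, -50, -50, 100)
#' ev_at_criterion(env, pay, criterion = 50)
#' @export
ev_at_criterion <- function(env, payoffs, criterion) {
  assert_environment(env)
  assert_payoffs(payoffs)
  pr <- outcome_probabilities(env, criterion)
  al <- env$base_rate
  al * payoffs$h * pr$p_cd + al * payoffs$m * pr$p_md +
    (1 - al) * payoffs$a * pr$p_fa + (1 - al) * payoffs$j * pr$p_cr
}

#' Subjectively weighted utility of placing a criterion
#'
#' Two subjective generalizations of [ev_at_criterion()]:
#'
#' * `mode = "value_weighted"`: payoffs pass through the scheme's
#'   prospect-theory value function `V` while base rate and outcome
#'   probabilities remain objective --
#'   `U(x) = alpha*V(h)*p[CD] + alpha*V(m)*p[MD] + (1-alpha)*V(a)*p[FA] +
#'   (1-alpha)*V(j)*p[CR]`.
#' * `mode = "fully_weighted"`: additionally, the base-rate weight `B` is
#'   applied independently to `alpha` and `1 - alpha`, and the
#'   signal-probability weight `S` independently to each of the four outcome
#'   probabilities --
#'   `U(x) = B(alpha)*V(h)*S(p[CD]) + B(alpha)*V(m)*S(p[MD]) +
#'   B(1-alpha)*V(a)*S(p[FA]) + B(1-alpha)*V(j)*S(p[CR])`.
#'
#' Each probability is weighted independently, exactly as the weighted-sum
#' form is written: after weighting, `S(p[CD]) + S(p[MD])` need not equal 1
#' and `B(alpha) + B(1-alpha)` need not equal 1; no renormalization is
#' performed. Set `complementary = TRUE` to instead weight `p[CD]` and
#' `p[FA]` and take the complements for `p[MD]` and `p[CR]` (a sensitivity
#' analysis, not the default reading).
#'
#' With [scheme_identity()] both modes reduce exactly to the objective
#' expected value.
#'
#' @inheritParams ev_at_criterion
#' @param scheme A [weighting_scheme()].
#' @param mode `"value_weighted"` or `"fully_weighted"`.
#' @param complementary If `TRUE`, weighted miss and correct-rejection
#'   probabilities are taken as complements of the weighted hit and
#'   false-alarm probabilities.
#' @return Numeric vector of weighted utilities, in subjective-value units.
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15)
#' pay <- payoff_matrix(100, -50, -50, 100)
#' utility_at_criterion(env, pay, weighting_scheme(), 50, mode = "fully_weighted")
#' @export
utility_at_criterion <- function(env, payoffs, scheme, criterion,
                                 mode = c("value_weighted", "fully_weighted"),
                                 complementary = FALSE) {
  mode <- match.arg(mode)
  assert_environment(env)
  assert_payoffs(payoffs)
  if (!inherits(scheme, "weighting_scheme")) {
    abort("`scheme` must be a weighting_scheme()", class = "sdtvalue_invalid_scheme")
  }
  pr <- outcome_probabilities(env, criterion)
  V <- function(v) subjective_value(v, scheme$value_fn)
  al <- env$base_rate
  if (mode == "value_weighted") {
    w_t <- al; w_f <- 1 - al
    p_cd <- pr$p_cd; p_md <- pr$p_md; p_fa <- pr$p_fa; p_cr <- pr$p_cr
  } else {
    B <- function(p) probability_weight(p, scheme$base_rate_weight_fn)
    S <- function(p) probability_weight(p, scheme$signal_prob_weight_fn)
    w_t <- B(al); w_f <- B(1 - al)
    p_cd <- S(pr$p_cd); p_fa <- S(pr$p_fa)
    if (complementary) {
      p_md <- 1 - p_cd; p_cr <- 1 - p_fa
    } else {
      p_md <- S(pr$p_md); p_cr <- S(pr$p_cr)
    }
  }
  w_t * V(payoffs$h) * p_cd + w_t * V(payoffs$m) * p_md +
    w_f * V(payoffs$a) * p_fa + w_f * V(payoffs$j) * p_cr
}

# Shared dispatcher: the (weighted) value of a criterion under a given mode.
criterion_value_fn <- function(env, payoffs, scheme, mode, complementary = FALSE) {
  if (mode == "ev") {
    function(x) ev_at_criterion(env, payoffs, x)
  } else {
    if (is.null(scheme)) scheme <- weighting_scheme()
    function(x) utility_at_criterion(env, payoffs, scheme, x,
                                     mode = mode, complementary = complementary)
  }
}

#' Expected value (or weighted utility) over a criterion grid
#'
#' Evaluates [ev_at_criterion()] (`mode = "ev"`) or
#' [utility_at_criterion()] (other modes) over a regular grid of criterion
#' locations, together with the outcome probabilities at each point.
#'
#' @inheritParams utility_at_criterion
#' @param scheme A [weighting_scheme()]; required for the weighted modes and
#'   ignored for `mode = "ev"`.
#' @param mode One of `"ev"`, `"value_weighted"`, `"fully_weighted"`.
#' @param bounds Length-2 grid bounds; defaults to the environment's domain
#'   bounds.
#' @param n Number of grid points (>= 2; default 2001).
#' @return A tibble of class `ev_curve` with columns `x`, `p_cd`, `p_md`,
#'   `p_fa`, `p_cr`, `value`, carrying the environment, payoffs, scheme and
#'   mode as attributes.
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15)
#' pay <- payoff_matrix(100, -50, -50, 100)
#' curve <- ev_curve(env, pay)
#' curve[which.max(curve$value), ]
#' @export
ev_curve <- function(env, payoffs, scheme = NULL,
                     mode = c("ev", "value_weighted", "fully_weighted"),
                     bounds = NULL, n = 2001, complementary = FALSE) {
  mode <- match.arg(mode)
  assert_environment(env)
  assert_payoffs(payoffs)
  if (is.null(bounds)) bounds <- env$domain_bounds
  if (length(bounds) != 2L || !all(is.finite(bounds)) || bounds[1] >= bounds[2]) {
    abort("`bounds` must be an increasing pair of finite values",
          class = "sdtvalue_config_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("grid needs at least 2 points", class = "sdtvalue_config_error")
  }
  x <- seq(bounds[1], bounds[2], length.out = as.integer(n))
  f <- criterion_value_fn(env, payoffs, scheme, mode, complementary)
  out <- dplyr::mutate(outcome_probabilities(env, x), value = f(x))
  names(out)[names(out) == "criterion"] <- "x"
  structure(out,
            class = c("ev_curve", class(out)),
            environment = env, payoffs = payoffs,
            scheme = scheme, mode = mode)
}

#' Expected value with no perceptual uncertainty
#'
#' When target and foil are perceptually so distinct that misclassification
#' probabilities vanish, the criterion expected-value function collapses to
#' the constant `alpha * h + (1 - alpha) * j` -- the base-rate-weighted
#' average of the two options' own expected values, independent of where the
#' criterion is placed. This is the degenerate signal-detection problem that
#' classical economic choice between two distinct options corresponds to.
#'
#' @param alpha Base rate of the target option, in `[0, 1]`.
#' @param h Payoff (or expected value) of correctly taking the target option.
#' @param j Payoff (or expected value) of correctly taking the foil option.
#' @return A single number in payoff units.
#'
#' @examples
#' no_uncertainty_value(0.5, 45, 45) # 45
#' @export
no_uncertainty_value <- function(alpha, h, j) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1]", class = "sdtvalue_domain_error")
  }
  alpha * h + (1 - alpha) * j
}
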