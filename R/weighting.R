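#' Value-function constructors
#'
#' Parameterized families of subjective value functions used by
#' [weighted_valuation()] and the weighted criterion-utility functions.
#'
#' * `value_identity()` -- returns payoffs unchanged (objective value).
#' * `value_power(exponent)` -- power utility with sign preserved,
#'   `u(v) = sign(v) * |v|^exponent`; diminishing marginal utility for
#'   exponents below 1.
#' * `value_prospect(gain_exponent, loss_exponent, loss_aversion, reference)`
#'   -- the prospect-theory value function measured as deviation from a
#'   reference point `r`: `V(v) = (v - r)^gain_exponent` for gains and
#'   `V(v) = -loss_aversion * (r - v)^loss_exponent` for losses. It is
#'   concave over gains, convex over losses, and steeper for losses when
#'   `loss_aversion > 1` ("losses loom larger than gains").
#'
#' Defaults are the canonical estimates from cumulative prospect theory's
#' original calibration: exponents 0.88 and loss aversion 2.25.
#'
#' @param exponent,gain_exponent,loss_exponent Curvature parameters in (0, 1].
#' @param loss_aversion Loss-aversion multiplier, > 0 (values > 1 make losses
#'   loom larger).
#' @param reference Reference point `r` separating gains from losses
#'   (default 0, status-quo framing).
#' @return An object of class `value_fn`.
#' @name value_functions
NULL

#' @rdname value_functions
#' @export
value_identity <- function() {
  structure(list(family = "identity"), class = "value_fn")
}

#' @rdname value_functions
#' @export
value_power <- function(exponent = 0.88) {
  check_exponent(exponent, "exponent")
  structure(list(family = "power", exponent = exponent), class = "value_fn")
}

#' @rdname value_functions
#' @export
value_prospect <- function(gain_exponent = 0.88, loss_exponent = 0.88,
                           loss_aversion = 2.25, reference = 0) {
  check_exponent(gain_exponent, "gain_exponent")
  check_exponent(loss_exponent, "loss_exponent")
  if (!is.numeric(loss_aversion) || length(loss_aversion) != 1L || loss_aversion <= 0) {
    abort("`loss_aversion` must be a positive scalar",
          class = "sdtvalue_invalid_scheme")
  }
  if (!is.numeric(reference) || length(reference) != 1L || !is.finite(reference)) {
    abort("`reference` must be a finite scalar", class = "sdtvalue_invalid_scheme")
  }
  structure(list(
    family = "prospect",
    gain_exponent = gain_exponent, loss_exponent = loss_exponent,
    loss_aversion = loss_aversion, reference = reference
  ), class = "value_fn")
}

check_exponent <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1) {
    abort(sprintf("`%s` must lie in (0, 1]", name),
          class = "sdtvalue_invalid_scheme")
  }
  invisible(x)
}

#' Probability-weighting constructors
#'
#' * `weight_identity()` -- decision weights equal stated probabilities.
#' * `weight_tk1992(delta)` -- the one-parameter inverse-S weighting function
#'   `w(p) = p^delta / (p^delta + (1-p)^delta)^(1/delta)`. For `delta < 1` it
#'   overweights small probabilities and underweights large ones while
#'   preserving the endpoints `w(0) = 0`, `w(1) = 1`. `delta` must lie in
#'   (0.28, 1]; below about 0.28 this functional form is no longer monotone.
#'
#' @param delta Curvature parameter in (0.28, 1]; default 0.61, the canonical
#'   gain-domain estimate.
#' @return An object of class `prob_weight_fn`.
#' @name weight_functions
NULL

#' @rdname weight_functions
#' @export
weight_identity <- function() {
  structure(list(family = "identity"), class = "prob_weight_fn")
}

#' @rdname weight_functions
#' @export
weight_tk1992 <- function(delta = 0.61) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0.28 || delta > 1) {
    abort("`delta` must lie in (0.28, 1] (monotonicity bound)",
          class = "sdtvalue_invalid_scheme")
  }
  structure(list(family = "tk1992", delta = delta), class = "prob_weight_fn")
}

#' Bundle subjective weighting functions into a scheme
#'
#' A weighting scheme collects the four subjective transforms used across the
#' package: a value function for payoffs, a probability-weighting function
#' for stated gamble probabilities, and -- for the weighted criterion-utility
#' function -- a base-rate weight `B` applied to the target/foil base rates
#' and a signal-probability weight `S` applied to the four outcome
#' probabilities.
#'
#' The default scheme is fully subjective: prospect value function and
#' inverse-S weighting with the canonical parameters, applied everywhere.
#' [scheme_identity()] returns the fully objective scheme, under which every
#' weighted valuation reduces exactly to its expected-value counterpart.
#'
#' @param value_fn A value function (see [value_functions]).
#' @param prob_weight_fn Probability weight for gamble outcome probabilities.
#' @param base_rate_weight_fn Weight `B` applied independently to the base
#'   rate and its complement (no forced complementarity).
#' @param signal_prob_weight_fn Weight `S` applied independently to each of
#'   the four outcome probabilities (no renormalization; see
#'   [utility_at_criterion()]).
#' @return An object of class `weighting_scheme`.
#'
#' @examples
#' weighting_scheme()    # canonical subjective defaults
#' scheme_identity()     # reduces every valuation to objective expected value
#' @export
weighting_scheme <- function(value_fn = value_prospect(),
                             prob_weight_fn = weight_tk1992(),
                             base_rate_weight_fn = weight_tk1992(),
                             signal_prob_weight_fn = weight_tk1992()) {
  if (!inherits(value_fn, "value_fn")) {
    abort("`value_fn` must be built with value_identity(), value_power() or value_prospect()",
          class = "sdtvalue_invalid_scheme")
  }
  for (w in list(prob_weight_fn, base_rate_weight_fn, signal_prob_weight_fn)) {
    if (!inherits(w, "prob_weight_fn")) {
      abort("weight functions must be built with weight_identity() or weight_tk1992()",
            class = "sdtvalue_invalid_scheme")
    }
  }
  structure(list(
    value_fn = value_fn,
    prob_weight_fn = prob_weight_fn,
    base_rate_weight_fn = base_rate_weight_fn,
    signal_prob_weight_fn = signal_prob_weight_fn
  ), class = "weighting_scheme")
}

#' @rdname weighting_scheme
#' @export
scheme_identity <- function() {
  weighting_scheme(
    value_fn = value_identity(),
    prob_weight_fn = weight_identity(),
    base_rate_weight_fn = weight_identity(),
    signal_prob_weight_fn = weight_identity()
  )
}

#' @export
print.weighting_scheme <- function(x, ...) {
  fmt <- function(f) {
    ps <- f[setdiff(names(f), "family")]
    if (!length(ps)) return(f$family)
    sprintf("%s(%s)", f$family,
            paste(sprintf("%s=%g", names(ps), unlist(ps)), collapse = ", "))
  }
  cat("<weighting_scheme>\n")
  cat("  value:        ", fmt(x$value_fn), "\n")
  cat("  probability:  ", fmt(x$prob_weight_fn), "\n")
  cat("  base rate B:  ", fmt(x$base_rate_weight_fn), "\n")
  cat("  signal prob S:", fmt(x$signal_prob_weight_fn), "\n")
  invisible(x)
}

is_identity_scheme <- function(scheme) {
  is.null(scheme) ||
    (inherits(scheme, "weighting_scheme") &&
       all(vapply(scheme, function(f) f$family == "identity", logical(1))))
}

#' Subjective value of a payoff
#'
#' Applies a value function (or the value function of a scheme) to objective
#' payoffs.
#'
#' @param v Numeric vector of payoffs.
#' @param scheme A `value_fn` or a [weighting_scheme()].
#' @return Numeric vector of subjective values.
#'
#' @examples
#' subjective_value(c(-100, 0, 100), value_prospect())
#' @export
subjective_value <- function(v, scheme = weighting_scheme()) {
  fn <- if (inherits(scheme, "weighting_scheme")) scheme$value_fn else scheme
  if (!inherits(fn, "value_fn")) {
    abort("`scheme` must be a value function or weighting scheme",
          class = "sdtvalue_invalid_scheme")
  }
  switch(fn$family,
    identity = v,
    power = sign(v) * abs(v)^fn$exponent,
    prospect = {
      dev <- v - fn$reference
      ifelse(dev >= 0,
             dev^fn$gain_exponent,
             -fn$loss_aversion * (-dev)^fn$loss_exponent)
    }
  )
}

#' Decision weight of a probability
#'
#' Applies a probability-weighting function to probabilities in `[0, 1]`.
#' The inverse-S family preserves the endpoints and, for curvature below 1,
#' returns weights greater than small stated probabilities and smaller than
#' large ones.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param fn A `prob_weight_fn` (see [weight_functions]).
#' @return Numeric vector of decision weights.
#'
#' @examples
#' probability_weight(c(0.01, 0.5, 0.99), weight_tk1992(0.61))
#' @export
probability_weight <- function(p, fn = weight_tk1992()) {
  if (!inherits(fn, "prob_weight_fn")) {
    abort("`fn` must be built with weight_identity() or weight_tk1992()",
          class = "sdtvalue_invalid_scheme")
  }
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1]", class = "sdtvalue_domain_error")
  }
  switch(fn$family,
    identity = p,
    tk1992 = {
      d <- fn$delta
      p^d / (p^d + (1 - p)^d)^(1 / d)
    }
  )
}

#' Subjective valuation of a gamble
#'
#' Valuation under the two classical generalizations of expected value:
#'
#' * `mode = "utility"`: `sum(p_i * u(v_i))` -- probabilities enter raw,
#'   payoffs pass through the scheme's value function (expected utility).
#' * `mode = "prospect"`: `sum(w(p_i) * V(v_i))` -- payoffs pass through the
#'   value function and each stated probability is transformed independently
#'   by the scheme's probability-weighting function (non-cumulative; decision
#'   weights are not rank-dependent and need not sum to 1).
#'
#' With an all-identity scheme both modes reduce exactly to
#' [expected_value()].
#'
#' @inheritParams expected_value
#' @param scheme A [weighting_scheme()].
#' @param mode `"prospect"` (default) or `"utility"`.
#' @return A single number in subjective-value units.
#'
#' @examples
#' bike <- gamble(c(0.5, 0.25, 0.25), c(100, -10, -90), label = "bike")
#' weighted_valuation(bike, weighting_scheme(), mode = "prospect")
#' weighted_valuation(bike, scheme_identity()) == expected_value(bike)
#' @export
weighted_valuation <- function(g, scheme = weighting_scheme(),
                               mode = c("prospect", "utility")) {
  mode <- match.arg(mode)
  validate_gamble(g)
  if (!inherits(scheme, "weighting_scheme")) {
    abort("`scheme` must be a weighting_scheme()", class = "sdtvalue_invalid_scheme")
  }
  vals <- subjective_value(g$value, scheme$value_fn)
  wts <- if (mode == "utility") g$probability
         else probability_weight(g$probability, scheme$prob_weight_fn)
  sum(wts * vals)
}
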