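#' Define a perceptual decision environment
#'
#' A perceptual environment describes a one-dimensional signal-detection
#' problem: signals arise from a Gaussian *target* distribution with
#' probability `base_rate` and from a Gaussian *foil* distribution otherwise.
#' An observer places a decision criterion on the signal axis and responds
#' "target" whenever the observed signal is at or beyond the criterion (on the
#' target side).
#'
#' Signal-domain units are opaque labels (percent chance of rain, scowl
#' intensity, a biomarker concentration, ...) carried through to output; no
#' unit arithmetic is performed.
#'
#' If `mu_target < mu_foil`, the environment is stored as given but flagged
#' internally so that all computations run in a canonical orientation (target
#' distribution to the right of the foil distribution); criteria in all inputs
#' and outputs remain in user coordinates.
#'
#' @param mu_target,mu_foil Means of the target and foil signal distributions.
#' @param sigma_target,sigma_foil Standard deviations (> 0). `sigma_foil`
#'   defaults to `sigma_target` (the equal-variance model).
#' @param base_rate Probability in (0, 1) that an encountered signal comes
#'   from the target distribution.
#' @param domain_bounds Length-2 numeric giving the signal-domain extent used
#'   for curve grids and simulation bounds. Must enclose both means +/- 6
#'   standard deviations; defaults to exactly that range.
#' @param units Optional label for the signal axis, used in printing and
#'   plotting.
#'
#' @return An object of class `perceptual_environment`: a list with fields
#'   `mu_target`, `mu_foil`, `sigma_target`, `sigma_foil`, `base_rate`,
#'   `domain_bounds`, `units`, and the internal orientation flag `flipped`.
#'
#' @examples
#' # The bike-or-drive weather example: signal is % chance of rain
#' env <- perceptual_environment(
#'   mu_target = 60, mu_foil = 40, sigma_target = 15,
#'   base_rate = 0.5, units = "% chance of rain"
#' )
#' env
#' @export
perceptual_environment <- function(mu_target, mu_foil,
                                   sigma_target, sigma_foil = sigma_target,
                                   base_rate = 0.5,
                                   domain_bounds = NULL,
                                   units = "signal") {
  stop_env <- function(msg) abort(msg, class = "sdtvalue_invalid_environment")
  for (v in list(mu_target, mu_foil, sigma_target, sigma_foil, base_rate)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_env("environment parameters must be finite numeric scalars")
    }
  }
  if (sigma_target <= 0 || sigma_foil <= 0) {
    stop_env("`sigma_target` and `sigma_foil` must be > 0")
  }
  if (base_rate <= 0 || base_rate >= 1) {
    stop_env("`base_rate` must lie strictly between 0 and 1")
  }
  sig_max <- max(sigma_target, sigma_foil)
  lo <- min(mu_target, mu_foil) - 6 * sig_max
  hi <- max(mu_target, mu_foil) + 6 * sig_max
  if (is.null(domain_bounds)) {
    domain_bounds <- c(lo, hi)
  } else {
    if (length(domain_bounds) != 2L || !all(is.finite(domain_bounds)) ||
        domain_bounds[1] >= domain_bounds[2]) {
      stop_env("`domain_bounds` must be an increasing pair of finite values")
    }
    if (domain_bounds[1] > lo || domain_bounds[2] < hi) {
      stop_env("`domain_bounds` must enclose both means +/- 6 standard deviations")
    }
  }
  structure(
    list(
      mu_target = mu_target, mu_foil = mu_foil,
      sigma_target = sigma_target, sigma_foil = sigma_foil,
      base_rate = base_rate,
      domain_bounds = as.numeric(domain_bounds),
      units = units,
      flipped = mu_target < mu_foil
    ),
    class = "perceptual_environment"
  )
}

#' @export
print.perceptual_environment <- function(x, ...) {
  cat("<perceptual_environment>\n")
  cat(sprintf("  target: N(%g, %g^2)   foil: N(%g, %g^2)\n",
              x$mu_target, x$sigma_target, x$mu_foil, x$sigma_foil))
  cat(sprintf("  base rate (target): %g   units: %s\n", x$base_rate, x$units))
  cat(sprintf("  domain: [%g, %g]%s\n", x$domain_bounds[1], x$domain_bounds[2],
              if (x$flipped) "   (target below foil; axis flipped internally)" else ""))
  invisible(x)
}

is_environment <- function(x) inherits(x, "perceptual_environment")

assert_environment <- function(env) {
  if (!is_environment(env)) {
    abort("`env` must be a `perceptual_environment` object",
          class = "sdtvalue_invalid_environment")
  }
  invisible(env)
}

# Map to the canonical orientation (target on the right). Criterion values map
# as x -> -x when flipped; distribution means are negated likewise.
canonical_env <- function(env) {
  if (!env$flipped) return(env)
  out <- env
  out$mu_target <- -env$mu_target
  out$mu_foil <- -env$mu_foil
  out$domain_bounds <- rev(-env$domain_bounds)
  out$flipped <- FALSE
  out
}

to_canonical_x <- function(env, x) if (env$flipped) -x else x
from_canonical_x <- to_canonical_x

#' Outcome probabilities at a decision criterion
#'
#' Computes the probabilities of the four decision outcomes -- correct
#' detection (CD), missed detection (MD), false alarm (FA), and correct
#' rejection (CR) -- for an observer who responds "target" iff the signal is
#' at or beyond the criterion on the target side. `p_cd` is the tail integral
#' of the target density beyond the criterion and `p_fa` the same integral of
#' the foil density; `p_md = 1 - p_cd`, `p_cr = 1 - p_fa`. Tail integrals use
#' the normal distribution function directly (complementary-error-function
#' accuracy), not quadrature.
#'
#' @param env A [perceptual_environment()].
#' @param criterion Numeric vector of criterion locations in signal-domain
#'   units. `-Inf`/`Inf` are accepted and treated as limits (respond "target"
#'   always / never).
#'
#' @return A tibble with one row per criterion and columns `criterion`,
#'   `p_cd`, `p_md`, `p_fa`, `p_cr`.
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15)
#' outcome_probabilities(env, criterion = c(35, 50, 65))
#' @export
outcome_probabilities <- function(env, criterion) {
  assert_environment(env)
  if (!is.numeric(criterion) || any(is.na(criterion))) {
    abort("`criterion` must be numeric and non-missing")
  }
  ce <- canonical_env(env)
  x <- to_canonical_x(env, criterion)
  p_cd <- pnorm(x, ce$mu_target, ce$sigma_target, lower.tail = FALSE)
  p_fa <- pnorm(x, ce$mu_foil, ce$sigma_foil, lower.tail = FALSE)
  tibble(
    criterion = criterion,
    p_cd = p_cd, p_md = 1 - p_cd,
    p_fa = p_fa, p_cr = 1 - p_fa
  )
}

#' Likelihood ratio of target to foil at a signal value
#'
#' Ratio of the target to the foil Gaussian density at `x`. At the decision
#' criterion this ratio is the bias measure beta; the optimal criterion under
#' the expected-value rule is where it equals the critical likelihood ratio
#' set by payoffs and base rate.
#'
#' @inheritParams outcome_probabilities
#' @param x Numeric vector of signal values.
#' @return Numeric vector of density ratios.
#' @export
likelihood_ratio <- function(env, x) {
  assert_environment(env)
  dnorm(x, env$mu_target, env$sigma_target) / dnorm(x, env$mu_foil, env$sigma_foil)
}

#' Sensitivity and bias from hit and false-alarm rates
#'
#' The standard equal-variance signal-detection measures: sensitivity
#' `d_prime = z(p_cd) - z(p_fa)`, criterion offset
#' `c = -(z(p_cd) + z(p_fa)) / 2`, and the likelihood-ratio bias
#' `beta = exp(d_prime * c)` (the ratio of target to foil densities at the
#' implied criterion, in standardized units).
#'
#' Rates of exactly 0 or 1 have no finite z-transform; apply a boundary
#' correction first (see [estimate_from_counts()]).
#'
#' @param p_cd Hit (correct-detection) rates in (0, 1), or a data frame with
#'   columns `p_cd` and `p_fa` such as [outcome_probabilities()] returns.
#' @param p_fa False-alarm rates in (0, 1). Ignored when `p_cd` is a data
#'   frame.
#'
#' @return A tibble with columns `d_prime`, `c`, `beta`.
#'
#' @examples
#' sdt_measures(0.7475, 0.2525)
#' env <- perceptual_environment(60, 40, 15)
#' sdt_measures(outcome_probabilities(env, 50))
#' @export
sdt_measures <- function(p_cd, p_fa = NULL) {
  if (is.data.frame(p_cd)) {
    dat <- p_cd
    if (!all(c("p_cd", "p_fa") %in% names(dat))) {
      abort("data frame input must have columns `p_cd` and `p_fa`")
    }
    p_fa <- dat$p_fa
    p_cd <- dat$p_cd
  }
  if (length(p_cd) != length(p_fa)) abort("`p_cd` and `p_fa` must have equal length")
  if (any(p_cd <= 0 | p_cd >= 1 | p_fa <= 0 | p_fa >= 1)) {
    abort(paste0(
      "rates must lie strictly between 0 and 1; ",
      "boundary rates have no finite z-transform -- use estimate_from_counts() ",
      "with a correction (e.g. \"log_linear\")"
    ), class = "sdtvalue_boundary_rate")
  }
  zc <- qnorm(p_cd)
  zf <- qnorm(p_fa)
  d_prime <- zc - zf
  cc <- -(zc + zf) / 2
  tibble(d_prime = d_prime, c = cc, beta = exp(d_prime * cc))
}

#' Sensitivity and bias of a criterion in a known environment
#'
#' Environment-aware counterpart of [sdt_measures()]: computes the outcome
#' probabilities at `criterion` and derives `d_prime`, `c`, and `beta`. For
#' unequal variances the conventions are: `beta` is the actual ratio of target
#' to foil densities at the criterion, and `d_prime` standardizes the mean
#' separation by the root-mean-square of the two standard deviations.
#'
#' @inheritParams outcome_probabilities
#' @return A tibble with columns `criterion`, `d_prime`, `c`, `beta`.
#' @export
sdt_at_criterion <- function(env, criterion) {
  assert_environment(env)
  ce <- canonical_env(env)
  sig_rms <- sqrt((ce$sigma_target^2 + ce$sigma_foil^2) / 2)
  d_prime <- (ce$mu_target - ce$mu_foil) / sig_rms
  xc <- to_canonical_x(env, criterion)
  cc <- (xc - (ce$mu_target + ce$mu_foil) / 2) / sig_rms
  tibble(
    criterion = criterion,
    d_prime = d_prime,
    c = cc,
    beta = dnorm(xc, ce$mu_target, ce$sigma_target) /
      dnorm(xc, ce$mu_foil, ce$sigma_foil)
  )
}

#' Estimate sensitivity and bias from outcome counts
#'
#' Converts a confusion tally into hit and false-alarm rates, applies a
#' boundary correction, and returns the [sdt_measures()] estimates. With
#' `correction = "log_linear"` (the default), 0.5 is added to each cell and 1
#' to each denominator, which keeps estimates finite with small bias; with
#' `"half_count"`, rates of 0 and 1 are replaced by `1/(2N)` and `1 - 1/(2N)`;
#' with `"none"`, boundary rates raise an error.
#'
#' @param counts A data frame or named list with fields `n_cd`, `n_md`,
#'   `n_fa`, `n_cr` (as returned by [tally()]).
#' @param correction One of `"log_linear"`, `"half_count"`, `"none"`.
#'
#' @return A tibble with columns `d_prime`, `c`, `beta`, `p_cd`, `p_fa`
#'   (the corrected rates actually used).
#'
#' @examples
#' estimate_from_counts(list(n_cd = 45, n_md = 5, n_fa = 5, n_cr = 45))
#' @export
estimate_from_counts <- function(counts,
                                 correction = c("log_linear", "half_count", "none")) {
  correction <- match.arg(correction)
  need <- c("n_cd", "n_md", "n_fa", "n_cr")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have fields n_cd, n_md, n_fa, n_cr")
  }
  n <- lapply(need, function(k) as.numeric(counts[[k]]))
  names(n) <- need
  if (any(vapply(n, function(v) length(v) != 1L || is.na(v) || v < 0, logical(1)))) {
    abort("counts must be nonnegative scalars")
  }
  n_target <- n$n_cd + n$n_md
  n_foil <- n$n_fa + n$n_cr
  if (n_target == 0 || n_foil == 0) {
    abort("need at least one target-category and one foil-category trial")
  }
  rate <- function(k, N) {
    switch(correction,
      log_linear = (k + 0.5) / (N + 1),
      half_count = {
        p <- k / N
        if (p == 0) 1 / (2 * N) else if (p == 1) 1 - 1 / (2 * N) else p
      },
      none = k / N
    )
  }
  p_cd <- rate(n$n_cd, n_target)
  p_fa <- rate(n$n_fa, n_foil)
  if (correction == "none" && (p_cd %in% c(0, 1) || p_fa %in% c(0, 1))) {
    abort(paste0(
      "a rate is exactly 0 or 1; choose correction = \"log_linear\" or ",
      "\"half_count\" for finite estimates"
    ), class = "sdtvalue_boundary_rate")
  }
  dplyr::mutate(sdt_measures(p_cd, p_fa), p_cd = p_cd, p_fa = p_fa)
}
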