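#' Simulate a criterion-based observer
#'
#' Draws `n` independent trials from a perceptual environment and records the
#' decisions of an observer holding a fixed criterion. Each trial draws its
#' category (target with probability `base_rate`), then its signal from that
#' category's Gaussian; the observer responds "target" iff the signal is at
#' or beyond the criterion on the target side (ties count as target
#' responses). The outcome label crosses category with response -- CD
#' (target/target), MD (target/foil), FA (foil/target), CR (foil/foil) --
#' and the payoff is the corresponding payoff-matrix entry.
#'
#' The random stream is fully determined by `seed`: all category draws are
#' made first, then all signal draws, so identical inputs give identical
#' trial tables.
#'
#' @inheritParams ev_at_criterion
#' @param criterion The observer's fixed criterion, in signal-domain units.
#' @param n Number of trials (>= 0).
#' @param seed Integer seed fixing the simulation stream.
#' @return A tibble with columns `index`, `category`, `signal`, `response`,
#'   `outcome`, `payoff`.
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15)
#' pay <- payoff_matrix(100, -50, -50, 100)
#' trials <- simulate_trials(env, pay, criterion = 50, n = 10, seed = 1)
#' trials
#' @export
simulate_trials <- function(env, payoffs, criterion, n, seed = NULL) {
  assert_environment(env)
  assert_payoffs(payoffs)
  if (!is.numeric(criterion) || length(criterion) != 1L || !is.finite(criterion)) {
    abort("`criterion` must be a finite scalar")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    abort("`n` must be a nonnegative integer")
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble(
      index = integer(), category = character(), signal = numeric(),
      response = character(), outcome = character(), payoff = numeric()
    ))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  is_target <- runif(n) < env$base_rate
  mu <- ifelse(is_target, env$mu_target, env$mu_foil)
  sg <- ifelse(is_target, env$sigma_target, env$sigma_foil)
  signal <- rnorm(n, mean = mu, sd = sg)
  resp_target <- if (env$flipped) signal <= criterion else signal >= criterion
  category <- ifelse(is_target, "target", "foil")
  response <- ifelse(resp_target, "target", "foil")
  outcome <- classify_outcome(category, response)
  tibble(
    index = seq_len(n),
    category = category,
    signal = signal,
    response = response,
    outcome = outcome,
    payoff = unname(c(payoffs$h, payoffs$m, payoffs$a, payoffs$j)[
      match(outcome, c("CD", "MD", "FA", "CR"))])
  )
}

classify_outcome <- function(category, response) {
  dplyr::case_when(
    category == "target" & response == "target" ~ "CD",
    category == "target" & response == "foil" ~ "MD",
    category == "foil" & response == "target" ~ "FA",
    category == "foil" & response == "foil" ~ "CR"
  )
}

#' Tally decision outcomes
#'
#' Collapses a trial table into the four outcome counts and the mean accrued
#' payoff.
#'
#' @param trials A trial tibble as produced by [simulate_trials()] or
#'   [read_trials()].
#' @return A one-row tibble with columns `n_cd`, `n_md`, `n_fa`, `n_cr`, `n`,
#'   `mean_payoff`.
#' @export
tally <- function(trials) {
  if (!is.data.frame(trials) || !all(c("outcome", "payoff") %in% names(trials))) {
    abort("`trials` must be a data frame with `outcome` and `payoff` columns")
  }
  cnt <- function(k) sum(trials$outcome == k)
  tibble(
    n_cd = cnt("CD"), n_md = cnt("MD"), n_fa = cnt("FA"), n_cr = cnt("CR"),
    n = nrow(trials),
    mean_payoff = if (nrow(trials)) mean(trials$payoff) else NA_real_
  )
}

#' Bernoulli log-likelihood of observed responses given signals
#'
#' The probability that a criterion-observer with criterion `criterion` and
#' criterion jitter `softness` (standard deviation of trial-to-trial
#' criterion noise) responds "target" to a signal `s` is
#' `pnorm((s - criterion) / softness)` (reversed for environments whose
#' target lies below the foil). This function returns the summed Bernoulli
#' log-likelihood of the recorded responses. As `softness -> 0` the response
#' rule becomes the deterministic step used by [simulate_trials()].
#'
#' @param trials A trial tibble with `signal` and `response` columns.
#' @param criterion Candidate criterion location.
#' @param softness Criterion-noise standard deviation, > 0.
#' @param flipped Set `TRUE` for environments whose target distribution lies
#'   below the foil distribution.
#' @return The log-likelihood (a scalar, possibly very negative).
#' @export
observer_loglik <- function(trials, criterion, softness, flipped = FALSE) {
  if (softness <= 0) abort("`softness` must be > 0")
  z <- (trials$signal - criterion) / softness
  if (flipped) z <- -z
  lp_t <- pnorm(z, log.p = TRUE)
  lp_f <- pnorm(z, log.p = TRUE, lower.tail = FALSE)
  sum(ifelse(trials$response == "target", lp_t, lp_f))
}

#' Recover observer parameters from trial data
#'
#' Estimates sensitivity, bias, and the criterion location of the observer
#' that generated a trial table.
#'
#' * `method = "counts_analytic"`: tallies outcomes, corrects boundary rates
#'   ([estimate_from_counts()]), and returns the closed-form `d_prime`, `c`,
#'   `beta`. With a known environment, the criterion estimate maps `c` back
#'   to signal units: `x = (mu_t + mu_f)/2 + c * sigma_rms`.
#' * `method = "trialwise_ml"`: maximizes the Bernoulli likelihood of the
#'   recorded responses given the recorded signals ([observer_loglik()])
#'   jointly over the criterion and the criterion-noise scale. When the
#'   responses are perfectly separable in the signal -- as they always are
#'   for a deterministic criterion observer -- the likelihood is maximized
#'   (at its supremum, log-likelihood 0) by any criterion inside the
#'   separating gap with vanishing noise; the fit then reports the gap
#'   midpoint with the noise scale at its lower bound, exactly. Otherwise a
#'   bounded quasi-Newton search restarted from three jittered initial
#'   values estimates both parameters. Sensitivity measures are still taken
#'   from the counts. Non-convergence is flagged, never silent.
#'
#' @param trials A trial tibble (needs `signal` and `response` columns for
#'   `trialwise_ml`; `outcome` for the counts).
#' @param env The generating [perceptual_environment()], used to express the
#'   criterion in signal units (optional for `counts_analytic`, required for
#'   `trialwise_ml` bounds).
#' @param method `"counts_analytic"` or `"trialwise_ml"`.
#' @param correction Boundary-rate correction passed to
#'   [estimate_from_counts()].
#' @return An object of class `observer_fit` with [tidy()] and [glance()]
#'   methods; `$estimates` holds a one-row tibble with `d_prime`, `c`,
#'   `beta`, `criterion` (and `softness` for `trialwise_ml`).
#'
#' @examples
#' env <- perceptual_environment(60, 40, 15)
#' pay <- payoff_matrix(100, -50, -50, 100)
#' trials <- simulate_trials(env, pay, criterion = 50, n = 2000, seed = 7)
#' fit <- fit_observer(trials, env)
#' tidy(fit)
#' @export
fit_observer <- function(trials, env = NULL,
                         method = c("counts_analytic", "trialwise_ml"),
                         correction = "log_linear") {
  method <- match.arg(method)
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    abort("`trials` must be a non-empty trial table")
  }
  counts <- tally(trials)
  est <- estimate_from_counts(counts, correction = correction)

  crit_counts <- NA_real_
  if (!is.null(env)) {
    assert_environment(env)
    ce <- canonical_env(env)
    sig_rms <- sqrt((ce$sigma_target^2 + ce$sigma_foil^2) / 2)
    xc <- (ce$mu_target + ce$mu_foil) / 2 + est$c * sig_rms
    crit_counts <- from_canonical_x(env, xc)
  }

  if (method == "counts_analytic") {
    estimates <- tibble(
      d_prime = est$d_prime, c = est$c, beta = est$beta, criterion = crit_counts
    )
    return(new_observer_fit(estimates, method, TRUE, NA_real_, counts))
  }

  if (is.null(env)) abort("`trialwise_ml` needs `env` for search bounds")
  if (!all(c("signal", "response") %in% names(trials))) {
    abort("`trialwise_ml` needs `signal` and `response` columns")
  }
  sig_scale <- max(env$sigma_target, env$sigma_foil)

  # Perfectly separable responses: the ML criterion set is the gap between
  # the largest foil-response signal and the smallest target-response signal
  # (orientation-dependent); report its midpoint with vanishing noise.
  s_can <- if (env$flipped) -trials$signal else trials$signal
  s_t <- s_can[trials$response == "target"]
  s_f <- s_can[trials$response == "foil"]
  gap_lo <- if (length(s_f)) max(s_f) else -Inf
  gap_hi <- if (length(s_t)) min(s_t) else Inf
  if (gap_lo < gap_hi) {
    mid_can <- if (is.finite(gap_lo) && is.finite(gap_hi)) (gap_lo + gap_hi) / 2
               else if (is.finite(gap_lo)) gap_lo else if (is.finite(gap_hi)) gap_hi
               else mean(env$domain_bounds)
    estimates <- tibble(
      d_prime = est$d_prime, c = est$c, beta = est$beta,
      criterion = if (env$flipped) -mid_can else mid_can,
      softness = sig_scale * 1e-3
    )
    return(new_observer_fit(estimates, method, TRUE, 0, counts))
  }

  lb <- c(env$domain_bounds[1], log(sig_scale * 1e-3))
  ub <- c(env$domain_bounds[2], log(sig_scale * 10))
  nll <- function(par) {
    -observer_loglik(trials, par[1], exp(par[2]), flipped = env$flipped)
  }
  x0 <- if (is.finite(crit_counts)) crit_counts else mean(env$domain_bounds)
  starts <- list(
    c(x0, log(sig_scale * 0.1)),
    c(x0 + sig_scale, log(sig_scale * 0.5)),
    c(x0 - sig_scale, log(sig_scale * 0.02))
  )
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    s[1] <- min(max(s[1], lb[1]), ub[1])
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    warn("trialwise_ml failed to converge from all starts; returning count-based estimates")
    estimates <- tibble(
      d_prime = est$d_prime, c = est$c, beta = est$beta,
      criterion = crit_counts, softness = NA_real_
    )
    return(new_observer_fit(estimates, method, FALSE, NA_real_, counts))
  }
  estimates <- tibble(
    d_prime = est$d_prime, c = est$c, beta = est$beta,
    criterion = best$par[1], softness = exp(best$par[2])
  )
  new_observer_fit(estimates, method, converged, -best$value, counts)
}

new_observer_fit <- function(estimates, method, converged, logLik, counts) {
  structure(list(
    estimates = estimates, method = method, converged = converged,
    logLik = logLik, counts = counts
  ), class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("<observer_fit>  method: %s  converged: %s\n",
              x$method, x$converged))
  print(x$estimates)
  invisible(x)
}

#' Grid search over subjective-weighting parameters (experimental)
#'
#' An exploratory routine, not an estimator with established identification:
#' given trial data, it fits the observer's empirical criterion and then
#' scores every candidate combination of loss aversion, value curvature, and
#' probability-weighting curvature by how closely the optimal criterion of
#' the implied fully-weighted utility function matches the fitted criterion.
#' Many parameter combinations can predict the same criterion; treat the
#' result as a compatibility region, not a point estimate.
#'
#' @inheritParams fit_observer
#' @param payoffs The [payoff_matrix()] the observer faced.
#' @param loss_aversion,exponent,delta Numeric vectors of candidate values;
#'   the full crossing is evaluated.
#' @return A tibble with one row per parameter combination, the predicted
#'   optimal criterion `x_star_pred`, and `score` (squared distance to the
#'   fitted criterion), sorted by score.
#' @export
fit_weighting_grid <- function(trials, env, payoffs,
                               loss_aversion = c(1, 1.5, 2.25, 3),
                               exponent = c(0.7, 0.88, 1),
                               delta = c(0.4, 0.61, 0.8, 1),
                               method = "counts_analytic") {
  fit <- fit_observer(trials, env, method = method)
  x_hat <- fit$estimates$criterion
  grid <- tidyr::expand_grid(
    loss_aversion = loss_aversion, exponent = exponent, delta = delta
  )
  grid$x_star_pred <- purrr::pmap_dbl(grid, function(loss_aversion, exponent, delta) {
    scheme <- weighting_scheme(
      value_fn = value_prospect(gain_exponent = exponent, loss_exponent = exponent,
                                loss_aversion = loss_aversion),
      prob_weight_fn = if (delta == 1) weight_identity() else weight_tk1992(delta),
      base_rate_weight_fn = if (delta == 1) weight_identity() else weight_tk1992(delta),
      signal_prob_weight_fn = if (delta == 1) weight_identity() else weight_tk1992(delta)
    )
    optimal_criterion(env, payoffs, scheme, mode = "fully_weighted")$x_star
  })
  grid$score <- (grid$x_star_pred - x_hat)^2
  dplyr::arrange(grid, .data$score)
}
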