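#' Tidy an observer fit
#'
#' One row per estimated quantity, broom-style.
#'
#' @param x An `observer_fit` from [fit_observer()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.observer_fit <- function(x, ...) {
  est <- x$estimates
  tibble(term = names(est), estimate = as.numeric(est[1, ]))
}

#' Glance at an observer fit
#'
#' @param x An `observer_fit` from [fit_observer()].
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_target`, `n_foil`, `method`,
#'   `converged`, `logLik`, `mean_payoff`.
#' @export
glance.observer_fit <- function(x, ...) {
  cn <- x$counts
  tibble(
    n = cn$n,
    n_target = cn$n_cd + cn$n_md,
    n_foil = cn$n_fa + cn$n_cr,
    method = x$method,
    converged = x$converged,
    logLik = x$logLik,
    mean_payoff = cn$mean_payoff
  )
}
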