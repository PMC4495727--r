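# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: tail probabilities come from adaptive
# quadrature of the Gaussian density, and optimal criteria from the
# closed-form likelihood-ratio algebra written out directly.

# P(X >= x) for X ~ N(mu, sigma^2), by quadrature of the density.
quad_tail <- function(x, mu, sigma) {
  stats::integrate(function(s) stats::dnorm(s, mu, sigma), x, Inf,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Expected value of a criterion assembled from quadrature probabilities.
quad_ev <- function(x, mu_t, mu_f, sigma, alpha, h, m, a, j) {
  p_cd <- quad_tail(x, mu_t, sigma)
  p_fa <- quad_tail(x, mu_f, sigma)
  alpha * h * p_cd + alpha * m * (1 - p_cd) +
    (1 - alpha) * a * p_fa + (1 - alpha) * j * (1 - p_fa)
}

# Closed-form optimal criterion for the equal-variance objective problem.
lr_optimum <- function(mu_t, mu_f, sigma, alpha, h, m, a, j) {
  beta_star <- ((1 - alpha) * (j - a)) / (alpha * (h - m))
  (mu_t + mu_f) / 2 + sigma^2 * log(beta_star) / (mu_t - mu_f)
}

# A random well-posed equal-variance environment + payoffs. Separation and
# payoff ratios are kept in ranges where the optimum stays inside the
# +/- 6 sigma domain bounds (offset <= ~6 sigma by construction).
random_problem <- function() {
  sigma <- runif(1, 5, 20)
  mu_f <- runif(1, -50, 50)
  mu_t <- mu_f + runif(1, 0.8, 2.5) * sigma
  alpha <- runif(1, 0.2, 0.8)
  h <- runif(1, 10, 100)
  m <- h - runif(1, 5, 150)
  j <- runif(1, 10, 100)
  a <- j - runif(1, 5, 150)
  list(
    env = perceptual_environment(mu_t, mu_f, sigma, base_rate = alpha),
    payoffs = payoff_matrix(h, m, a, j),
    pars = list(mu_t = mu_t, mu_f = mu_f, sigma = sigma, alpha = alpha,
                h = h, m = m, a = a, j = j)
  )
}

# The running weather example: rain (target) vs. no rain, in % chance of rain.
rain_env <- function() {
  perceptual_environment(60, 40, 15, base_rate = 0.5, units = "% chance of rain")
}
rain_payoffs <- function(a = -50) payoff_matrix(100, -50, a, 100)

digest_file <- function(f) unname(tools::md5sum(f))
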