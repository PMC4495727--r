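test_that("simulation respects n, the base rate, and the outcome taxonomy", {
  env <- rain_env()
  pay <- rain_payoffs()
  expect_identical(nrow(simulate_trials(env, pay, 50, 0, seed = 1)), 0L)

  rare_foil <- perceptual_environment(60, 40, 15, base_rate = 0.999)
  tr <- simulate_trials(rare_foil, pay, 50, 1000, seed = 2)
  expect_gte(sum(tr$category == "target"), 990)

  tr <- simulate_trials(env, pay, 50, 500, seed = 3)
  expect_identical(tr$outcome, sdtvalue:::classify_outcome(tr$category, tr$response))
  expect_identical(tr$response, ifelse(tr$signal >= 50, "target", "foil"))
  lut <- c(CD = 100, MD = -50, FA = -50, CR = 100)
  expect_identical(tr$payoff, unname(lut[tr$outcome]))
})

test_that("identical seeds give byte-identical trial files", {
  env <- rain_env()
  pay <- rain_payoffs()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(simulate_trials(env, pay, 50, 500, seed = 99), f1)
  write_trials(simulate_trials(env, pay, 50, 500, seed = 99), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(
    simulate_trials(env, pay, 50, 500, seed = 99)$signal,
    simulate_trials(env, pay, 50, 500, seed = 100)$signal
  ))
})

test_that("empirical rates converge to the analytic outcome probabilities", {
  env <- rain_env()
  pay <- rain_payoffs()
  n <- 100000
  tr <- simulate_trials(env, pay, 50, n, seed = 4)
  cn <- tally(tr)
  p_hat <- cn$n_cd / (cn$n_cd + cn$n_md)
  p_true <- outcome_probabilities(env, 50)$p_cd
  se <- sqrt(p_true * (1 - p_true) / (cn$n_cd + cn$n_md))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("tallies partition trials and average the accrued payoffs", {
  env <- rain_env()
  pay <- rain_payoffs()
  tr <- simulate_trials(env, pay, 47, 1000, seed = 5)
  cn <- tally(tr)
  expect_identical(cn$n_cd + cn$n_md + cn$n_fa + cn$n_cr, cn$n)

  fixture <- tibble::tibble(
    index = 1:4,
    category = c("target", "target", "foil", "foil"),
    signal = c(65, 45, 55, 35),
    response = c("target", "foil", "target", "foil"),
    outcome = c("CD", "MD", "FA", "CR"),
    payoff = c(100, -50, -50, 100)
  )
  expect_identical(tally(fixture)$mean_payoff, 25)
})

test_that("the optimal criterion earns more than a shifted one, on average", {
  env <- rain_env()
  pay <- rain_payoffs()
  n <- 200000
  at_opt <- tally(simulate_trials(env, pay, 50, n, seed = 6))$mean_payoff
  shifted <- tally(simulate_trials(env, pay, 62, n, seed = 6))$mean_payoff
  expect_gt(at_opt, shifted)
  # and the empirical mean matches the analytic expected value within 3 SE
  tr <- simulate_trials(env, pay, 50, n, seed = 7)
  se <- stats::sd(tr$payoff) / sqrt(n)
  expect_lt(abs(mean(tr$payoff) - ev_at_criterion(env, pay, 50)), 3 * se)
})

test_that("observer fitting recovers the generating parameters", {
  env <- rain_env()
  pay <- rain_payoffs()
  tr <- simulate_trials(env, pay, 50, 10000, seed = 8)
  for (method in c("counts_analytic", "trialwise_ml")) {
    fit <- fit_observer(tr, env, method = method)
    expect_s3_class(fit, "observer_fit")
    expect_true(fit$converged)
    expect_lt(abs(fit$estimates$d_prime - 4 / 3), 0.1)
    expect_lt(abs(fit$estimates$criterion - 50), 1)
  }
  td <- tidy(fit_observer(tr, env))
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit_observer(tr, env))
  expect_identical(gl$n, 10000L)
})

test_that("recovery has no first-order bias across replicates", {
  env <- rain_env()
  pay <- rain_payoffs()
  crit <- vapply(1:100, function(i) {
    tr <- simulate_trials(env, pay, 50, 2000, seed = 1000 + i)
    fit_observer(tr, env)$estimates$criterion
  }, numeric(1))
  expect_lt(abs(mean(crit) - 50), 0.5)
})

test_that("one-sided response sets still yield finite corrected estimates", {
  env <- rain_env()
  pay <- rain_payoffs()
  tr <- simulate_trials(env, pay, 50, 200, seed = 9)
  tr$response <- "target"
  tr$outcome <- sdtvalue:::classify_outcome(tr$category, tr$response)
  fit <- fit_observer(tr, env, method = "counts_analytic")
  expect_true(all(is.finite(unlist(fit$estimates))))
})

test_that("the trialwise likelihood is maximized near the generating criterion", {
  env <- rain_env()
  pay <- rain_payoffs()
  tr <- simulate_trials(env, pay, 50, 5000, seed = 10)
  for (tau in c(0.5, 2)) {
    expect_gt(observer_loglik(tr, 50, tau), observer_loglik(tr, 55, tau))
  }
  # noisy responders: both criterion and softness are estimated
  set.seed(11)
  noisy <- tr
  eff_crit <- rnorm(nrow(noisy), 50, 5)
  noisy$response <- ifelse(noisy$signal >= eff_crit, "target", "foil")
  noisy$outcome <- sdtvalue:::classify_outcome(noisy$category, noisy$response)
  fit <- fit_observer(noisy, env, method = "trialwise_ml")
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$criterion - 50), 1)
  expect_lt(abs(fit$estimates$softness - 5), 1)
})

test_that("the experimental weighting grid ranks the generating scheme sensibly", {
  env <- rain_env()
  pay <- rain_payoffs(a = -90) # asymmetric payoffs so schemes differ
  x_star <- optimal_criterion(env, pay)$x_star
  tr <- simulate_trials(env, pay, x_star, 4000, seed = 12)
  grid <- fit_weighting_grid(tr, env, pay,
                             loss_aversion = c(1, 2.25),
                             exponent = c(0.88, 1),
                             delta = c(0.61, 1))
  expect_identical(nrow(grid), 8L)
  expect_true(all(diff(grid$score) >= 0))
  # the objective scheme predicts the criterion the observer actually used
  objective <- grid[grid$loss_aversion == 1 & grid$exponent == 1 & grid$delta == 1, ]
  expect_lt(abs(objective$x_star_pred - x_star), 0.01)
  expect_lte(objective$score, grid$score[nrow(grid)])
})
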