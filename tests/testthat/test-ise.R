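test_that("criterion expected value assembles payoffs and probabilities correctly", {
  env <- rain_env()
  pay <- rain_payoffs()
  expect_equal(ev_at_criterion(env, pay, 50),
               quad_ev(50, 60, 40, 15, 0.5, 100, -50, -50, 100),
               tolerance = 1e-9)
  expect_equal(ev_at_criterion(env, pay, 50), 62.12612, tolerance = 1e-6)
  for (x in c(35, 47, 55, 68)) {
    expect_equal(ev_at_criterion(env, pay, x),
                 quad_ev(x, 60, 40, 15, 0.5, 100, -50, -50, 100),
                 tolerance = 1e-9)
  }
})

test_that("near-degenerate base rates silence the foil terms", {
  env <- perceptual_environment(60, 40, 15, base_rate = 1 - 1e-12)
  pay <- rain_payoffs()
  pr <- outcome_probabilities(env, 50)
  expect_equal(ev_at_criterion(env, pay, 50),
               100 * pr$p_cd - 50 * pr$p_md, tolerance = 1e-9)
})

test_that("a flat payoff matrix conserves value at every criterion", {
  env <- rain_env()
  flat <- payoff_matrix(7, 7, 7, 7)
  x <- seq(10, 90, length.out = 41)
  expect_equal(ev_at_criterion(env, flat, x), rep(7, length(x)), tolerance = 1e-12)
  crv <- ev_curve(env, flat, n = 101)
  expect_equal(crv$value, rep(7, 101), tolerance = 1e-12)
  sol <- optimal_criterion(env, flat)
  expect_true(sol$tied)
})

test_that("the value curve peaks at the balanced midpoint and mirrors symmetry", {
  env <- rain_env()
  crv <- ev_curve(env, rain_payoffs())
  expect_equal(crv$x[which.max(crv$value)], 50, tolerance = 0.1)
  # h=j and m=a with alpha 1/2: the curve is symmetric about the midpoint
  v_left <- ev_at_criterion(env, rain_payoffs(), 50 - c(5, 10, 20))
  v_right <- ev_at_criterion(env, rain_payoffs(), 50 + c(5, 10, 20))
  expect_equal(v_left, v_right, tolerance = 1e-9)
  expect_error(ev_curve(env, rain_payoffs(), n = 1), class = "sdtvalue_config_error")
})

test_that("grid refinement and the likelihood-ratio closed form agree on the worked example", {
  env <- rain_env()
  grid <- optimal_criterion(env, rain_payoffs())
  lr <- optimal_criterion(env, rain_payoffs(), method = "closed_form_lr")
  expect_equal(lr$x_star, 50)
  expect_equal(lr$beta_star, 1)
  expect_equal(grid$x_star, 50, tolerance = 1e-4)

  heavy <- optimal_criterion(env, rain_payoffs(a = -90), method = "closed_form_lr")
  light <- optimal_criterion(env, rain_payoffs(a = -10), method = "closed_form_lr")
  expect_equal(heavy$x_star, 50 + 225 * log(190 / 150) / 20, tolerance = 1e-12)
  expect_equal(heavy$x_star, 52.65937, tolerance = 1e-5)
  expect_equal(light$x_star, 46.51076, tolerance = 1e-5)

  expect_error(
    optimal_criterion(env, payoff_matrix(5, 5, -50, 100), method = "closed_form_lr"),
    class = "sdtvalue_degenerate_payoffs"
  )
  expect_error(
    optimal_criterion(perceptual_environment(60, 40, 15, 10), rain_payoffs(),
                      method = "closed_form_lr"),
    class = "sdtvalue_config_error"
  )
})

test_that("grid-refined optima track the closed form across random environments", {
  set.seed(31)
  for (rep in 1:40) {
    prob <- random_problem()
    x_lr <- do.call(lr_optimum, prob$pars)
    sol <- optimal_criterion(prob$env, prob$payoffs)
    expect_equal(sol$x_star, x_lr, tolerance = 0.05)
    pkg_lr <- optimal_criterion(prob$env, prob$payoffs, method = "closed_form_lr")
    expect_equal(pkg_lr$x_star, x_lr, tolerance = 1e-10)
  }
})

test_that("shifting all payoffs by a constant moves value, not the optimum", {
  set.seed(32)
  for (rep in 1:5) {
    prob <- random_problem()
    k <- runif(1, -100, 100)
    p2 <- with(prob$pars, payoff_matrix(h + k, m + k, a + k, j + k))
    x <- seq(prob$env$domain_bounds[1], prob$env$domain_bounds[2], length.out = 51)
    expect_equal(ev_at_criterion(prob$env, p2, x),
                 ev_at_criterion(prob$env, prob$payoffs, x) + k,
                 tolerance = 1e-9)
    expect_equal(optimal_criterion(prob$env, p2)$x_star,
                 optimal_criterion(prob$env, prob$payoffs)$x_star,
                 tolerance = 1e-3)
  }
})

test_that("costlier false alarms push the optimum conservative, higher hits liberal", {
  set.seed(33)
  for (rep in 1:5) {
    prob <- random_problem()
    x0 <- optimal_criterion(prob$env, prob$payoffs, method = "closed_form_lr")$x_star
    worse_fa <- with(prob$pars, payoff_matrix(h, m, a - runif(1, 5, 60), j))
    better_h <- with(prob$pars, payoff_matrix(h + runif(1, 5, 60), m, a, j))
    expect_gte(optimal_criterion(prob$env, worse_fa, method = "closed_form_lr")$x_star, x0)
    expect_lte(optimal_criterion(prob$env, better_h, method = "closed_form_lr")$x_star, x0)
  }
})

test_that("the no-uncertainty constant is the base-rate-weighted option average", {
  expect_identical(no_uncertainty_value(0.5, 45, 45), 45)
  expect_identical(no_uncertainty_value(1, 45, 99), 45)
  expect_identical(no_uncertainty_value(0, 45, 99), 99)
  expect_error(no_uncertainty_value(1.5, 1, 1), class = "sdtvalue_domain_error")

  # a 40-sigma separation makes the full function numerically constant at the
  # no-uncertainty value across mid-domain criteria
  env <- perceptual_environment(40, 0, 1, base_rate = 0.5,
                                domain_bounds = c(-10, 50))
  pay <- payoff_matrix(45, -100, -100, 45)
  for (x in c(12, 20, 28)) {
    expect_equal(ev_at_criterion(env, pay, x), no_uncertainty_value(0.5, 45, 45),
                 tolerance = 1e-6)
  }
})

test_that("identity weighting collapses both utility modes onto expected value", {
  set.seed(34)
  for (rep in 1:20) {
    prob <- random_problem()
    x <- runif(5, prob$env$domain_bounds[1], prob$env$domain_bounds[2])
    ev <- ev_at_criterion(prob$env, prob$payoffs, x)
    for (mode in c("value_weighted", "fully_weighted")) {
      expect_equal(
        utility_at_criterion(prob$env, prob$payoffs, scheme_identity(), x, mode = mode),
        ev, tolerance = 1e-12
      )
    }
  }
})

test_that("subjective weighting preserves the symmetry of a balanced problem", {
  env <- rain_env()
  pay <- rain_payoffs() # h = j, m = a, alpha = 1/2
  sch <- weighting_scheme() # prospect value + tk1992 weights everywhere
  # value weighting alone keeps the argmax at the midpoint
  sol6 <- optimal_criterion(env, pay, sch, mode = "value_weighted")
  expect_equal(sol6$x_star, 50, tolerance = 1e-3)
  # base-rate weighting treats alpha and 1 - alpha identically at 1/2
  w <- probability_weight(0.5, weight_tk1992(0.61))
  expect_equal(w, probability_weight(1 - 0.5, weight_tk1992(0.61)))
  sol7 <- optimal_criterion(env, pay, sch, mode = "fully_weighted")
  u_left <- utility_at_criterion(env, pay, sch, 50 - c(3, 8), mode = "fully_weighted")
  u_right <- utility_at_criterion(env, pay, sch, 50 + c(3, 8), mode = "fully_weighted")
  expect_equal(u_left, u_right, tolerance = 1e-9)
  expect_equal(sol7$x_star, 50, tolerance = 1e-3)
})

test_that("the complementary-weighting flag changes only miss and rejection terms", {
  env <- rain_env()
  pay <- rain_payoffs()
  sch <- weighting_scheme()
  u_raw <- utility_at_criterion(env, pay, sch, 55, mode = "fully_weighted")
  u_comp <- utility_at_criterion(env, pay, sch, 55, mode = "fully_weighted",
                                 complementary = TRUE)
  expect_false(isTRUE(all.equal(u_raw, u_comp)))
  # with identity S they coincide
  sch_id_s <- weighting_scheme(signal_prob_weight_fn = weight_identity())
  expect_equal(
    utility_at_criterion(env, pay, sch_id_s, 55, mode = "fully_weighted"),
    utility_at_criterion(env, pay, sch_id_s, 55, mode = "fully_weighted",
                         complementary = TRUE),
    tolerance = 1e-12
  )
})

test_that("payoff variability yields an asymmetric envelope around the mean optimum", {
  env <- rain_env()
  envl <- ev_envelope(env, rain_payoffs(),
                      list(heavy = rain_payoffs(a = -90),
                           light = rain_payoffs(a = -10)))
  opt <- tibble::deframe(envl$optima[c("curve", "x_star")])
  # conservative/liberal ordering: heavy rain (min curve) > mean > light rain
  expect_gt(opt["min"], opt["mean"])
  expect_gt(opt["mean"], opt["max"])
  expect_equal(opt[["mean"]], 50, tolerance = 1e-3)
  # the mean optimum is NOT the midpoint of the variant optima
  mid <- (opt[["min"]] + opt[["max"]]) / 2
  expect_equal(mid, 49.58507, tolerance = 1e-4)
  expect_gt(abs(opt[["mean"]] - mid), 0.1)
  # pointwise ordering of the band
  wide <- tidyr::pivot_wider(envl$curves, names_from = "curve", values_from = "value")
  expect_true(all(wide$min <= wide$mean + 1e-9))
  expect_true(all(wide$mean <= wide$max + 1e-9))
})

test_that("a single variant equal to the mean collapses the envelope", {
  env <- rain_env()
  envl <- ev_envelope(env, rain_payoffs(), list(rain_payoffs()), n = 201)
  wide <- tidyr::pivot_wider(envl$curves, names_from = "curve", values_from = "value")
  expect_equal(wide$min, wide$mean, tolerance = 1e-12)
  expect_equal(wide$max, wide$mean, tolerance = 1e-12)
  expect_equal(diff(range(envl$optima$x_star)), 0, tolerance = 1e-4)
  expect_error(ev_envelope(env, rain_payoffs(), list()),
               class = "sdtvalue_config_error")
})
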