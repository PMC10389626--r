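# Closed-form oracle values below were computed independently from the
# published coefficients with plain logistic algebra (see also the inline
# recomputations): for the example patient, x_a'alpha = -0.68 and
# x_e'eta = 2.41, giving f2 = 0.3362613, v(1,1) = 0.21,
# v(2,1) = -0.6079134, S4 = 0.5523079 / 0.3525353, f4(1; delta=1) =
# 0.1997726 and f5(1) = 0.7947576.

test_that("cause probability matches the closed-form logistic and sums to 1", {
  p <- params_center65()
  prof <- example_profile()
  expect_equal(cause_probability(prof, p, 1), plogis(-0.68), tolerance = 1e-12)
  expect_equal(cause_probability(prof, p, 1), 0.3362613, tolerance = 1e-6)
  raw <- random_raw_cohort(20, seed = 7)
  expect_equal(cause_probability(raw, p, 1) + cause_probability(raw, p, 2),
               rep(1, 20), tolerance = 1e-15)
})

test_that("time index v matches closed forms and its cause-2 algebra", {
  p <- params_center65()
  prof <- example_profile()
  expect_equal(time_index_v(1, 1, prof, p), -2.20 + 2.41, tolerance = 1e-12)
  expect_equal(time_index_v(2, 1, prof, p), 0.21 - 1.18 * log(2),
               tolerance = 1e-12)
  # d = 2 never includes the gamma or rho terms
  for (t in c(0.3, 1, 2.7)) {
    expect_equal(time_index_v(t, 2, prof, p) - time_index_v(t, 1, prof, p),
                 -(-2.20 + log(t) * (-0.42)), tolerance = 1e-12)
  }
  expect_error(time_index_v(0, 1, prof, p), "> 0")
})

test_that("S4 matches closed forms, decreases in t, and has limits 1 and 0", {
  p <- params_center65()
  prof <- example_profile()
  expect_equal(survival_S4(1, 1, prof, p), 0.5523079, tolerance = 1e-6)
  expect_equal(survival_S4(2, 1, prof, p), 0.3525353, tolerance = 1e-6)
  tt <- exp(seq(log(0.01), log(50), length.out = 60))
  for (d in 1:2) {
    s <- survival_S4(tt, d, prof, p)
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s < 1))
  }
  expect_gt(survival_S4(1e-9, 1, prof, p), 1 - 1e-6)
  expect_lt(survival_S4(1e9, 1, prof, p), 1e-6)
  # weibull family keeps the same monotone behavior
  pw <- params_center65(); pw$family <- "weibull"
  sw <- survival_S4(tt, 1, prof, pw)
  expect_true(all(diff(sw) < 0))
})

test_that("interval mass f4 telescopes and vanishes with the interval", {
  p <- params_center65()
  prof <- example_profile()
  expect_equal(interval_density_f4(1, 1, prof, p, delta = 1),
               0.1997726, tolerance = 1e-6)
  grid <- seq(0.5, 3, by = 0.25)
  pieces <- interval_density_f4(grid[-length(grid)], 1, prof, p, delta = 0.25)
  expect_equal(sum(pieces),
               survival_S4(0.5, 1, prof, p) - survival_S4(3, 1, prof, p),
               tolerance = 1e-12)
  expect_lt(interval_density_f4(1, 1, prof, p, delta = 1e-9), 1e-8)
})

test_that("mixture survival f5 matches the closed form and equals 1 - CIF", {
  p <- params_center65()
  prof <- example_profile()
  expect_equal(censored_survival_f5(1, prof, p), 0.7947576, tolerance = 1e-6)
  # equal components make the mixture independent of f2
  pi <- intercept_only_params(alpha0 = 1.3, rho0 = 0)
  pi$coefficients$gamma[1] <- 0
  prof1 <- random_raw_cohort(1, seed = 3)
  expect_equal(censored_survival_f5(1.7, prof1, pi),
               survival_S4(1.7, 2, prof1, pi), tolerance = 1e-14)
  # non-increasing in t, and the cross-module identity with cif_total
  raw <- random_raw_cohort(15, seed = 11)
  for (t in c(0.2, 1, 3.6)) {
    expect_equal(1 - censored_survival_f5(t, raw, p),
                 cif(t, raw, p)$cif_total, tolerance = 1e-12)
  }
  tt <- seq(0.05, 4, by = 0.05)
  f5 <- censored_survival_f5(tt, prof, p)
  expect_true(all(diff(f5) < 0))
})

test_that("log-likelihood equals the independent per-record product oracle", {
  for (seed in 1:20) {
    n <- sample(3:20, 1)
    raw <- random_raw_cohort(n, seed = 1000 + seed)
    p <- random_params(seed)
    expect_equal(crmix_loglik(raw, p, delta = 1 / 365.25),
                 oracle_loglik(raw, p, delta = 1 / 365.25),
                 tolerance = 1e-10)
  }
})

test_that("a single censored record contributes exactly log f5", {
  p <- params_center65()
  raw <- random_raw_cohort(1, seed = 5)
  raw$event <- 0L
  expect_equal(crmix_loglik(raw, p),
               log(censored_survival_f5(raw$time, raw, p)), tolerance = 1e-12)
})

test_that("halving delta shifts the log-likelihood by n_events log(1/2) and
           leaves the maximizer unchanged", {
  ch <- simulate_cohort(simulation_config(n = 1200, seed = 21))
  p <- published_params()
  d1 <- 1 / 365.25
  ll1 <- crmix_loglik(ch, p, delta = d1)
  ll2 <- crmix_loglik(ch, p, delta = d1 / 2)
  nev <- sum(ch$event > 0)
  expect_equal(ll2 - ll1, nev * log(0.5), tolerance = 0.05 * abs(nev * log(0.5)))
  f1 <- suppressWarnings(crmix(ch, delta = d1, nstart = 1, hessian = FALSE))
  f2 <- suppressWarnings(crmix(ch, delta = d1 / 2, nstart = 1, hessian = FALSE))
  expect_equal(coef(f1), coef(f2), tolerance = 5e-3)
})

test_that("non-monotone parameter sets are flagged, not silently used", {
  bad <- intercept_only_params(phi0 = 0.3)
  expect_false(is_monotone(bad))
  prof <- random_raw_cohort(1, seed = 9)
  # cause 2 carries the positive phi slope, so its S4 increases in t
  expect_error(interval_density_f4(2, 2, prof, bad, delta = 0.5),
               "monotonicity")
  expect_error(simulate_event(crmix_design(prof, bad), bad), "refusing")
})
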