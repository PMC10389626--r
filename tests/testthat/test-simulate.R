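test_that("simulated covariate marginals match the configuration", {
  cfg <- simulation_config(n = 10000, seed = 121)
  set.seed(cfg$seed)
  cov <- sample_covariates(cfg)
  # 99% binomial interval around the configured male fraction
  p <- cfg$marginals$p_male
  half <- 2.576 * sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(cov$sex == "male") - p), half)
  p_scc <- cfg$marginals$p_scc
  expect_lt(abs(mean(cov$histology == "squamous_cell_carcinoma") - p_scc),
            2.576 * sqrt(p_scc * (1 - p_scc) / 10000) + 1e-12)
  expect_true(all(cov$age >= 30 & cov$age <= 95))
  # a marginal set to 1 gives a constant column
  cfg1 <- simulation_config(n = 50, seed = 2, p_r1r2 = 1)
  set.seed(2)
  expect_true(all(sample_covariates(cfg1)$margin == "r1r2"))
})

test_that("the validation preset flips the case mix", {
  cfg <- simulation_config(n = 8000, seed = 5, preset = "validation")
  set.seed(cfg$seed)
  cov <- sample_covariates(cfg)
  expect_lt(mean(cov$histology == "squamous_cell_carcinoma"), 0.25)
  expect_gt(mean(cov$chemoradiotherapy == "yes"), 0.6)
})

test_that("simulation is reproducible by seed and differs across seeds", {
  c1 <- simulate_cohort(simulation_config(n = 300, seed = 9))
  c2 <- simulate_cohort(simulation_config(n = 300, seed = 9))
  c3 <- simulate_cohort(simulation_config(n = 300, seed = 10))
  expect_identical(c1$time, c2$time)
  expect_identical(c1$event, c2$event)
  expect_false(identical(c1$time, c3$time))
})

test_that("inverse-transform sampling inverts the survival function exactly", {
  p <- published_params()
  prof <- example_profile()
  d <- crmix_design(prof, p)
  lp <- crmix:::.linpred(d, p)
  for (tstar in c(0.4, 1, 2.5)) {
    u <- survival_S4(tstar, 1, d, p)
    a <- lp$e + lp$g; b <- lp$p + lp$r
    expect_equal(invert_survival_time(u, a, b, "loglogistic"), tstar,
                 tolerance = 1e-10)
  }
  expect_error(invert_survival_time(0.5, 0, 0.2), "negative")
})

test_that("simulated log-logistic times match survreg's fit of the same
           distribution", {
  # dual route: our inversion sampler vs survival::survreg on uncensored
  # single-cause draws; v = a + b log t corresponds to survreg's
  # loglogistic with scale = -1/b and intercept = -a/b
  a <- 2.4; b <- -1.2
  set.seed(333)
  t <- invert_survival_time(runif(20000), a, b, "loglogistic")
  sr <- survival::survreg(survival::Surv(t) ~ 1, dist = "loglogistic")
  expect_equal(unname(coef(sr)[1]), -a / b, tolerance = 0.02)
  expect_equal(sr$scale, -1 / b, tolerance = 0.03)
})

test_that("uncensored cause-1 event times follow 1 - S4 (KS distance)", {
  p <- published_params()
  prof <- example_profile()
  d <- crmix:::.design_rows(crmix_design(prof, p), rep(1L, 50000))
  set.seed(555)
  ev <- simulate_event(d, p, cap = Inf)
  t1 <- sort(ev$time[ev$event == 1])
  emp <- seq_along(t1) / length(t1)
  theo <- 1 - survival_S4(t1, 1, crmix_design(prof, p), p)
  expect_lt(max(abs(emp - theo)), 0.02)
})

test_that("the censored fraction decreases as the cap grows", {
  p <- published_params()
  ch <- simulate_cohort(simulation_config(n = 4000, seed = 21))
  d <- crmix_design(encode_cohort(ch), p)
  fr <- vapply(c(0.5, 1, 2, 4), function(cap) {
    set.seed(77)
    mean(simulate_event(d, p, cap = cap)$event == 0)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
  # degenerate cap censors nearly everyone
  set.seed(77)
  expect_gt(mean(simulate_event(d, p, cap = 0.001)$event == 0), 0.99)
})

test_that("cohort-level death fraction matches the model's mean CIF at the
           cap", {
  cfg <- simulation_config(n = 1027, seed = 31)
  ch <- simulate_cohort(cfg)
  target <- mean(cif(4, encode_cohort(ch), cfg$params)$cif_total)
  emp <- mean(ch$event > 0)
  se <- sqrt(target * (1 - target) / nrow(ch))
  expect_lt(abs(emp - target), 3.5 * se)
})

test_that("surgery-origin mode yields strictly positive landmark times", {
  cfg <- simulation_config(n = 500, seed = 41, origin = "surgery")
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$time > 0 & ch$time <= 4))
  expect_true(all(ch$event %in% 0:2))
})

test_that("the association overlay induces the configured dependence", {
  cfg <- simulation_config(n = 20000, seed = 51,
                           assoc = list(chemo_given_scc = 1.5))
  set.seed(cfg$seed)
  cov <- sample_covariates(cfg)
  scc <- cov$histology == "squamous_cell_carcinoma"
  expect_gt(mean(cov$chemoradiotherapy[scc] == "yes"),
            mean(cov$chemoradiotherapy[!scc] == "yes") + 0.15)
})
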