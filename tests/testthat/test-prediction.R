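test_that("CIF identities hold to machine precision on randomized inputs", {
  for (seed in 1:10) {
    p <- random_params(seed + 100)
    raw <- random_raw_cohort(8, seed = seed)
    t <- runif(1, 0.1, 3.9)
    ci <- cif(t, raw, p)
    expect_equal(ci$cif_total, ci$cif_cancer + ci$cif_other,
                 tolerance = 1e-12)
    expect_equal(ci$cif_total, 1 - censored_survival_f5(t, raw, p),
                 tolerance = 1e-12)
    expect_true(all(ci$cif_cancer >= 0 & ci$cif_total < 1))
  }
  # t -> 0 sends every series to 0
  p <- published_params()
  ci0 <- cif(1e-12, example_profile(), p)
  expect_lt(ci0$cif_total, 1e-9)
  expect_equal(cif(0, example_profile(), p)$cif_total, 0)
})

test_that("conditional-CIF chaining multiplies all-cause survivals", {
  for (seed in 1:8) {
    p <- random_params(seed + 200)
    prof <- random_raw_cohort(1, seed = seed + 50)
    t0 <- runif(1, 0, 1.5); t1 <- runif(1, 0.1, 1); t2 <- runif(1, 0.1, 1)
    all12 <- conditional_cif(t1 + t2, t0, prof, p)$cif_allcause
    a1 <- conditional_cif(t1, t0, prof, p)$cif_allcause
    a2 <- conditional_cif(t2, t0 + t1, prof, p)$cif_allcause
    expect_equal(1 - all12, (1 - a1) * (1 - a2), tolerance = 1e-10)
  }
})

test_that("conditional risks at t0 = 0 reduce to the unconditional CIF and
           vanish at horizon 0", {
  p <- published_params()
  prof <- example_profile()
  cc <- conditional_cif(2, 0, prof, p)
  un <- cif(2, prof, p)
  expect_equal(cc$cif_allcause, un$cif_total, tolerance = 1e-12)
  expect_equal(cc$cif_cancer, un$cif_cancer, tolerance = 1e-12)
  z <- conditional_cif(0, 1.3, prof, p)
  expect_equal(z$cif_allcause, 0, tolerance = 1e-12)
  expect_equal(z$cif_cancer, 0, tolerance = 1e-12)
  expect_gte(cc$cif_allcause, cc$cif_cancer)
})

test_that("the published calculator examples reproduce within half a
           percentage point", {
  rep <- reproduce_worked_example()
  expect_true(attr(rep, "pass"))
  expect_equal(rep$computed_pct[1], 30.4, tolerance = 0.5 / 30.4)
  expect_equal(rep$computed_pct[2], 21.7, tolerance = 0.5 / 21.7)
  expect_lt(abs(rep$computed_pct[3] - 5.8), 0.5)
  expect_lt(abs(rep$computed_pct[4] - 3.7), 0.5)
  # zero tolerance must fail: the shipped coefficients are rounded
  rep0 <- reproduce_worked_example(tolerance_pp = 0)
  expect_false(attr(rep0, "pass"))
})

test_that("risk tables respect the 1-5 post-surgery-year domain and are
           monotone in the horizon", {
  p <- published_params()
  prof <- example_profile()
  expect_error(risk_table(prof, 0.5, 1, p), "1-5|>= 1")
  expect_error(risk_table(prof, 2, 4, p), "5 post-surgery")
  expect_warning(risk_table(prof, 2, 4, p, allow_extrapolation = TRUE),
                 "extrapolating")
  rt <- risk_table(prof, 1.5, c(0, 0.5, 1, 2), p)
  expect_equal(rt$cif_allcause[1], 0)
  expect_true(all(diff(rt$cif_allcause) > 0))
  expect_true(all(diff(rt$cif_cancer) >= 0))
  # worse stage raises every risk (coefficient signs are clinically coherent)
  prof3 <- prof; prof3$stage <- "iii"
  rt3 <- risk_table(prof3, 1.5, c(0.5, 1, 2), p)
  expect_true(all(rt3$cif_allcause > rt$cif_allcause[-1]))
  expect_true(all(rt3$cif_cancer > rt$cif_cancer[-1]))
})

test_that("formulaic conditional risks agree with forward simulation", {
  p <- published_params()
  prof <- example_profile()
  design <- crmix_design(prof, p)
  idx <- rep(1L, 200000)
  big <- crmix:::.design_rows(design, idx)
  set.seed(909)
  ev <- simulate_event(big, p, cap = Inf)
  # unconditional cancer CIF at t = 2
  target <- cif(2, prof, p)$cif_cancer
  emp <- mean(ev$event == 1 & ev$time <= 2)
  se <- sqrt(target * (1 - target) / nrow(ev))
  expect_lt(abs(emp - target), 3 * se + 1e-12)
  # conditional on surviving to t0 = 1.6: risk over the next 0.5 years
  alive <- ev$time > 1.6
  cc <- conditional_cif(0.5, 1.6, prof, p)
  emp_all <- mean(ev$time[alive] <= 2.1)
  se_all <- sqrt(cc$cif_allcause * (1 - cc$cif_allcause) / sum(alive))
  expect_lt(abs(emp_all - cc$cif_allcause), 3 * se_all)
  emp_can <- mean(ev$event[alive] == 1 & ev$time[alive] <= 2.1)
  se_can <- sqrt(cc$cif_cancer * (1 - cc$cif_cancer) / sum(alive))
  expect_lt(abs(emp_can - cc$cif_cancer), 3 * se_can)
})
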