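make_marker_cohort <- function(time, event) {
  data.frame(time = time, event = event)
}

test_that("time-dependent AUC matches hand-countable configurations", {
  # two cases {0.9, 0.7}, two controls {0.8, 0.1}: 3 of 4 pairs concordant
  ch <- make_marker_cohort(time = c(0.5, 0.8, 3, 3.5),
                           event = c(1L, 2L, 0L, 0L))
  auc <- time_dependent_auc(ch, horizon = 2, outcome = "allcause",
                            marker = c(0.9, 0.7, 0.8, 0.1))
  expect_equal(auc, 0.75)
  # perfectly separated markers
  auc1 <- time_dependent_auc(ch, horizon = 2, outcome = "allcause",
                             marker = c(0.9, 0.8, 0.2, 0.1))
  expect_equal(auc1, 1)
  # no cases before the horizon -> explicit error
  ch0 <- make_marker_cohort(time = c(3, 3.5), event = c(0L, 0L))
  expect_error(time_dependent_auc(ch0, horizon = 2, outcome = "allcause",
                                  marker = c(0.2, 0.4)), "no cases")
})

test_that("AUC equals the brute-force pairwise concordance on random cohorts", {
  for (seed in 1:15) {
    set.seed(seed + 400)
    n <- sample(10:50, 1)
    ch <- make_marker_cohort(time = runif(n, 0.1, 4),
                             event = sample(0:2, n, TRUE))
    marker <- round(runif(n), 2)  # rounding forces ties
    for (outcome in c("allcause", "cancer")) {
      st <- crmix:::.horizon_status(ch$time, ch$event, 2, outcome)
      if (!length(st$case) || !length(st$control)) next
      expect_equal(
        time_dependent_auc(ch, horizon = 2, outcome = outcome,
                           marker = marker),
        oracle_auc(marker[st$case], marker[st$control]))
    }
  }
})

test_that("a marker independent of outcome gives AUC near one half", {
  set.seed(77)
  ch <- simulate_cohort(simulation_config(n = 2000, seed = 77))
  marker <- runif(2000)
  auc <- time_dependent_auc(ch, horizon = 2, outcome = "allcause",
                            marker = marker)
  st <- crmix:::.horizon_status(encode_cohort(ch)$time,
                                encode_cohort(ch)$event, 2, "allcause")
  m <- length(st$case); k <- length(st$control)
  null_sd <- sqrt((m + k + 1) / (12 * m * k))
  expect_lt(abs(auc - 0.5), 3 * null_sd)
})

test_that("model-based markers discriminate on model-generated data", {
  ch <- simulate_cohort(simulation_config(n = 2000, seed = 404))
  p <- published_params()
  auc3 <- time_dependent_auc(ch, p, horizon = 2, outcome = "allcause")
  auc5 <- time_dependent_auc(ch, p, horizon = 4, outcome = "cancer")
  expect_gt(auc3, 0.65)
  expect_gt(auc5, 0.65)
})

test_that("bootstrap AUC cross-validation is reproducible and shows the
           optimism ordering", {
  ch <- simulate_cohort(simulation_config(n = 500, seed = 55))
  one <- bootstrap_auc_cv(ch, horizons = 2, outcomes = "allcause",
                          n_boot = 1, mode = "apparent", seed = 9)
  expect_equal(one$median, one$lo)
  expect_equal(one$median, one$hi)
  expect_equal(one$median, attr(one, "replicates")[1, 1])

  a <- bootstrap_auc_cv(ch, horizons = 2, outcomes = "allcause",
                        n_boot = 40, mode = "apparent", seed = 13)
  b <- bootstrap_auc_cv(ch, horizons = 2, outcomes = "allcause",
                        n_boot = 40, mode = "apparent", seed = 13)
  expect_identical(attr(a, "replicates"), attr(b, "replicates"))
  oob <- bootstrap_auc_cv(ch, horizons = 2, outcomes = "allcause",
                          n_boot = 40, mode = "out_of_bag", seed = 13)
  expect_gte(a$median, oob$median)
  expect_true(a$lo <= a$median & a$median <= a$hi)
})

test_that("the AUC difference between a cohort and itself is centered at
           zero, and attenuated effects shift it positive", {
  p <- published_params()
  ch <- simulate_cohort(simulation_config(n = 800, seed = 61))
  d0 <- auc_difference_ci(ch, ch, p, horizons = 2, outcomes = "allcause",
                          n_boot = 100, seed = 3)
  expect_true(d0$lo <= 0 && d0$hi >= 0)
  expect_lt(abs(d0$median), 0.05)
  # external cohort generated with halved covariate effects
  p_att <- p
  p_att$coefficients$alpha[-1] <- p_att$coefficients$alpha[-1] * 0.5
  p_att$coefficients$eta[-1] <- p_att$coefficients$eta[-1] * 0.5
  ext <- simulate_cohort(simulation_config(n = 1500, seed = 62,
                                           params = p_att))
  int <- simulate_cohort(simulation_config(n = 1500, seed = 63))
  dd <- auc_difference_ci(int, ext, p, horizons = 2, outcomes = "allcause",
                          n_boot = 60, seed = 5)
  expect_gt(dd$median, 0)
})

test_that("the Hosmer-Lemeshow statistic is zero under exact decile
           calibration and invariant to patient order", {
  predicted <- rep(seq(0.05, 0.5, by = 0.05), each = 20)
  observed <- unlist(lapply(seq(0.05, 0.5, by = 0.05), function(p)
    rep(c(1, 0), c(round(20 * p), 20 - round(20 * p)))))
  hl <- hosmer_lemeshow(predicted, observed)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 8)
  set.seed(5)
  perm <- sample(length(predicted))
  hl2 <- hosmer_lemeshow(predicted[perm], observed[perm])
  expect_equal(hl2$statistic, hl$statistic, tolerance = 1e-12)
  # single homogeneous group collapses gracefully
  hl3 <- hosmer_lemeshow(rep(0.5, 40), rep(c(1, 0), 20), n_groups = 10)
  expect_equal(hl3$statistic, 0, tolerance = 1e-12)
  expect_true(all(hl$table$n > 0))
  expect_equal(sum(hl$table$n), length(predicted))
})

test_that("KM versus model overlay: degenerate cohorts and ordering
           invariance", {
  ch <- simulate_cohort(simulation_config(n = 1500, seed = 71))
  int_fit <- suppressWarnings(crmix(ch, crmix_formulas(alpha = ~1, eta = ~1),
                                    nstart = 1, hessian = FALSE))
  gof <- km_vs_model_gof(ch, int_fit)
  expect_lt(gof$discrepancy, 0.05)
  # immortal cohort: KM stays at 1, discrepancy = 1 - min f5
  imm <- encode_cohort(ch)
  imm$event <- 0L
  imm$time <- 4
  gof_imm <- km_vs_model_gof(imm, int_fit)
  expect_equal(gof_imm$discrepancy, 1 - min(gof_imm$f5), tolerance = 1e-12)
  expect_true(all(gof_imm$km == 1))
  # permutation of patients changes nothing
  perm <- encode_cohort(ch)[sample(nrow(ch)), ]
  expect_equal(km_vs_model_gof(perm, int_fit)$discrepancy, gof$discrepancy,
               tolerance = 1e-12)
  # covariate fits are refused
  full_fit <- suppressWarnings(crmix(ch, nstart = 1, hessian = FALSE))
  expect_error(km_vs_model_gof(ch, full_fit), "intercept-only")
})
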