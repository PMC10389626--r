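# Discrimination and calibration: time-dependent AUC with bootstrap
# cross-validation, bootstrap AUC-difference CIs between cohorts,
# Hosmer-Lemeshow decile calibration, and Kaplan-Meier vs model
# goodness of fit.

# concordance of cases vs controls with half credit for ties, via ranks
.auc_rank <- function(cases, controls) {
  r <- rank(c(cases, controls))
  m <- length(cases); n <- length(controls)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# case/control status at a horizon: cases have the outcome event by the
# horizon; controls are event-free and under observation at the horizon;
# records censored before the horizon (or, for the cancer-specific outcome,
# dead of the competing cause before it) are excluded
.horizon_status <- function(time, event, horizon, outcome) {
  case <- if (outcome == "cancer") event == 1 & time <= horizon
  else event > 0 & time <= horizon
  control <- time >= horizon & !(event > 0 & time <= horizon)
  list(case = which(case), control = which(control & !case))
}

#' Time-dependent AUC of predicted risk
#'
#' Uses the model-predicted cumulative incidence at the horizon (total for
#' all-cause, cancer-specific for disease-specific mortality) as the
#' marker, or a user-supplied marker. AUC is the probability that a case's
#' marker exceeds a control's, with 0.5 credit for ties.
#'
#' @param cohort a `crmix_cohort` (or encoded data frame with
#'   `time`/`event`).
#' @param params `crmix_params` used to compute the marker (ignored when
#'   `marker` is given).
#' @param horizon prediction horizon, landmark years.
#' @param outcome `"allcause"` or `"cancer"`.
#' @param marker optional numeric risk marker, one value per patient.
#' @return the AUC (scalar).
#' @export
time_dependent_auc <- function(cohort, params = NULL, horizon,
                               outcome = c("allcause", "cancer"),
                               marker = NULL) {
  outcome <- match.arg(outcome)
  enc <- if (inherits(cohort, "crmix_cohort")) encode_cohort(cohort)
  else as.data.frame(cohort)
  if (is.null(marker)) {
    if (is.null(params)) stop("either params or marker must be supplied")
    ci <- cif(horizon, enc, params)
    marker <- if (outcome == "cancer") ci$cif_cancer else ci$cif_total
  }
  st <- .horizon_status(enc$time, enc$event, horizon, outcome)
  if (!length(st$case) || !length(st$control))
    stop("AUC undefined: no ", if (!length(st$case)) "cases" else "controls",
         " at horizon ", horizon)
  .auc_rank(marker[st$case], marker[st$control])
}

#' Bootstrap cross-validated AUC
#'
#' Resamples the cohort with replacement, refits the model on each
#' resample, and evaluates the time-dependent AUC either on the resample
#' itself (`"apparent"`) or on the out-of-bag records (`"out_of_bag"`,
#' default — it guards against optimism). Reports the median and
#' 2.5-97.5% quantiles over replicates.
#'
#' @param cohort a `crmix_cohort` or encoded data frame.
#' @param formulas model formulas for the refits.
#' @param horizons prediction horizons, landmark years.
#' @param outcomes outcomes to evaluate.
#' @param n_boot bootstrap replicates.
#' @param mode `"out_of_bag"` or `"apparent"`.
#' @param seed RNG seed (bit-reproducible results).
#' @param family,delta passed to [crmix()].
#' @return data frame with `horizon`, `outcome`, `median`, `lo`, `hi`,
#'   `n_ok`; per-replicate AUCs attached as attribute `"replicates"`.
#' @export
bootstrap_auc_cv <- function(cohort, formulas = crmix_formulas(), horizons,
                             outcomes = c("allcause", "cancer"),
                             n_boot = 1000,
                             mode = c("out_of_bag", "apparent"), seed = 1,
                             family = "loglogistic", delta = 1 / 365.25) {
  mode <- match.arg(mode)
  enc <- if (inherits(cohort, "crmix_cohort")) encode_cohort(cohort)
  else as.data.frame(cohort)
  n <- nrow(enc)
  full <- suppressWarnings(crmix(enc, formulas, family = family, delta = delta,
                                 nstart = 1, hessian = FALSE))
  idx <- .with_seed(seed, lapply(seq_len(n_boot), function(i)
    sample.int(n, n, replace = TRUE)))
  grid <- expand.grid(horizon = horizons, outcome = outcomes,
                      stringsAsFactors = FALSE)
  reps <- matrix(NA_real_, n_boot, nrow(grid))
  fails <- 0L
  for (b in seq_len(n_boot)) {
    take <- idx[[b]]
    fit <- tryCatch(
      suppressWarnings(crmix(enc[take, , drop = FALSE], formulas,
                             family = family, delta = delta, nstart = 1,
                             init = full$coefficients, hessian = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) { fails <- fails + 1L; next }
    eval_on <- if (mode == "apparent") enc[take, , drop = FALSE]
    else enc[-unique(take), , drop = FALSE]
    if (!nrow(eval_on)) { fails <- fails + 1L; next }
    for (g in seq_len(nrow(grid))) {
      reps[b, g] <- tryCatch(
        time_dependent_auc(eval_on, fit$params, grid$horizon[g],
                           grid$outcome[g]),
        error = function(e) NA_real_)
    }
  }
  if (fails > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap refits failed", fails, n_boot))
  out <- grid
  out$median <- apply(reps, 2, stats::median, na.rm = TRUE)
  out$lo <- apply(reps, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
                  names = FALSE)
  out$hi <- apply(reps, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
                  names = FALSE)
  out$n_ok <- apply(reps, 2, function(v) sum(is.finite(v)))
  attr(out, "replicates") <- reps
  out
}

#' Bootstrap CI for the AUC difference between two cohorts
#'
#' Under fixed model parameters, resamples each cohort with replacement,
#' computes both AUCs per replicate, and reports the median difference
#' (internal minus external) with 2.5-97.5% quantile intervals.
#'
#' @param cohort_internal,cohort_external cohorts to compare.
#' @param params fixed `crmix_params` supplying the risk marker.
#' @param horizons prediction horizons, landmark years.
#' @param outcomes outcomes to evaluate.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return data frame with `horizon`, `outcome`, `median`, `lo`, `hi`;
#'   replicate differences attached as attribute `"replicates"`.
#' @export
auc_difference_ci <- function(cohort_internal, cohort_external, params,
                              horizons, outcomes = c("allcause", "cancer"),
                              n_boot = 200, seed = 1) {
  enc_i <- if (inherits(cohort_internal, "crmix_cohort"))
    encode_cohort(cohort_internal) else as.data.frame(cohort_internal)
  enc_e <- if (inherits(cohort_external, "crmix_cohort"))
    encode_cohort(cohort_external) else as.data.frame(cohort_external)
  stopifnot(nrow(enc_i) > 0, nrow(enc_e) > 0)
  draws <- .with_seed(seed, lapply(seq_len(n_boot), function(b)
    list(i = sample.int(nrow(enc_i), nrow(enc_i), TRUE),
         e = sample.int(nrow(enc_e), nrow(enc_e), TRUE))))
  grid <- expand.grid(horizon = horizons, outcome = outcomes,
                      stringsAsFactors = FALSE)
  reps <- matrix(NA_real_, n_boot, nrow(grid))
  for (b in seq_len(n_boot)) {
    di <- enc_i[draws[[b]]$i, , drop = FALSE]
    de <- enc_e[draws[[b]]$e, , drop = FALSE]
    for (g in seq_len(nrow(grid))) {
      reps[b, g] <- tryCatch(
        time_dependent_auc(di, params, grid$horizon[g], grid$outcome[g]) -
          time_dependent_auc(de, params, grid$horizon[g], grid$outcome[g]),
        error = function(e) NA_real_)
    }
  }
  out <- grid
  out$median <- apply(reps, 2, stats::median, na.rm = TRUE)
  out$lo <- apply(reps, 2, stats::quantile, probs = 0.025, na.rm = TRUE,
                  names = FALSE)
  out$hi <- apply(reps, 2, stats::quantile, probs = 0.975, na.rm = TRUE,
                  names = FALSE)
  attr(out, "replicates") <- reps
  out
}

#' Hosmer-Lemeshow calibration across tenths of predicted risk
#'
#' Groups patients by quantiles of predicted risk, compares observed event
#' counts O_g with expected E_g = n_g * mean predicted, and forms the
#' statistic `sum (O_g - E_g)^2 / [E_g (1 - pbar_g)]`, referred to a
#' chi-square with `groups - 2` degrees of freedom. Groups whose
#' denominator vanishes are merged with their neighbor.
#'
#' @param predicted predicted risks in [0, 1].
#' @param observed binary outcomes (0/1) at the same horizon.
#' @param n_groups number of quantile groups (default deciles).
#' @return list with `table` (per-group n, mean predicted, observed
#'   proportion, O, E), `statistic`, `df`, `p_value`, `merged`.
#' @export
hosmer_lemeshow <- function(predicted, observed, n_groups = 10) {
  stopifnot(length(predicted) == length(observed),
            all(predicted >= 0 & predicted <= 1),
            all(observed %in% 0:1))
  br <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_groups + 1),
                               names = FALSE))
  g <- if (length(br) > 2) cut(predicted, br, include.lowest = TRUE,
                               labels = FALSE)
  else rep(1L, length(predicted))
  tab <- do.call(rbind, lapply(sort(unique(g)), function(k) {
    sel <- g == k
    data.frame(group = k, n = sum(sel), mean_pred = mean(predicted[sel]),
               obs_prop = mean(observed[sel]), O = sum(observed[sel]),
               E = sum(sel) * mean(predicted[sel]))
  }))
  # merge groups with degenerate variance into the neighbor above
  merged <- 0L
  repeat {
    bad <- which(tab$E * (1 - tab$mean_pred) <= 0)
    if (!length(bad) || nrow(tab) == 1) break
    k <- bad[1]
    j <- if (k < nrow(tab)) k + 1L else k - 1L
    pooled_n <- tab$n[k] + tab$n[j]
    tab$mean_pred[j] <- (tab$n[k] * tab$mean_pred[k] +
                           tab$n[j] * tab$mean_pred[j]) / pooled_n
    tab$n[j] <- pooled_n
    tab$O[j] <- tab$O[k] + tab$O[j]
    tab$E[j] <- tab$n[j] * tab$mean_pred[j]
    tab$obs_prop[j] <- tab$O[j] / tab$n[j]
    tab <- tab[-k, , drop = FALSE]
    merged <- merged + 1L
  }
  denom <- tab$E * (1 - tab$mean_pred)
  stat <- if (all(denom > 0)) sum((tab$O - tab$E)^2 / denom) else 0
  df <- max(nrow(tab) - 2, 1)
  list(table = tab, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       merged = merged)
}

#' Kaplan-Meier versus model survival goodness of fit
#'
#' Overlays the Kaplan-Meier estimate of all-cause survival with the
#' intercept-only model's mixture survival f5 and reports the sup-norm
#' discrepancy over the KM step times.
#'
#' @param cohort a `crmix_cohort` or encoded data frame.
#' @param fit an intercept-only `crmix` fit (no candidate predictors beyond
#'   the constants).
#' @return list of class `"crmix_gof"`: `time`, `km`, `f5`, `discrepancy`.
#' @export
km_vs_model_gof <- function(cohort, fit) {
  covar <- setdiff(unique(unlist(lapply(fit$formulas, all.vars))), character(0))
  if (length(covar))
    stop("goodness-of-fit overlay requires an intercept-only fit")
  enc <- if (inherits(cohort, "crmix_cohort")) encode_cohort(cohort)
  else as.data.frame(cohort)
  km <- survival::survfit(survival::Surv(enc$time, enc$event > 0) ~ 1)
  times <- km$time
  f5 <- censored_survival_f5(times, enc[rep(1, length(times)), , drop = FALSE],
                             fit$params)
  structure(list(time = times, km = km$surv, f5 = f5,
                 discrepancy = max(abs(km$surv - f5))),
            class = "crmix_gof")
}

#' @export
print.crmix_gof <- function(x, ...) {
  cat(sprintf("KM vs model survival: max |KM - f5| = %.4f over %d time points\n",
              x$discrepancy, length(x$time)))
  invisible(x)
}

#' @export
plot.crmix_gof <- function(x, ...) {
  graphics::plot(x$time, x$km, type = "s", ylim = c(0, 1),
                 xlab = "years since 1-year landmark",
                 ylab = "all-cause survival", ...)
  graphics::lines(x$time, x$f5, col = 2, lwd = 2)
  graphics::legend("topright", c("Kaplan-Meier", "model f5"),
                   lty = 1, col = c(1, 2), bty = "n")
  invisible(x)
}
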