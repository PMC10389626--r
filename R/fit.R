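#' Fit the competing-risks mixture survival model by maximum likelihood
#'
#' Maximizes the interval-censored mixture likelihood: a logistic model for
#' the eventual cause of death times cause-conditional parametric survival
#' on the landmark time scale, with deaths treated as daily interval masses.
#' Optimization is quasi-Newton (BFGS) with an analytic gradient and an
#' optional multi-start over jittered initial values; standard errors come
#' from the inverted observed-information matrix.
#'
#' @param data a `crmix_cohort` (raw covariates) or an encoded data frame
#'   (see [encode_cohort()]) carrying `time` and `event` columns.
#' @param formulas per-parameter formula list, see [crmix_formulas()].
#' @param family `"loglogistic"` (default, the published model),
#'   `"weibull"`, or `"gompertz"`.
#' @param delta interval width for death times, in landmark years; default
#'   one day, 1/365.25.
#' @param init optional `crmix_params` or flattened named vector of starting
#'   values.
#' @param nstart number of optimizer starts (first is `init` or the default
#'   start; the rest are jittered reproducibly).
#' @param jitter_sd standard deviation of the start jitter.
#' @param start_seed seed for the jittered starts.
#' @param maxit,reltol BFGS control.
#' @param hessian compute the observed information and standard errors.
#' @param age_center,age_scale encoding constants applied when `data` holds
#'   raw covariates.
#' @return an object of class `"crmix"`: coefficients, fitted
#'   `crmix_params`, log-likelihood, AIC, covariance matrix, convergence
#'   diagnostics.
#' @export
crmix <- function(data, formulas = crmix_formulas(),
                  family = c("loglogistic", "weibull", "gompertz"),
                  delta = 1 / 365.25, init = NULL, nstart = 3,
                  jitter_sd = 0.25, start_seed = 1,
                  maxit = 1000, reltol = 1e-10, hessian = TRUE,
                  age_center = 65.1, age_scale = 10) {
  family <- match.arg(family)
  cl <- match.call()
  enc <- if (inherits(data, "crmix_cohort"))
    encode_cohort(data, age_center, age_scale) else as.data.frame(data)
  if (is.null(enc$time) || is.null(enc$event))
    stop("data must carry time and event columns")
  if (nrow(enc) == 0) stop("empty cohort")
  if (sum(enc$event == 1) == 0 || sum(enc$event == 2) == 0)
    warning("cohort lacks events of both causes; fit may be degenerate")

  template <- .params_template(enc, formulas, family, age_center, age_scale)
  design <- crmix_design(enc, template)
  obj <- .make_objective(design, template, delta)

  start0 <- if (is.null(init)) .default_start(enc, template)
  else if (inherits(init, "crmix_params")) flatten_params(init)
  else init
  starts <- list(start0)
  if (nstart > 1) {
    rs <- .with_seed(start_seed, lapply(seq_len(nstart - 1), function(i)
      stats::rnorm(obj$k, 0, jitter_sd)))
    for (i in seq_along(rs)) starts[[i + 1]] <- start0 + rs[[i]]
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj$fn, obj$gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  theta <- stats::setNames(best$par, names(flatten_params(template)))
  params <- unflatten_params(theta, template)
  loglik <- -obj$fn(theta)
  gnorm <- sqrt(sum(obj$gr(theta)^2))
  status <- if (best$convergence == 0) "converged" else "not_converged"

  vc <- se <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(theta, obj$fn, obj$gr),
                  error = function(e) NULL)
    vc <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(vc)) {
      dimnames(vc) <- list(names(theta), names(theta))
      se <- sqrt(pmax(diag(vc), 0))
    }
  }

  out <- structure(list(
    coefficients = theta, params = params, loglik = loglik,
    aic = 2 * obj$k - 2 * loglik, k = obj$k, vcov = vc, se = se,
    convergence = list(status = status, iterations = best$counts[["function"]],
                       gradient_norm = gnorm, optim_code = best$convergence),
    monotone = params$monotone, family = family, delta = delta,
    formulas = formulas, n = nrow(enc),
    nevent = c(cancer = sum(enc$event == 1), other = sum(enc$event == 2),
               censored = sum(enc$event == 0)),
    data = enc, call = cl), class = "crmix")
  if (!out$monotone)
    warning("fitted parameters violate the decreasing-survival condition")
  out
}

# template parameter object with zero coefficients named after the
# design-matrix columns of each formula
.params_template <- function(enc, formulas, family, age_center, age_scale) {
  zero <- lapply(formulas, function(f) {
    mm <- stats::model.matrix(f, data = utils::head(as.data.frame(enc), 1))
    stats::setNames(numeric(ncol(mm)), colnames(mm))
  })
  crmix_params(alpha = zero$alpha, eta = zero$eta, phi = zero$phi,
               gamma = zero$gamma, rho = zero$rho, family = family,
               formulas = formulas, age_center = age_center,
               age_scale = age_scale)
}

.default_start <- function(enc, template) {
  th <- flatten_params(template)
  ev <- enc$event[enc$event > 0]
  p1 <- if (length(ev)) (sum(ev == 1) + 0.5) / (length(ev) + 1) else 0.5
  th["alpha.(Intercept)"] <- stats::qlogis(p1)
  th["eta.(Intercept)"] <- 1
  th["phi.(Intercept)"] <- -0.5
  th["rho.(Intercept)"] <- -0.1
  th
}

# evaluate expr under a temporary seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Compare candidate survival-time families by AIC
#'
#' Fits the model under each family on identical design vectors and ranks
#' them by AIC; per-family fit failures are reported in the table rather
#' than propagated.
#'
#' @inheritParams crmix
#' @param families families to fit.
#' @param ... further arguments passed to [crmix()].
#' @return data frame with columns `family`, `k`, `loglik`, `aic`,
#'   `converged`, sorted by AIC; the fits are attached as attribute
#'   `"fits"`.
#' @export
compare_families <- function(data, formulas = crmix_formulas(),
                             families = c("loglogistic", "weibull", "gompertz"),
                             ...) {
  fits <- lapply(families, function(fam)
    tryCatch(suppressWarnings(crmix(data, formulas, family = fam, ...)),
             error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, "error")
  tab <- data.frame(
    family = families,
    k = vapply(fits, function(f) if (inherits(f, "crmix")) f$k else NA_integer_, 1L),
    loglik = vapply(fits, function(f) if (inherits(f, "crmix")) f$loglik else NA_real_, 1),
    aic = vapply(fits, function(f) if (inherits(f, "crmix")) f$aic else NA_real_, 1),
    converged = vapply(fits, function(f)
      inherits(f, "crmix") && f$convergence$status == "converged", TRUE),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, families)
  tab
}

#' @export
print.crmix <- function(x, ...) {
  cat("Competing-risks mixture survival model (", x$family, ")\n", sep = "")
  cat(sprintf("  n = %d (%d cancer deaths, %d other-cause deaths, %d censored)\n",
              x$n, x$nevent["cancer"], x$nevent["other"], x$nevent["censored"]))
  cat(sprintf("  log-likelihood = %.3f, AIC = %.3f, %s\n",
              x$loglik, x$aic, x$convergence$status))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.crmix <- function(object, ...) {
  est <- object$coefficients
  se <- if (is.null(object$se)) rep(NA_real_, length(est)) else object$se
  z <- est / se
  tab <- data.frame(estimate = est, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se)
  out <- list(coefficients = tab, loglik = object$loglik, aic = object$aic,
              n = object$n, nevent = object$nevent, family = object$family,
              convergence = object$convergence, monotone = object$monotone)
  class(out) <- "summary.crmix"
  out
}

#' @export
print.summary.crmix <- function(x, ...) {
  cat("Competing-risks mixture survival model (", x$family, ")\n", sep = "")
  cat(sprintf("  n = %d, log-likelihood = %.3f, AIC = %.3f (%s, %d evals)\n",
              x$n, x$loglik, x$aic, x$convergence$status,
              x$convergence$iterations))
  printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "z", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  if (!x$monotone)
    cat("warning: decreasing-survival condition violated\n")
  invisible(x)
}

#' @export
coef.crmix <- function(object, ...) object$coefficients

#' @export
vcov.crmix <- function(object, ...) object$vcov

#' @export
logLik.crmix <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
residuals.crmix <- function(object, ...) {
  # per-record log-likelihood contributions (deaths: log f2 + log f4;
  # censored: log f5), useful for spotting poorly-fit records
  enc <- object$data
  p <- object$params
  out <- numeric(nrow(enc))
  ev <- enc$event > 0
  if (any(ev)) {
    de <- crmix_design(enc[ev, , drop = FALSE], p)
    p1 <- cause_probability(de, p)
    out[ev] <- log(ifelse(enc$event[ev] == 1, p1, 1 - p1)) +
      log(interval_density_f4(enc$time[ev], enc$event[ev], de, p,
                              object$delta))
  }
  if (any(!ev)) {
    dc <- crmix_design(enc[!ev, , drop = FALSE], p)
    out[!ev] <- log(censored_survival_f5(enc$time[!ev], dc, p))
  }
  out
}

#' Predict cumulative incidence from a fitted model
#'
#' @param object a fitted `crmix` model.
#' @param newdata patient rows (raw or encoded); defaults to the fitted
#'   cohort.
#' @param times evaluation times on the landmark scale; for `type =
#'   "conditional"` these are additional years beyond `t0`.
#' @param t0 landmark years already survived (only for
#'   `type = "conditional"`).
#' @param type `"cif"` for cause-specific and total cumulative incidence,
#'   `"survival"` for the mixture survival f5, `"conditional"` for risks
#'   conditional on having survived to `t0`.
#' @param ... unused.
#' @return a data frame; for multi-row `newdata` a `row` column indexes
#'   patients.
#' @export
predict.crmix <- function(object, newdata = NULL, times = 1:4, t0 = 0,
                          type = c("cif", "survival", "conditional"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  params <- object$params
  if (type == "conditional")
    return(conditional_cif(times, t0, newdata, params))
  design <- crmix_design(newdata, params)
  n <- attr(design, "n")
  grid <- expand.grid(row = seq_len(n), time = times)
  di <- .design_rows(design, grid$row)
  if (type == "survival") {
    data.frame(grid, survival = censored_survival_f5(grid$time, di, params))
  } else {
    ci <- cif(grid$time, di, params)
    data.frame(grid, ci)
  }
}

# subset a crmix_design by row indices
.design_rows <- function(design, idx) {
  out <- lapply(unclass(design)[c("alpha", "eta", "phi", "gamma", "rho")],
                function(m) m[idx, , drop = FALSE])
  if (!is.null(attr(design, "time"))) attr(out, "time") <- attr(design, "time")[idx]
  if (!is.null(attr(design, "event"))) attr(out, "event") <- attr(design, "event")[idx]
  attr(out, "n") <- length(idx)
  class(out) <- "crmix_design"
  out
}

#' Simulate cohorts from a fitted model
#'
#' Draws event causes and times for the covariate rows of `newdata` from the
#' fitted parameters, applying administrative censoring at `cap`.
#'
#' @param object a fitted `crmix` model.
#' @param nsim number of simulated cohorts.
#' @param seed RNG seed.
#' @param newdata covariate rows (default: the fitted cohort's).
#' @param cap administrative censoring cap in landmark years.
#' @param ... unused.
#' @return a list of `nsim` data frames with columns `time`, `event`.
#' @export
simulate.crmix <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                           cap = 4, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data
  design <- crmix_design(newdata, object$params)
  lapply(seq_len(nsim), function(i)
    simulate_event(design, object$params, cap = cap))
}

#' @export
plot.crmix <- function(x, newdata = NULL, times = seq(0.02, 4, by = 0.02),
                       ...) {
  if (is.null(newdata)) newdata <- x$data[1, , drop = FALSE]
  cc <- cif_curves(times, newdata, x$params)
  plot(cc, ...)
  invisible(cc)
}
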