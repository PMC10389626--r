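# Model primitives.
#
# The model factorizes a patient's contribution into a logistic
# cause-assignment probability f2 and a cause-conditional survival function
# S4 driven by the time index
#   v(t | d, x) = 1{d=1} * x_g'gamma + x_e'eta + w(t) * x_p'phi
#                 + 1{d=1} * w(t) * x_r'rho
# with w(t) = log t (log-logistic, Weibull) or t (Gompertz). Deaths enter the
# likelihood as daily interval masses f4 = S4(t) - S4(t + delta); censored
# records contribute the mixture survival f5 = sum_j S4(t|j) f2(j).

.links <- list(
  loglogistic = list(S = function(v) stats::plogis(v),
                     dS = function(v) { s <- stats::plogis(v); s * (1 - s) }),
  weibull     = list(S = function(v) exp(-exp(-v)),
                     dS = function(v) exp(-exp(-v) - v)),
  gompertz    = list(S = function(v) exp(-exp(-v)),
                     dS = function(v) exp(-exp(-v) - v))
)

.time_basis <- function(t, family) if (family == "gompertz") t else log(t)

#' Build per-parameter design matrices
#'
#' Applies the parameter set's formulas to (raw or already-encoded) patient
#' data, producing the five design matrices whose columns match the
#' coefficient names of each block.
#'
#' @param newdata a `crmix_cohort`, raw covariate data frame, or the output
#'   of [encode_cohort()].
#' @param params a `crmix_params` supplying formulas and encoding constants.
#' @return list of matrices `alpha`, `eta`, `phi`, `gamma`, `rho` with
#'   attributes `time`/`event` when present; class `"crmix_design"`.
#' @export
crmix_design <- function(newdata, params) {
  if (inherits(newdata, "crmix_design")) return(newdata)
  needed <- unique(unlist(lapply(params$formulas, all.vars)))
  if (!all(needed %in% names(newdata))) {
    newdata <- encode_cohort(newdata, age_center = params$age_center,
                             age_scale = params$age_scale)
  }
  out <- lapply(params$formulas, function(f)
    stats::model.matrix(f, data = as.data.frame(newdata)))
  for (b in names(out)) {
    want <- names(params$coefficients[[b]])
    if (!is.null(want) && !identical(colnames(out[[b]]), want)) {
      if (!all(want %in% colnames(out[[b]])))
        stop("design/coefficient mismatch in block ", b)
      out[[b]] <- out[[b]][, want, drop = FALSE]
    }
  }
  attr(out, "time") <- newdata$time
  attr(out, "event") <- newdata$event
  attr(out, "n") <- nrow(out$alpha)
  class(out) <- "crmix_design"
  out
}

# linear predictors for each block, recycled checks left to callers
.linpred <- function(design, params) {
  cf <- params$coefficients
  list(a = as.vector(design$alpha %*% cf$alpha),
       e = as.vector(design$eta %*% cf$eta),
       p = as.vector(design$phi %*% cf$phi),
       g = as.vector(design$gamma %*% cf$gamma),
       r = as.vector(design$rho %*% cf$rho))
}

#' Cause-assignment probability f2
#'
#' The logistic probability that a patient's eventual death is from
#' esophageal cancer (cause 1), `f2(d = 1 | x) = plogis(x_a' alpha)`; the
#' other-cause probability is its complement.
#'
#' @param newdata patient data (raw, encoded, or a `crmix_design`).
#' @param params a `crmix_params`.
#' @param cause 1 (cancer) or 2 (other cause).
#' @return probability vector, one per patient row.
#' @export
cause_probability <- function(newdata, params, cause = 1) {
  stopifnot(cause %in% 1:2)
  design <- crmix_design(newdata, params)
  p1 <- stats::plogis(as.vector(design$alpha %*% params$coefficients$alpha))
  if (cause == 1) p1 else 1 - p1
}

#' Time index v of the survival function
#'
#' `v(t|d,x) = 1{d=1} x_g'gamma + x_e'eta + w(t) x_p'phi
#'  + 1{d=1} w(t) x_r'rho`, with `w(t) = log t` for the log-logistic and
#' Weibull families and `w(t) = t` for Gompertz.
#'
#' @param t time(s) on the landmark scale, > 0.
#' @param d cause, 1 or 2 (scalar or vector).
#' @inheritParams cause_probability
#' @return numeric vector.
#' @export
time_index_v <- function(t, d, newdata, params) {
  if (any(t <= 0)) stop("t must be > 0")
  stopifnot(all(d %in% 1:2))
  design <- crmix_design(newdata, params)
  lp <- .linpred(design, params)
  w <- .time_basis(t, params$family)
  ind <- as.numeric(d == 1)
  lp$e + ind * lp$g + w * (lp$p + ind * lp$r)
}

#' Cause-conditional survival function S4
#'
#' Survival of the latent cause-specific event time: the inverse logit of the
#' time index `v` for the log-logistic family, `exp(-exp(-v))` for Weibull
#' and Gompertz. Decreasing from 1 to 0 in t when the slope condition of
#' [is_monotone()] holds.
#'
#' @inheritParams time_index_v
#' @return probability vector.
#' @export
survival_S4 <- function(t, d, newdata, params) {
  v <- time_index_v(t, d, newdata, params)
  .links[[params$family]]$S(v)
}

#' Daily interval death mass f4
#'
#' The probability of dying from cause `d` in the interval `[t, t + delta)`:
#' `S4(t) - S4(t + delta)`. Non-negative under a monotone parameter set; a
#' negative value is flagged as a numeric error.
#'
#' @inheritParams time_index_v
#' @param delta interval width in landmark years (default one day).
#' @export
interval_density_f4 <- function(t, d, newdata, params, delta = 1 / 365.25) {
  if (any(delta <= 0)) stop("delta must be > 0")
  out <- survival_S4(t, d, newdata, params) -
    survival_S4(t + delta, d, newdata, params)
  if (any(out < 0))
    stop("negative interval mass: parameters violate the monotonicity condition")
  out
}

#' Mixture survival f5
#'
#' Probability of being alive (from either cause) at time t:
#' `f5(t|x) = S4(t|1) f2(1|x) + S4(t|2) f2(2|x)`. Equals
#' `1 - cif_total(t)`.
#'
#' @inheritParams time_index_v
#' @export
censored_survival_f5 <- function(t, newdata, params) {
  design <- crmix_design(newdata, params)
  p1 <- cause_probability(design, params, 1)
  survival_S4(t, 1, design, params) * p1 +
    survival_S4(t, 2, design, params) * (1 - p1)
}

#' Model log-likelihood of a cohort
#'
#' Sums per-patient log contributions: deaths contribute
#' `log f2(d|x) + log[S4(t|d) - S4(t+delta|d)]`, censored records
#' `log f5(t|x)`. Returns `-Inf` when any contribution is non-positive and
#' reports the offending record index.
#'
#' @param data a `crmix_cohort` or encoded data frame with `time`, `event`.
#' @param params a `crmix_params`.
#' @param delta daily interval width (landmark years).
#' @export
crmix_loglik <- function(data, params, delta = 1 / 365.25) {
  design <- crmix_design(data, params)
  obj <- .make_objective(design, params, delta)
  -obj$fn(flatten_params(params), report = TRUE)
}

# Objective factory: negative log-likelihood and analytic gradient over the
# flattened parameter vector, with matrices pre-subset by event group.
.make_objective <- function(design, params, delta) {
  t <- attr(design, "time"); d <- attr(design, "event")
  if (is.null(t) || is.null(d)) stop("data must carry time and event columns")
  family <- params$family
  link <- .links[[family]]
  iE <- which(d > 0); i0 <- which(d == 0)
  ind <- as.numeric(d[iE] == 1)
  ks <- vapply(params$coefficients, length, 1L)
  blocks <- names(ks)
  off <- cumsum(c(0, ks))[seq_along(ks)]
  names(off) <- blocks
  X <- lapply(blocks, function(b) design[[b]])
  names(X) <- blocks
  XE <- lapply(X, function(m) m[iE, , drop = FALSE])
  X0 <- lapply(X, function(m) m[i0, , drop = FALSE])
  wE1 <- .time_basis(t[iE], family)
  wE2 <- .time_basis(t[iE] + delta, family)
  w0 <- .time_basis(t[i0], family)

  split_theta <- function(theta)
    lapply(blocks, function(b) theta[off[[b]] + seq_len(ks[[b]])])

  parts <- function(theta) {
    th <- split_theta(theta); names(th) <- blocks
    pE <- stats::plogis(drop(XE$alpha %*% th$alpha))
    eE <- drop(XE$eta %*% th$eta); phE <- drop(XE$phi %*% th$phi)
    gE <- drop(XE$gamma %*% th$gamma); rE <- drop(XE$rho %*% th$rho)
    v1 <- eE + ind * gE + wE1 * (phE + ind * rE)
    v2 <- eE + ind * gE + wE2 * (phE + ind * rE)
    p0 <- stats::plogis(drop(X0$alpha %*% th$alpha))
    e0 <- drop(X0$eta %*% th$eta); ph0 <- drop(X0$phi %*% th$phi)
    g0 <- drop(X0$gamma %*% th$gamma); r0 <- drop(X0$rho %*% th$rho)
    vA <- e0 + g0 + w0 * (ph0 + r0)   # cause 1
    vB <- e0 + w0 * ph0               # cause 2
    list(pE = pE, v1 = v1, v2 = v2, p0 = p0, vA = vA, vB = vB)
  }

  fn <- function(theta, report = FALSE) {
    pp <- parts(theta)
    f4 <- link$S(pp$v1) - link$S(pp$v2)
    lE <- log(ifelse(ind == 1, pp$pE, 1 - pp$pE)) + log(pmax(f4, 0))
    f5 <- pp$p0 * link$S(pp$vA) + (1 - pp$p0) * link$S(pp$vB)
    l0 <- log(f5)
    ll <- sum(lE) + sum(l0)
    if (!is.finite(ll)) {
      if (report) {
        bad <- c(iE[!is.finite(lE)], i0[!is.finite(l0)])
        warning("non-finite likelihood contribution at record(s) ",
                paste(utils::head(bad, 5), collapse = ", "))
        return(-Inf)
      }
      return(1e10 + sum(theta^2))
    }
    -ll
  }

  gr <- function(theta) {
    pp <- parts(theta)
    S1 <- link$S(pp$v1); S2 <- link$S(pp$v2)
    f4 <- S1 - S2
    SA <- link$S(pp$vA); SB <- link$S(pp$vB)
    f5 <- pp$p0 * SA + (1 - pp$p0) * SB
    if (any(f4 <= 0) || any(f5 <= 0) || !all(is.finite(c(f4, f5))))
      return(2 * theta)
    c1 <- link$dS(pp$v1) / f4; c2 <- link$dS(pp$v2) / f4
    dA <- link$dS(pp$vA); dB <- link$dS(pp$vB)
    g <- numeric(length(theta))
    put <- function(b, val) g[off[[b]] + seq_len(ks[[b]])] <<-
      g[off[[b]] + seq_len(ks[[b]])] + val
    # events
    put("alpha", colSums((ind - pp$pE) * XE$alpha))
    put("eta",   colSums((c1 - c2) * XE$eta))
    put("phi",   colSums((c1 * wE1 - c2 * wE2) * XE$phi))
    put("gamma", colSums(ind * (c1 - c2) * XE$gamma))
    put("rho",   colSums(ind * (c1 * wE1 - c2 * wE2) * XE$rho))
    # censored
    q0 <- 1 - pp$p0
    put("alpha", colSums(((SA - SB) * pp$p0 * q0 / f5) * X0$alpha))
    mix <- (pp$p0 * dA + q0 * dB) / f5
    put("eta",   colSums(mix * X0$eta))
    put("phi",   colSums(mix * w0 * X0$phi))
    put("gamma", colSums((pp$p0 * dA / f5) * X0$gamma))
    put("rho",   colSums((pp$p0 * dA / f5) * w0 * X0$rho))
    -g
  }

  list(fn = fn, gr = gr, k = sum(ks), ks = ks, off = off, blocks = blocks)
}
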