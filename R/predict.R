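# Cumulative incidence and conditional (dynamic) risk prediction: the
# computational core of the published interactive calculator.

#' Cause-specific and total cumulative incidence
#'
#' `CIF_cancer(t) = [1 - S4(t|1)] f2(1)`, `CIF_other(t) = [1 - S4(t|2)]
#' [1 - f2(1)]`, `CIF_total = CIF_cancer + CIF_other = 1 - f5(t)`.
#'
#' @param t time(s) on the landmark scale, > 0 (t = 0 is defined as zero
#'   incidence and accepted).
#' @param newdata patient rows (raw, encoded, or a `crmix_design`); recycled
#'   against `t` when one of the two has length 1.
#' @param params a `crmix_params`.
#' @return data frame with columns `cif_cancer`, `cif_other`, `cif_total`.
#' @export
cif <- function(t, newdata, params) {
  if (any(t < 0)) stop("t must be >= 0")
  design <- crmix_design(newdata, params)
  p1 <- cause_probability(design, params, 1)
  tt <- pmax(t, .Machine$double.eps)  # CIF(0) := 0, reached continuously
  cc <- (1 - survival_S4(tt, 1, design, params)) * p1
  co <- (1 - survival_S4(tt, 2, design, params)) * (1 - p1)
  cc[t == 0] <- 0; co[t == 0] <- 0
  data.frame(cif_cancer = cc, cif_other = co, cif_total = cc + co)
}

#' Cumulative incidence curves for one patient profile
#'
#' @param times strictly increasing evaluation grid (landmark years).
#' @param profile a single patient row.
#' @param params a `crmix_params`.
#' @return data frame of class `"crmix_cif"` with `time` and the three
#'   incidence series.
#' @export
cif_curves <- function(times, profile, params) {
  stopifnot(all(diff(times) > 0))
  design <- crmix_design(profile, params)
  if (attr(design, "n") != 1) stop("profile must be a single patient row")
  out <- data.frame(time = times, cif(times, design, params))
  class(out) <- c("crmix_cif", "data.frame")
  out
}

#' @export
plot.crmix_cif <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$cif_total, x$cif_cancer, x$cif_other),
                    type = "l", lty = c(1, 2, 3), col = c(1, 2, 4),
                    xlab = "years since 1-year landmark",
                    ylab = "cumulative incidence", ylim = c(0, 1), ...)
  graphics::legend("topleft", c("total", "cancer", "other cause"),
                   lty = c(1, 2, 3), col = c(1, 2, 4), bty = "n")
  invisible(x)
}

#' Conditional cumulative incidence given survival to t0
#'
#' For a patient alive `t0` landmark years after the 1-year post-surgery
#' landmark, the risk over the next `t_add` years:
#' cancer-specific `[CIF_cancer(t0 + t) - CIF_cancer(t0)] / [1 - CIF(t0)]`
#' and all-cause `1 - [1 - CIF(t0 + t)] / [1 - CIF(t0)]`. At `t0 = 0`
#' (survived exactly one post-surgery year) both reduce to the
#' unconditional CIFs.
#'
#' @param t_add additional years (>= 0), may be a vector.
#' @param t0 landmark years already survived (>= 0).
#' @param newdata a single patient row.
#' @param params a `crmix_params`.
#' @return data frame with `t0`, `horizon`, `cif_cancer`, `cif_allcause`.
#' @export
conditional_cif <- function(t_add, t0, newdata, params) {
  stopifnot(length(t0) == 1, t0 >= 0, all(t_add >= 0))
  design <- crmix_design(newdata, params)
  if (attr(design, "n") != 1) stop("newdata must be a single patient row")
  base <- cif(t0, design, params)
  if (base$cif_total >= 1 - 1e-12)
    stop("CIF(t0) is numerically 1; conditional risk undefined")
  later <- cif(t0 + t_add, design, params)
  denom <- 1 - base$cif_total
  data.frame(
    t0 = t0, horizon = t_add,
    cif_cancer = (later$cif_cancer - base$cif_cancer) / denom,
    cif_allcause = 1 - (1 - later$cif_total) / denom)
}

#' Patient-level conditional risk table
#'
#' The calculator interface: takes the time already survived on the
#' post-surgery scale (>= 1 year, as users state it), converts to the
#' landmark scale internally, and tabulates conditional all-cause and
#' cancer-specific risks at the requested additional horizons. The
#' supported domain is 1 to 5 post-surgery years, the follow-up the model
#' was fitted on; extrapolation beyond 5 years is refused unless
#' `allow_extrapolation = TRUE`.
#'
#' @param profile a single patient row (raw covariates).
#' @param t0_post_surgery years survived since surgery, in [1, 5).
#' @param horizons additional years ahead.
#' @param params a `crmix_params`.
#' @param allow_extrapolation override the 5-year domain cap (with a
#'   warning).
#' @return data frame with one row per horizon.
#' @export
risk_table <- function(profile, t0_post_surgery, horizons, params,
                       allow_extrapolation = FALSE) {
  if (t0_post_surgery < 1)
    stop("t0 must be >= 1 post-surgery year (the model's landmark); ",
         "supported domain is 1-5 years after surgery")
  if (t0_post_surgery + max(horizons) > 5 + 1e-9) {
    if (allow_extrapolation)
      warning("extrapolating beyond the 5-year post-surgery support")
    else
      stop("t0 + horizon exceeds 5 post-surgery years; the model supports ",
           "predictions between 1 and 5 years after surgery ",
           "(set allow_extrapolation = TRUE to override)")
  }
  out <- conditional_cif(horizons, t0_post_surgery - 1, profile, params)
  data.frame(t0_post_surgery = t0_post_surgery, horizon = out$horizon,
             cif_allcause = out$cif_allcause, cif_cancer = out$cif_cancer)
}

#' The published worked-example patient profile
#'
#' A 65-year-old man with 9 years of education, squamous cell carcinoma of
#' pathological stage 0-I, no neoadjuvant chemo(radio)therapy, tumor-free
#' resection margins, no reoperation, and no recorded comorbidity.
#'
#' @return a one-row data frame of raw covariates.
#' @export
example_profile <- function() {
  data.frame(patient_id = "example", age = 65, sex = "male",
             education_gt12 = "no", cci_class = "0",
             histology = "squamous_cell_carcinoma", chemoradiotherapy = "no",
             stage = "0-i", margin = "r0", reoperation_30d = "no",
             stringsAsFactors = FALSE)
}
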