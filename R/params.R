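# Parameter container: five coefficient blocks (alpha for the logistic
# cause-assignment model; eta, phi, gamma, rho entering the time index v),
# a distribution family, and the encoding constants / per-block formulas
# needed to rebuild design matrices from raw covariates.

.default_formulas <- function() {
  list(alpha = ~ age_s + scc + chemo + stage2 + stage3 + stage4 + r1r2,
       eta   = ~ age_s + female + educ_gt12 + scc + stage3 + stage4 + r1r2 + reop,
       phi   = ~ 1,
       gamma = ~ 1,
       rho   = ~ 1)
}

#' Per-parameter model formulas
#'
#' Returns the formula list defining which encoded covariates enter each of
#' the five model parameters. The defaults are the final published model:
#' seven predictors in `eta` (with stage II merged into the stage 0-I
#' reference), five in `alpha`, and intercept-only time-scale parameters
#' `phi`, `gamma`, `rho`. Formulas are evaluated against the columns of
#' [encode_cohort()].
#'
#' @param alpha,eta,phi,gamma,rho one-sided formulas; omitted blocks keep
#'   their default.
#' @return named list of formulas with class `"crmix_formulas"`.
#' @export
crmix_formulas <- function(alpha, eta, phi, gamma, rho) {
  f <- .default_formulas()
  if (!missing(alpha)) f$alpha <- alpha
  if (!missing(eta))   f$eta   <- eta
  if (!missing(phi))   f$phi   <- phi
  if (!missing(gamma)) f$gamma <- gamma
  if (!missing(rho))   f$rho   <- rho
  structure(f, class = "crmix_formulas")
}

#' Construct a model parameter set
#'
#' @param alpha,eta,phi,gamma,rho named numeric coefficient vectors; names
#'   must match the design-matrix columns generated by `formulas`.
#' @param family survival-time distribution for the cause-specific times:
#'   `"loglogistic"` (survival is the inverse logit of the time index v),
#'   `"weibull"` (complementary log-log link on v), or `"gompertz"` (same
#'   link with t replacing log t inside v).
#' @param formulas per-parameter formula list, see [crmix_formulas()].
#' @param age_center,age_scale encoding constants, see [encode_cohort()].
#' @return object of class `"crmix_params"`.
#' @export
crmix_params <- function(alpha, eta, phi, gamma, rho,
                         family = c("loglogistic", "weibull", "gompertz"),
                         formulas = crmix_formulas(),
                         age_center = 65.1, age_scale = 10) {
  family <- match.arg(family)
  coefs <- list(alpha = alpha, eta = eta, phi = phi, gamma = gamma, rho = rho)
  for (b in names(coefs)) {
    if (!is.numeric(coefs[[b]]) || any(!is.finite(coefs[[b]])))
      stop("non-finite coefficients in block ", b)
  }
  obj <- structure(list(coefficients = coefs, family = family,
                        formulas = formulas, age_center = age_center,
                        age_scale = age_scale),
                   class = "crmix_params")
  obj$monotone <- is_monotone(obj)
  obj
}

#' Check the decreasing-survival condition
#'
#' For the log-logistic and Weibull families the survival function S4 is
#' decreasing in time for both causes exactly when the log-time slope is
#' negative: `phi` intercept < 0 (other-cause death) and `phi + rho`
#' intercept < 0 (cancer death). For Gompertz the same condition applies to
#' the linear-time slope. Violation is reported, not fatal: such parameter
#' sets define no valid survival model and fits landing there carry a
#' warning flag.
#'
#' @param params a `crmix_params`.
#' @return logical.
#' @export
is_monotone <- function(params) {
  p0 <- unname(params$coefficients$phi[1])
  r0 <- unname(params$coefficients$rho[1])
  is.finite(p0) && is.finite(r0) && p0 < 0 && (p0 + r0) < 0
}

#' @export
print.crmix_params <- function(x, ...) {
  cat("Competing-risks mixture parameters (", x$family, ")\n", sep = "")
  for (b in names(x$coefficients)) {
    cat("  ", b, ":\n", sep = "")
    print(round(x$coefficients[[b]], 4))
  }
  if (!x$monotone)
    cat("  [warning] survival not decreasing in t for both causes\n")
  invisible(x)
}

#' Flatten / rebuild parameter vectors
#'
#' `flatten_params()` concatenates the five blocks into one named vector
#' (`block.name` naming convention); `unflatten_params()` is its inverse
#' given a template parameter object.
#'
#' @param params a `crmix_params`.
#' @return named numeric vector.
#' @export
flatten_params <- function(params) {
  unlist(lapply(names(params$coefficients), function(b) {
    v <- params$coefficients[[b]]
    stats::setNames(as.numeric(v), paste(b, names(v), sep = "."))
  }))
}

#' @rdname flatten_params
#' @param theta named numeric vector as produced by `flatten_params()`.
#' @param template a `crmix_params` supplying block sizes, family, formulas.
#' @export
unflatten_params <- function(theta, template) {
  out <- template
  i <- 0L
  for (b in names(out$coefficients)) {
    k <- length(out$coefficients[[b]])
    out$coefficients[[b]][] <- theta[i + seq_len(k)]
    i <- i + k
  }
  out$monotone <- is_monotone(out)
  out
}

#' Serialize parameters to a flat key-value text file
#'
#' One `key value` pair per line: the family, the encoding constants, each
#' formula (deparsed), and each coefficient as `block.name`. The published
#' final-model coefficients ship with the package in this format (see
#' [published_params()]).
#'
#' @param params a `crmix_params`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  lines <- c(paste("family", params$family),
             paste("age_center", format(params$age_center, digits = 15)),
             paste("age_scale", format(params$age_scale, digits = 15)),
             vapply(names(params$formulas), function(b)
               paste0("formula.", b, " ", paste(deparse(params$formulas[[b]]),
                                                collapse = "")),
               character(1)))
  th <- flatten_params(params)
  lines <- c(lines, paste(names(th), format(th, digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  key <- sub(" .*$", "", lines)
  val <- sub("^[^ ]+ ", "", lines)
  getv <- function(k) val[match(k, key)]
  formulas <- crmix_formulas()
  for (b in names(formulas)) {
    fk <- paste0("formula.", b)
    if (fk %in% key) formulas[[b]] <- stats::as.formula(getv(fk))
  }
  blocks <- list()
  for (b in c("alpha", "eta", "phi", "gamma", "rho")) {
    sel <- startsWith(key, paste0(b, ".")) & !startsWith(key, "formula.")
    nm <- sub(paste0("^", b, "\\."), "", key[sel])
    blocks[[b]] <- stats::setNames(as.numeric(val[sel]), nm)
  }
  crmix_params(alpha = blocks$alpha, eta = blocks$eta, phi = blocks$phi,
               gamma = blocks$gamma, rho = blocks$rho,
               family = getv("family"), formulas = formulas,
               age_center = as.numeric(getv("age_center")),
               age_scale = as.numeric(getv("age_scale")))
}

#' Published final-model coefficients
#'
#' Loads the final-model coefficient fixture shipped with the package:
#' the log-odds coefficients of the cause-assignment model (`alpha`), the
#' survival-time location coefficients (`eta`), and the intercept-only
#' time-scale constants (`phi` = -0.76, `gamma` = -2.20, `rho` = -0.42),
#' log-logistic family, age centered at 65.1 years and scaled by 10.
#'
#' @return a `crmix_params`.
#' @export
published_params <- function() {
  read_params(system.file("extdata", "published_coefficients.txt",
                          package = "crmix", mustWork = TRUE))
}
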