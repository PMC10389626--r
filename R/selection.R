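# Bootstrap stability variable selection: sequential per-parameter Wald
# testing in a fixed order (eta, alpha, phi, gamma, rho), within-parameter
# interaction testing (none for rho, which is already a three-way
# interaction), repeated over bootstrap resamples with a majority rule.

# candidate term -> encoded columns; stage uses the merged coding (II with
# 0-I) inside eta and the full coding elsewhere
.default_candidates <- function() list(
  sex = "female", education = "educ_gt12", comorbidity = c("cci1", "cci2"),
  histology = "scc", chemoradiotherapy = "chemo",
  stage = c("stage2", "stage3", "stage4"), margin = "r1r2",
  reoperation = "reop")

#' Configure the variable-selection procedure
#'
#' Age and sex are selected a priori: both are forced into `eta`, age into
#' `alpha` (sex in `alpha` is left to testing), and neither is tested in the
#' time-scale parameters `phi`, `gamma`, `rho`. The remaining candidates are
#' tested one at a time per parameter, in the order `eta`, `alpha`, `phi`,
#' `gamma`, `rho`, and retained at `p < level`; pairwise interactions of the
#' retained terms are then tested within each parameter except `rho`.
#'
#' @param candidates named list mapping term names to encoded-column sets;
#'   the default is the eight non-age candidate predictors (stage as a
#'   multi-df group).
#' @param level significance level for retention.
#' @param B bootstrap replicates for [stability_selection()].
#' @param threshold inclusion-count threshold (strictly greater than);
#'   default majority, `B/2`.
#' @param seed RNG seed for the bootstrap stream.
#' @param order parameter testing order.
#' @param test_interactions test pairwise interactions of retained terms.
#' @param test `"wald"` (default) or `"lr"` (likelihood ratio).
#' @param stage_eta_merge apply the stage-II-to-reference merging when stage
#'   enters `eta`.
#' @return list of class `"crmix_selconfig"`.
#' @export
selection_config <- function(candidates = .default_candidates(),
                             level = 0.05, B = 100, threshold = B / 2,
                             seed = 1,
                             order = c("eta", "alpha", "phi", "gamma", "rho"),
                             test_interactions = TRUE,
                             test = c("wald", "lr"),
                             stage_eta_merge = TRUE) {
  stopifnot(level > 0, level < 1, B >= 1, threshold > 0, threshold <= B)
  structure(list(candidates = candidates, level = level, B = as.integer(B),
                 threshold = threshold, seed = seed, order = order,
                 test_interactions = isTRUE(test_interactions),
                 test = match.arg(test),
                 stage_eta_merge = isTRUE(stage_eta_merge)),
            class = "crmix_selconfig")
}

#' Wald p-value for a coefficient or coefficient group
#'
#' Two-sided Wald test for a single coefficient, multi-df Wald chi-square
#' for a group (e.g. the stage dummies), from the fit's
#' observed-information covariance.
#'
#' @param fit a converged `crmix` fit with available covariance.
#' @param term flattened coefficient name(s), e.g. `"eta.scc"` or
#'   `c("alpha.stage2", "alpha.stage3", "alpha.stage4")`.
#' @return p-value.
#' @export
wald_pvalue <- function(fit, term) {
  if (is.null(fit$vcov)) stop("covariance unavailable for this fit")
  if (!all(term %in% names(fit$coefficients)))
    stop("unknown coefficient(s): ",
         paste(setdiff(term, names(fit$coefficients)), collapse = ", "))
  b <- fit$coefficients[term]
  V <- fit$vcov[term, term, drop = FALSE]
  W <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(W)) stop("singular covariance block for ", paste(term, collapse = ","))
  stats::pchisq(W, df = length(b), lower.tail = FALSE)
}

# columns a term contributes to a given parameter block
.term_cols <- function(term, param, config) {
  cols <- config$candidates[[term]]
  if (term == "stage" && param == "eta" && config$stage_eta_merge)
    cols <- setdiff(cols, "stage2")
  cols
}

# base (forced-in) column sets per parameter
.base_cols <- function() list(alpha = "age_s", eta = c("age_s", "female"),
                              phi = character(0), gamma = character(0),
                              rho = character(0))

.cols_to_formula <- function(cols) {
  if (!length(cols)) ~1 else stats::reformulate(cols)
}

# fit the five-block model for given per-parameter column sets, warm-started
.fit_cols <- function(enc, col_sets, family, delta, warm = NULL) {
  fl <- crmix_formulas(alpha = .cols_to_formula(col_sets$alpha),
                       eta = .cols_to_formula(col_sets$eta),
                       phi = .cols_to_formula(col_sets$phi),
                       gamma = .cols_to_formula(col_sets$gamma),
                       rho = .cols_to_formula(col_sets$rho))
  init <- NULL
  if (!is.null(warm)) {
    tpl <- .params_template(enc, fl, family, 65.1, 10)
    init <- flatten_params(tpl)
    shared <- intersect(names(init), names(warm))
    init[shared] <- warm[shared]
  }
  suppressWarnings(crmix(enc, fl, family = family, delta = delta,
                         init = init, nstart = 1))
}

#' One pass of the sequential selection procedure
#'
#' For each parameter in the configured order, each candidate term is added
#' to the current model, its coefficients tested (Wald by default), and the
#' term retained permanently when `p < level`; within each parameter except
#' `rho`, pairwise interactions of the retained terms are then tested the
#' same way. Fit failures skip the step and count the term as not selected.
#'
#' @param data a `crmix_cohort` or encoded data frame with `time`/`event`.
#' @param config a `crmix_selconfig`.
#' @param family,delta passed to the fits.
#' @return list with `terms` (per-parameter term sets, forced terms
#'   included), `cols` (per-parameter encoded columns), `tests` (log of
#'   every test) and the final `fit`.
#' @export
select_once <- function(data, config = selection_config(),
                        family = "loglogistic", delta = 1 / 365.25) {
  enc <- if (inherits(data, "crmix_cohort")) encode_cohort(data)
  else as.data.frame(data)
  cols <- .base_cols()
  terms <- list(alpha = "age", eta = c("age", "sex"),
                phi = character(0), gamma = character(0), rho = character(0))
  tests <- list()
  log_test <- function(param, term, p, kept) tests[[length(tests) + 1L]] <<-
    data.frame(parameter = param, term = term, p = p, kept = kept,
               stringsAsFactors = FALSE)

  current_fit <- tryCatch(.fit_cols(enc, cols, family, delta),
                          error = function(e) NULL)
  warm <- if (!is.null(current_fit)) current_fit$coefficients else NULL

  try_term <- function(param, label, add_cols) {
    trial <- cols
    trial[[param]] <- c(trial[[param]], add_cols)
    fit <- tryCatch(.fit_cols(enc, trial, family, delta, warm = warm),
                    error = function(e) NULL)
    if (is.null(fit) || fit$convergence$status != "converged" ||
        is.null(fit$vcov)) {
      log_test(param, label, NA_real_, FALSE)
      return(FALSE)
    }
    p <- tryCatch({
      if (config$test == "lr" && !is.null(current_fit)) {
        stats::pchisq(2 * (fit$loglik - current_fit$loglik),
                      df = length(add_cols), lower.tail = FALSE)
      } else {
        wald_pvalue(fit, paste(param, add_cols, sep = "."))
      }
    }, error = function(e) NA_real_)
    kept <- is.finite(p) && p < config$level
    log_test(param, label, p, kept)
    if (kept) {
      cols <<- trial
      current_fit <<- fit
      warm <<- fit$coefficients
    }
    kept
  }

  for (param in config$order) {
    cand <- names(config$candidates)
    if (param %in% c("phi", "gamma", "rho"))
      cand <- setdiff(cand, c("age", "sex"))
    if (param == "eta") cand <- setdiff(cand, c("age", "sex"))
    if (param == "alpha") cand <- setdiff(cand, "age")
    for (term in cand) {
      add <- .term_cols(term, param, config)
      if (!length(add)) next
      if (try_term(param, term, add)) terms[[param]] <- c(terms[[param]], term)
    }
    if (config$test_interactions && param != "rho") {
      # interactions among the retained candidate terms; the a priori
      # age/sex terms are not re-tested
      pool <- setdiff(terms[[param]], c("age", "sex"))
      if (length(pool) >= 2) {
        prs <- utils::combn(pool, 2, simplify = FALSE)
        for (pr in prs) {
          c1 <- if (pr[1] %in% names(config$candidates))
            .term_cols(pr[1], param, config)
          else .base_cols()[[param]][match(pr[1], c("age", "sex"))]
          c2 <- if (pr[2] %in% names(config$candidates))
            .term_cols(pr[2], param, config)
          else .base_cols()[[param]][match(pr[2], c("age", "sex"))]
          c1 <- c1[!is.na(c1)]; c2 <- c2[!is.na(c2)]
          if (!length(c1) || !length(c2)) next
          combos <- expand.grid(a = c1, b = c2, stringsAsFactors = FALSE)
          icols <- character(0)
          for (j in seq_len(nrow(combos))) {
            nm <- paste0(combos$a[j], ".x.", combos$b[j])
            if (!nm %in% names(enc))
              enc[[nm]] <- enc[[combos$a[j]]] * enc[[combos$b[j]]]
            icols <- c(icols, nm)
          }
          label <- paste(pr, collapse = ":")
          if (try_term(param, label, icols))
            terms[[param]] <- c(terms[[param]], label)
        }
      }
    }
  }
  list(terms = terms, cols = cols,
       tests = do.call(rbind, tests), fit = current_fit)
}

#' Bootstrap stability selection
#'
#' Repeats [select_once()] on `B` bootstrap resamples (with replacement,
#' size = cohort size) drawn from a seeded stream, counts how often every
#' term is retained in every parameter, and forms final per-parameter term
#' sets by the majority rule (count strictly greater than `threshold`),
#' always including the a priori terms. Deterministic given
#' `config$seed`.
#'
#' @inheritParams select_once
#' @return list of class `"crmix_selection"`: `counts` (data frame
#'   parameter/term/count/frequency), `final` (per-parameter term sets),
#'   `B`, `failures`.
#' @export
stability_selection <- function(data, config = selection_config(),
                                family = "loglogistic", delta = 1 / 365.25) {
  enc <- if (inherits(data, "crmix_cohort")) encode_cohort(data)
  else as.data.frame(data)
  n <- nrow(enc)
  idx <- .with_seed(config$seed, lapply(seq_len(config$B), function(i)
    sample.int(n, n, replace = TRUE)))
  counts <- list()
  failures <- 0L
  bump <- function(param, term) {
    key <- paste(param, term, sep = "\r")
    counts[[key]] <<- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  for (b in seq_len(config$B)) {
    res <- tryCatch(select_once(enc[idx[[b]], , drop = FALSE], config,
                                family, delta),
                    error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    for (param in names(res$terms))
      for (term in setdiff(res$terms[[param]], c("age", "sex")))
        bump(param, term)
  }
  keys <- names(counts)
  tab <- data.frame(
    parameter = vapply(strsplit(keys, "\r"), `[`, "", 1),
    term = vapply(strsplit(keys, "\r"), `[`, "", 2),
    count = unlist(counts, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(tab)) tab$frequency <- tab$count / config$B
  final <- list(alpha = "age", eta = c("age", "sex"),
                phi = character(0), gamma = character(0), rho = character(0))
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab)))
      if (tab$count[i] > config$threshold)
        final[[tab$parameter[i]]] <- c(final[[tab$parameter[i]]], tab$term[i])
  }
  structure(list(counts = tab, final = final, B = config$B,
                 threshold = config$threshold, failures = failures,
                 config = config),
            class = "crmix_selection")
}

#' @export
print.crmix_selection <- function(x, ...) {
  cat(sprintf("Bootstrap stability selection (B = %d, threshold > %g, %d failures)\n",
              x$B, x$threshold, x$failures))
  if (nrow(x$counts)) {
    ord <- order(x$counts$parameter, -x$counts$count)
    print(x$counts[ord, ], row.names = FALSE)
  }
  cat("final term sets:\n")
  for (p in names(x$final))
    cat("  ", p, ": ", paste(x$final[[p]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
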