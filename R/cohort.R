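# Canonical factor levels for every categorical field. Lowercase tokens are the
# on-disk representation; order fixes the reference level (first).
.cohort_levels <- list(
  sex              = c("male", "female"),
  education_gt12   = c("no", "yes"),
  cci_class        = c("0", "1", "2+"),
  histology        = c("adenocarcinoma", "squamous_cell_carcinoma"),
  chemoradiotherapy = c("no", "yes"),
  stage            = c("0-i", "ii", "iii", "iv"),
  margin           = c("r0", "r1r2"),
  reoperation_30d  = c("no", "yes")
)

.cohort_columns <- c("patient_id", "age", names(.cohort_levels), "time", "event")

#' Construct a validated patient cohort
#'
#' A cohort is a data frame with one row per patient: identifier, the nine
#' candidate predictors, follow-up time on the landmark scale (years since
#' surviving the first post-surgery year) and an event code
#' (0 = censored, 1 = death from esophageal cancer, 2 = death from another
#' cause). All fields are validated; offending rows are reported by number.
#'
#' @param data data frame holding the columns `patient_id`, `age`, `sex`,
#'   `education_gt12` (or numeric `education_years`, collapsed at >12 years),
#'   `cci_class` (Charlson comorbidity class `0`/`1`/`2+`), `histology`,
#'   `chemoradiotherapy`, `stage` (`0-i`/`ii`/`iii`/`iv`), `margin`
#'   (`r0`/`r1r2`), `reoperation_30d`, `time` and `event`.
#' @param provenance label recorded on the cohort (e.g. `"derivation"`,
#'   `"validation"`, `"synthetic"`).
#' @param age_bounds plausible adult age range; ages outside are rejected.
#' @param time_cap administrative follow-up cap in landmark years (4 landmark
#'   years = 5 post-surgery years); times above are rejected.
#' @return a data frame of class `"crmix_cohort"`.
#' @export
as_cohort <- function(data, provenance = "unspecified",
                      age_bounds = c(18, 100), time_cap = 4) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"education_gt12" %in% names(data) && "education_years" %in% names(data)) {
    ey <- suppressWarnings(as.numeric(data$education_years))
    data$education_gt12 <- ifelse(ey > 12, "yes", "no")
  }
  missing_cols <- setdiff(.cohort_columns, names(data))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ", paste(missing_cols, collapse = ", "))

  out <- data.frame(patient_id = as.character(data$patient_id),
                    age = suppressWarnings(as.numeric(data$age)),
                    stringsAsFactors = FALSE)
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, paste0(what, " (row ", paste(rows, collapse = ", "), ")"))
  }
  for (col in names(.cohort_levels)) {
    raw <- tolower(trimws(as.character(data[[col]])))
    lev <- .cohort_levels[[col]]
    bad <- which(!(raw %in% lev) | is.na(raw))
    if (length(bad))
      note(bad, paste0("invalid ", col, " value ",
                       paste(unique(raw[bad]), collapse = "/")))
    out[[col]] <- factor(raw, levels = lev)
  }
  out$time <- suppressWarnings(as.numeric(data$time))
  out$event <- suppressWarnings(as.integer(data$event))

  note(which(is.na(out$age) | out$age < age_bounds[1] | out$age > age_bounds[2]),
       sprintf("age outside [%g, %g]", age_bounds[1], age_bounds[2]))
  note(which(is.na(out$time) | out$time <= 0 | out$time > time_cap + 1e-9),
       sprintf("time outside (0, %g]", time_cap))
  note(which(is.na(out$event) | !(out$event %in% 0:2)), "event not in {0,1,2}")
  if (anyDuplicated(out$patient_id))
    problems <- c(problems, "duplicate patient_id values")
  if (length(problems))
    stop("cohort validation error: ", paste(problems, collapse = "; "))

  attr(out, "provenance") <- provenance
  attr(out, "time_cap") <- time_cap
  class(out) <- c("crmix_cohort", "data.frame")
  out
}

#' Read a patient cohort from a delimited text file
#'
#' The canonical format is a headered CSV, one row per patient, with
#' enumerations as lowercase tokens. The follow-up time column is
#' `time_years`; its origin is declared either by the `time_scale` argument or
#' by a `time_scale_hint` column (`"landmark"` or `"post_surgery"`). Times on
#' the post-surgery scale are shifted by -1 year on read so that the model's
#' time origin is always the 1-year landmark.
#'
#' @param path path to the CSV file.
#' @param time_scale `"landmark"`, `"post_surgery"`, or `NULL` to use the
#'   file's `time_scale_hint` column (defaulting to `"landmark"`).
#' @param provenance cohort label.
#' @inheritParams as_cohort
#' @return a `crmix_cohort`.
#' @export
read_cohort <- function(path, time_scale = NULL, provenance = "file",
                        age_bounds = c(18, 100), time_cap = 4) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (is.null(time_scale)) {
    time_scale <- if ("time_scale_hint" %in% names(raw))
      tolower(raw$time_scale_hint[1]) else "landmark"
  }
  time_scale <- match.arg(time_scale, c("landmark", "post_surgery"))
  if (!"time_years" %in% names(raw))
    stop("cohort schema error: missing column(s) time_years")
  raw$time <- suppressWarnings(as.numeric(raw$time_years))
  if (time_scale == "post_surgery") raw$time <- raw$time - 1
  as_cohort(raw, provenance = provenance, age_bounds = age_bounds,
            time_cap = time_cap)
}

#' Write a cohort to the canonical CSV format
#'
#' Times are written on the landmark scale with a `time_scale_hint` column, so
#' that `write_cohort()` followed by [read_cohort()] round-trips every field.
#'
#' @param cohort a `crmix_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "crmix_cohort"))
  out <- data.frame(patient_id = cohort$patient_id,
                    age = cohort$age,
                    sex = as.character(cohort$sex),
                    education_gt12 = as.character(cohort$education_gt12),
                    cci_class = as.character(cohort$cci_class),
                    histology = as.character(cohort$histology),
                    chemoradiotherapy = as.character(cohort$chemoradiotherapy),
                    stage = as.character(cohort$stage),
                    margin = as.character(cohort$margin),
                    reoperation_30d = as.character(cohort$reoperation_30d),
                    time_years = cohort$time,
                    time_scale_hint = "landmark",
                    event = cohort$event,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a cohort into the numeric covariates the model uses
#'
#' Produces the dummy/scaled columns from which per-parameter design matrices
#' are built: `age_s = (age - age_center)/age_scale`, `female`, `educ_gt12`,
#' `cci1`, `cci2` (Charlson 1 and 2+ vs 0), `scc` (squamous vs
#' adenocarcinoma), `chemo`, `stage2`, `stage3`, `stage4` (vs stage 0-I),
#' `r1r2` (vs R0) and `reop`, plus `time` and `event` when present.
#'
#' @param cohort a `crmix_cohort` or any data frame with the raw columns.
#' @param age_center,age_scale centering and scaling constants for age; the
#'   defaults are the derivation cohort's median age and a 10-year unit.
#' @return a plain data frame of numeric columns.
#' @export
encode_cohort <- function(cohort, age_center = 65.1, age_scale = 10) {
  d <- cohort
  enc <- data.frame(
    age_s  = (d$age - age_center) / age_scale,
    female = as.numeric(d$sex == "female"),
    educ_gt12 = as.numeric(d$education_gt12 == "yes"),
    cci1 = as.numeric(d$cci_class == "1"),
    cci2 = as.numeric(d$cci_class == "2+"),
    scc  = as.numeric(d$histology == "squamous_cell_carcinoma"),
    chemo = as.numeric(d$chemoradiotherapy == "yes"),
    stage2 = as.numeric(d$stage == "ii"),
    stage3 = as.numeric(d$stage == "iii"),
    stage4 = as.numeric(d$stage == "iv"),
    r1r2 = as.numeric(d$margin == "r1r2"),
    reop = as.numeric(d$reoperation_30d == "yes"))
  if (!is.null(d$time)) enc$time <- d$time
  if (!is.null(d$event)) enc$event <- d$event
  enc
}

#' Summarize a cohort's characteristics
#'
#' Counts and percentages for each categorical predictor, median and IQR of
#' age and follow-up, and 5-year (4 landmark-year) all-cause and
#' disease-specific death counts, in the style of a cohort characteristics
#' table.
#'
#' @param cohort a `crmix_cohort`.
#' @return a data frame with columns `characteristic`, `level`, `n`, `pct`
#'   (or `median`/`iqr` rows for continuous fields).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "crmix_cohort"), nrow(cohort) > 0)
  n <- nrow(cohort)
  rows <- list()
  add <- function(char, level, count, pct = NA_real_,
                  median = NA_real_, iqr = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = char, level = level, n = count, pct = pct,
      median = median, iqr = iqr, stringsAsFactors = FALSE)
  }
  add("total", "", n, 100)
  qa <- stats::quantile(cohort$age, c(.25, .5, .75), names = FALSE)
  add("age_years", "", NA_integer_, median = qa[2],
      iqr = sprintf("%.1f-%.1f", qa[1], qa[3]))
  for (col in names(.cohort_levels)) {
    tab <- table(cohort[[col]])
    for (lev in names(tab))
      add(col, lev, as.integer(tab[[lev]]), round(100 * tab[[lev]] / n, 1))
  }
  qf <- stats::quantile(cohort$time, c(.25, .5, .75), names = FALSE)
  add("followup_landmark_years", "", NA_integer_, median = qf[2],
      iqr = sprintf("%.1f-%.1f", qf[1], qf[3]))
  dead5 <- sum(cohort$event > 0)
  add("five_year_allcause_deaths", "", dead5, round(100 * dead5 / n, 1))
  deadc <- sum(cohort$event == 1)
  add("five_year_disease_specific_deaths", "", deadc, round(100 * deadc / n, 1))
  do.call(rbind, rows)
}

#' @export
summary.crmix_cohort <- function(object, ...) summarize_cohort(object)

#' @export
print.crmix_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d one-year survivors (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  cat(sprintf("  events: %d cancer deaths, %d other-cause deaths, %d censored\n",
              sum(x$event == 1), sum(x$event == 2), sum(x$event == 0)))
  invisible(x)
}
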