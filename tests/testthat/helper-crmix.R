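# Shared fixtures and independent oracles. Oracles re-derive quantities from
# first principles (manual encoding, per-record products, double loops) so
# they never share code paths with the implementation they check.

# small deterministic raw cohort
tiny_cohort_df <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p3"),
    age = c(65, 72.5, 58),
    sex = c("male", "female", "male"),
    education_gt12 = c("no", "yes", "no"),
    cci_class = c("0", "1", "2+"),
    histology = c("squamous_cell_carcinoma", "adenocarcinoma",
                  "squamous_cell_carcinoma"),
    chemoradiotherapy = c("no", "yes", "no"),
    stage = c("0-i", "ii", "iii"),
    margin = c("r0", "r0", "r1r2"),
    reoperation_30d = c("no", "no", "yes"),
    time = c(1.2, 0.5, 3.9),
    event = c(1L, 2L, 0L),
    stringsAsFactors = FALSE)
}

# published coefficients with the age transform centered at the example
# patient's age, so the age term drops out of the closed-form checks
params_center65 <- function() {
  p <- published_params()
  p$age_center <- 65
  p
}

# random valid raw cohort for property tests
random_raw_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("r%04d", seq_len(n)),
    age = runif(n, 40, 85),
    sex = sample(c("male", "female"), n, TRUE),
    education_gt12 = sample(c("no", "yes"), n, TRUE),
    cci_class = sample(c("0", "1", "2+"), n, TRUE),
    histology = sample(c("adenocarcinoma", "squamous_cell_carcinoma"), n, TRUE),
    chemoradiotherapy = sample(c("no", "yes"), n, TRUE),
    stage = sample(c("0-i", "ii", "iii", "iv"), n, TRUE),
    margin = sample(c("r0", "r1r2"), n, TRUE),
    reoperation_30d = sample(c("no", "yes"), n, TRUE),
    time = round(runif(n, 0.05, 4), 3),
    event = sample(0:2, n, TRUE),
    stringsAsFactors = FALSE)
}

# random monotone parameter set on the default formulas
random_params <- function(seed) {
  set.seed(seed)
  tpl <- published_params()
  cf <- tpl$coefficients
  cf$alpha[] <- rnorm(length(cf$alpha), 0, 0.5)
  cf$eta[] <- c(rnorm(1, 2, 0.3), rnorm(length(cf$eta) - 1, 0, 0.4))
  cf$phi[] <- -runif(1, 0.4, 1.2)
  cf$gamma[] <- rnorm(1, -1.5, 0.5)
  cf$rho[] <- -runif(1, 0, 0.5)
  crmix_params(alpha = cf$alpha, eta = cf$eta, phi = cf$phi,
               gamma = cf$gamma, rho = cf$rho, family = tpl$family,
               formulas = tpl$formulas, age_center = tpl$age_center,
               age_scale = tpl$age_scale)
}

# independent likelihood oracle: manual covariate encoding, per-record
# contributions multiplied into one product, logged at the end
oracle_loglik <- function(raw, params, delta) {
  a <- params$coefficients$alpha; e <- params$coefficients$eta
  ph <- unname(params$coefficients$phi[1]); g <- unname(params$coefficients$gamma[1])
  r <- unname(params$coefficients$rho[1])
  prod_contrib <- 1
  for (i in seq_len(nrow(raw))) {
    x <- raw[i, ]
    ages <- (x$age - params$age_center) / params$age_scale
    scc <- as.numeric(x$histology == "squamous_cell_carcinoma")
    xa <- c(1, ages, scc, as.numeric(x$chemoradiotherapy == "yes"),
            as.numeric(x$stage == "ii"), as.numeric(x$stage == "iii"),
            as.numeric(x$stage == "iv"), as.numeric(x$margin == "r1r2"))
    xe <- c(1, ages, as.numeric(x$sex == "female"),
            as.numeric(x$education_gt12 == "yes"), scc,
            as.numeric(x$stage == "iii"), as.numeric(x$stage == "iv"),
            as.numeric(x$margin == "r1r2"),
            as.numeric(x$reoperation_30d == "yes"))
    p1 <- 1 / (1 + exp(-sum(xa * a)))
    S <- function(t, d) {
      v <- sum(xe * e) + (d == 1) * g + log(t) * (ph + (d == 1) * r)
      1 / (1 + exp(-v))
    }
    contrib <- if (x$event == 0) {
      p1 * S(x$time, 1) + (1 - p1) * S(x$time, 2)
    } else {
      pd <- if (x$event == 1) p1 else 1 - p1
      pd * (S(x$time, x$event) - S(x$time + delta, x$event))
    }
    prod_contrib <- prod_contrib * contrib
  }
  log(prod_contrib)
}

# brute-force AUC: double loop over all case-control pairs
oracle_auc <- function(cases, controls) {
  s <- 0
  for (u in cases) for (w in controls)
    s <- s + (u > w) + 0.5 * (u == w)
  s / (length(cases) * length(controls))
}

# intercept-only generating parameters for covariate-free scenarios
intercept_only_params <- function(alpha0 = -0.5, eta0 = 2.3, phi0 = -0.76,
                                  gamma0 = -2.2, rho0 = -0.42) {
  fl <- crmix_formulas(alpha = ~1, eta = ~1)
  crmix_params(alpha = c("(Intercept)" = alpha0),
               eta = c("(Intercept)" = eta0),
               phi = c("(Intercept)" = phi0),
               gamma = c("(Intercept)" = gamma0),
               rho = c("(Intercept)" = rho0),
               family = "loglogistic", formulas = fl)
}
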