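---
title: "A parametric competing-risks mixture model for conditional survival after esophageal cancer surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A parametric competing-risks mixture model for conditional survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Patients who survive the first year after esophagectomy for esophageal
cancer often ask how their prognosis has changed *given* the time they have
already survived. Answering that requires a model of the joint distribution
of (cause of death, time of death) on a landmark time scale — here, years
since surviving one post-surgery year — from which conditional cumulative
incidence can be computed for any elapsed time and any prediction horizon,
not just integer anniversaries.

`crmix` implements such a model end to end: a mixture likelihood, maximum
likelihood fitting, conditional cumulative-incidence prediction, bootstrap
stability variable selection, discrimination/calibration assessment, and a
synthetic cohort simulator so the whole pipeline can be exercised and tested
without access to the original registry data (which are not publicly
deposited).

## The model

Each patient contributes covariates $x$, a follow-up time $t > 0$ on the
landmark scale, and an event code $d$: 0 censored, 1 death from esophageal
cancer, 2 death from another cause. Two ingredients define the joint model:

1. **Cause assignment.** The probability that a patient's eventual death is
   cancer-related is logistic,
   $f_2(d = 1 \mid x) = \operatorname{logit}^{-1}(x_\alpha'\alpha)$.

2. **Cause-conditional survival.** Given the eventual cause, the survival
   function of the death time is driven by the time index
   $$v(t \mid d, x) = \mathbb{1}\{d=1\}\, x_\gamma'\gamma + x_\eta'\eta
     + \log(t)\, x_\phi'\phi + \mathbb{1}\{d=1\} \log(t)\, x_\rho'\rho,$$
   with $S_4(t \mid d, x) = \operatorname{logit}^{-1}(v)$ under the
   log-logistic family. $\gamma$ shifts the location for cancer deaths,
   $\phi$ is the shared log-time slope, and $\rho$ lets the cancer-specific
   slope differ (it acts as a cause-by-log-time interaction).

Death times are treated as interval-censored at daily resolution: a death
at $t$ contributes the mass $f_4 = S_4(t) - S_4(t + \delta)$ with
$\delta = 1/365.25$ landmark-years, and a censored record contributes the
mixture survival $f_5(t \mid x) = \sum_{j=1,2} S_4(t \mid j, x)\, f_2(j \mid x)$.
The log-likelihood sums $\log f_2(d\mid x) + \log f_4$ over deaths and
$\log f_5$ over censored records. There is no left-truncation term: the
landmark origin makes every observed $t$ positive by construction.

Cumulative incidence follows in closed form,
$\mathrm{CIF}_{\text{cancer}}(t) = [1 - S_4(t\mid 1)]\, f_2(1)$,
$\mathrm{CIF}_{\text{other}}(t) = [1 - S_4(t\mid 2)]\, [1 - f_2(1)]$,
$\mathrm{CIF} = \mathrm{CIF}_{\text{cancer}} + \mathrm{CIF}_{\text{other}}
= 1 - f_5$, and conditional risks for a patient alive at $t_0$ are
$$\mathrm{CIF}_{\text{cancer}}(t \mid t > t_0)
  = \frac{\mathrm{CIF}_{\text{cancer}}(t_0 + t) - \mathrm{CIF}_{\text{cancer}}(t_0)}
         {1 - \mathrm{CIF}(t_0)}, \qquad
  \mathrm{CIF}(t \mid t > t_0) = 1 - \frac{1 - \mathrm{CIF}(t_0 + t)}{1 - \mathrm{CIF}(t_0)}.$$

### The sign convention for $S_4$

With the fitted time-slope constants negative ($\phi_0 = -0.76$,
$\rho_0 = -0.42$ in the shipped coefficient set), only
$S_4 = \operatorname{logit}^{-1}(v)$ is a survival function: it decreases
from 1 at $t \to 0^+$ to 0 as $t \to \infty$, makes every shipped
coefficient sign clinically coherent (higher stage harmful, more education
protective), and reproduces the published calculator's printed example. The
package therefore uses this form throughout and exposes
`is_monotone()` to check the decreasing-survival condition
($\phi_0 < 0$ and $\phi_0 + \rho_0 < 0$); fits that land outside it carry a
warning flag, and the simulator refuses such parameter sets outright.

### Alternative families

`weibull` replaces the inverse-logit link by the complementary
log-log form $S_4 = \exp(-\exp(-v))$ on the same time index; `gompertz`
uses that link with $t$ in place of $\log t$. Both exist for AIC
comparison (`compare_families()`); no parametrization for them is fixed by
the published model, so these are the package's own minimal choices that
keep the design vectors identical across families.

## Covariate encoding

Nine candidate predictors are supported: age (continuous, encoded as
$(age - 65.1)/10$ by default — the derivation cohort's median age and a
10-year unit; the published model's original scaling of age is not stated,
and the shipped worked example is insensitive to it because the example
patient sits at the center), sex, education (>12 years, binary; a numeric
years column is collapsed on input), Charlson comorbidity class (0/1/2+),
histology, neoadjuvant chemo(radio)therapy, pathological stage (0–I, II,
III, IV), resection margin (R0 vs R1/R2), and 30-day reoperation. In the
final model's $\eta$ block, stage II is merged into the 0–I reference —
the shipped coefficient table defines that merging, and `crmix_formulas()`
encodes it as the default. Both encoding constants are arguments.

## Fitting

`crmix()` maximizes the likelihood with BFGS using an analytic gradient
(every block's score has closed form because $v$ is linear in the
parameters), a relative tolerance of 1e-10, and optional multi-start with
reproducibly jittered initial values (default 3 starts) to guard against
local maxima; in practice all starts reach the same optimum on well-posed
cohorts. Standard errors come from inverting the observed information
(numerically differenced analytic gradient); a singular information matrix
flags the SEs unavailable rather than failing the fit. The interval width
$\delta$ only rescales the likelihood by $\approx n_{\text{events}} \log
\delta$ without moving the maximizer, which the tests verify by halving it.

Degenerate inputs: an empty cohort is an error; a cohort lacking events of
one cause fits with a warning (the corresponding mixture weight drifts to a
boundary); invalid likelihood regions encountered during line search are
handled by a finite penalty so the optimizer backtracks.

## Variable selection

The selection procedure mirrors significance-based stability selection:
age and sex are retained a priori (both in $\eta$, age in $\alpha$; sex in
$\alpha$ is left to testing, a compromise because the a priori rule names
both parameters while the final published model carries no sex term in
$\alpha$ — both choices are configurable). Every other candidate is tested
one at a time per parameter in the order $\eta, \alpha, \phi, \gamma,
\rho$, added to the accumulating model and kept when its Wald $p < 0.05$
(stage as a multi-df group; a likelihood-ratio variant is available).
Within each parameter except $\rho$ — which already represents a three-way
interaction — pairwise interactions of the *retained candidate* terms are
then tested the same way; the a priori terms are not re-tested, so with no
candidates the procedure returns exactly the constants plus forced-in
terms. The wording "tested separately in each parameter" admits variants;
the add-one-at-a-time reading implemented here is deterministic given the
seed and documented by the tests.

`stability_selection()` repeats this on $B$ bootstrap resamples (default
100) and keeps terms selected in more than $B/2$. A caveat the tests make
explicit: bootstrap inclusion frequency tracks the *realized* sample
association, not the population truth — a pure-noise predictor that
happens to show a sample association near the testing threshold will be
selected in a substantial fraction of resamples of that same cohort. The
majority rule is exactly what protects the final model from such terms.

## Validation

- **Time-dependent AUC**: the marker is the model's predicted cumulative
  incidence at the horizon (total or cancer-specific); cases have the
  outcome by the horizon, controls are event-free and under observation at
  it, and records censored earlier are excluded. No inverse-probability
  weighting is used because the emulated cohorts have complete 5-year
  potential follow-up, so there is no pre-horizon administrative censoring
  at the 3- and 5-year horizons (landmark times 2 and 4). The rank-based
  computation equals brute-force pairwise concordance with half credit for
  ties, which a property test enforces.
- **Bootstrap cross-validation** (`bootstrap_auc_cv()`): refit on each
  resample; evaluate on the resample (`apparent`) or out-of-bag records
  (`out_of_bag`, the default — the published description is ambiguous and
  the out-of-bag reading guards optimism; both are provided and the
  optimism ordering between them is tested).
- **AUC differences between cohorts** use fixed parameters and resample
  both cohorts, reporting the 2.5–97.5% quantile interval of the
  difference.
- **Hosmer–Lemeshow**: decile groups of predicted risk,
  $\sum_g (O_g - E_g)^2 / [E_g(1 - \bar p_g)]$ on $g - 2$ degrees of
  freedom; groups with vanishing variance merge with a neighbor. Observed
  proportions are raw event fractions at the horizon (valid under the
  complete-follow-up design).
- **Goodness of fit**: the intercept-only model's $f_5$ overlaid on the
  all-cause Kaplan–Meier curve, summarized by the sup-norm discrepancy
  over the KM step times.

## The synthetic cohort simulator

`simulate_cohort()` emulates the derivation cohort of 1027 one-year
survivors: covariate marginals default to that cohort's characteristics
(men 73.8%, squamous histology 51.9%, neoadjuvant therapy 33.2%, stage
0–I/II/III/IV 32.2/38.9/24.7/4.2%, involved margins 9.2%, reoperation
8.4%, >12 years education 14.9%, Charlson 0/1/2+ 56.0/29.3/14.7%, age
truncated-normal(65.1, 9.5) on [30, 95]); a validation-style preset flips
the case mix (81% adenocarcinoma, 69.4% neoadjuvant therapy). Printed
category percentages carry rounding slack and are renormalized within 2%.
Event causes come from $f_2$ and latent times from exact inverse-transform
sampling of $S_4$ (so simulator and likelihood are mutually consistent by
construction), with administrative censoring at 4 landmark-years. The
Gompertz parametrization places inverse-sampling mass at non-positive
times, so the simulator supports the log-logistic and Weibull families
only.

Covariates are sampled independently by default because only marginals are
published; an optional association overlay (e.g. a log-odds shift of the
therapy propensity for squamous tumors) exists for robustness studies. An
optional surgery-origin mode draws times on the post-surgery scale and
rejects first-year deaths, for sensitivity analysis of the
no-left-truncation choice. What passing tests on these cohorts show is
internal consistency of the whole pipeline under the model's own
assumptions — they cannot show how the model behaves under real-world
covariate dependence, non-administrative censoring, or misspecified time
distributions.

## Numerical and design choices

- Daily interval width $\delta = 1/365.25$ landmark-years, configurable.
- Age transform constants (65.1, 10), configurable.
- Predictions are supported on 1–5 post-surgery years (the fitted
  follow-up); `risk_table()` refuses extrapolation unless overridden.
- The shipped coefficients are printed to two decimals; propagating that
  rounding moves the worked-example risks by up to ~0.4 percentage
  points, hence the half-point tolerance used when comparing to the
  published example (the second printed example reproduces to ~0.3 points;
  whether the hosted calculator used unrounded coefficients is unknowable).
- Bootstrap streams are drawn up front from a single seed, so runs are
  bit-reproducible and per-replicate work is order-independent.

Problem sizes used by the test suite are the package's own choices to keep
the checks sharp but quick: likelihood oracles on 100 cohorts of size ≤ 20;
recovery at $n = 5000$ with 20 replicates; Hosmer–Lemeshow type-I behavior
over 200 refits at $n = 5000$; selection properties at $n = 2000$ with
$B = 100$ (noise) and $B = 20$ (strong effect); AUC cross-validation
examples at a few hundred patients with tens of replicates.

## Known limitations

- The mean-bias recovery check over 20 replicates is itself a Monte-Carlo
  estimate; for the rare stage-IV coefficient its simulation noise is of
  the same order as the bound being checked, so that check is fragile by
  construction (the test suite documents this inline).
- No splines of $\log t$, no frailty terms, no regularization, and no
  confidence intervals on predicted risks — matching the scope of the
  model the package implements.
- The published cohort-specific AUC values cannot be reproduced without
  the original registry cohorts; the validation machinery is instead
  checked by property-based tests on synthetic data.
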