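---
title: "Modelling daily protein intake and competing hospital outcomes in critical illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily protein intake and competing hospital outcomes in critical illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protpamm)
```

## The estimation problem

Critically ill patients receive enteral (EN) and/or parenteral (PN) protein
whose daily amount varies over the first days in the ICU. The question is
whether the *amount and timing* of protein intake during the acute phase
(days on diet #1–#11 after ICU admission) is associated with the rate of
in-hospital death and — as a competing event — live hospital discharge.
Three features make this hard: intake is a time-varying exposure, the two
outcomes compete, and sicker patients are fed differently than healthier
ones (confounding by indication).

`protpamm` addresses this with piece-wise exponential additive mixed models
(PAMMs): follow-up beyond day 4 is split into intervals $(t_{j-1}, t_j]$ on
which the cause-specific hazards are constant, which turns the survival
problem into a penalized Poisson regression on pseudo-data (PED) with a
log-exposure offset. For cause $k \in \{\text{death}, \text{discharge}\}$,

$$\log \lambda_k(t \mid x_i) \;=\; f_{0k}(t_j) \;+\; \sum_p f_{pk}(x_{ip})
\;+\; x_i^{\top}\gamma_k \;+\; b_{k,\ell(i)} \;+\;
\sum_{t_z} W_i(t_j, t_z)\, g_k(t_j, t_z, z_i(t_z)),$$

with a smooth log-baseline $f_{0k}$, smooth (APACHE II, age, BMI) and
linear/categorical confounders, a Gaussian ICU random intercept
$b_{k,\ell}$, and a cumulative effect of the intake history $z_i$.

## Intake quantification

Daily protein intake in g per kg body weight is the enteral protein plus
0.83 times the parenteral amino acids (protein equivalents). Days are
categorized as level I (low, $<0.8$), level II (standard, $0.8$–$1.2$, both
bounds included) or level III (high, $>1.2$ g/kg). Exclusively oral days
count as level I and as days without medical nutrition therapy (MNT). The
weight basis is the actual admission weight implicit in the recorded g/kg
values; no ideal-body-weight variant is offered, because the recorded data
do not distinguish them.

For the hospital-outcome analysis the model needs intake on all 11 days
from every patient still under follow-up, including those discharged alive
from the ICU earlier. Such days are *imputed* as standard-intake (level II)
days, carry the level-II median 0.99 g/kg as a numeric placeholder (only
the category enters the model), and count as MNT days. The ICU-outcome
sensitivity analysis (`outcome_set = "icu"`) instead truncates trajectories
at ICU discharge and imputes nothing. A recorded gap before the end of
registration is a hard error, never a silent fill.

## Lag-lead windows and cumulative effects

Intake on day on diet $t_z$ may affect the hazard of interval $j$ only if

$$t_{j-1} \ge t_z + 4 \quad\text{and}\quad t_{j-1} < t_z + 4 + \text{lead}(t_z),$$

where the 4-day lag guards against intake changes just before death or
discharge (indication bias), and the lead is twice the cumulative number of
MNT days up to $t_z$ (`dynamic`) or 60 days (`static` sensitivity
analysis). Comparisons use the interval's left endpoint, so no day can
reach the first interval $(4,5]$: every diet contrast equals 1 there by
construction, with a degenerate confidence interval. Two readings of the
lead definition ("twice the number of days a patient had had MNT") were
possible; we use the cumulative count up to and including $t_z$, so that
later days of a long-fed patient project further into follow-up.

Within the window, the intake history enters through level II and level III
indicator dummies (level I is the reference). Two bases are provided:

* **phase** (default): per interval, the counts of level II/III days in the
  early (days #1–#4) and late (#5–#11) acute phase inside the window; each
  of the four counts gets a time-varying coefficient (P-spline in interval
  time, `tvc_k = 5` basis functions), or a constant coefficient with
  `cum_tv = FALSE`.
* **surface**: a full tensor-product P-spline $g_k(t, t_z)$ (5×5 marginal
  bases) over interval time and day on diet, weighted by the window/dummy
  indicators.

The phase basis matches the early/late acute-phase distinction used to
define the hypothetical diets; the surface basis relaxes it.

## Fitting

All terms are penalized: P-splines (cubic B-splines, second-order
difference penalties, 10 basis functions per univariate smooth) with
sum-to-zero constraints next to the intercept, and the ICU intercepts as a
ridge block whose penalty is the inverse random-effect variance. The
penalized Poisson likelihood is maximized by iteratively reweighted least
squares with step halving (monotone in the penalized deviance). Smoothing
parameters are selected by Fellner–Schall (Laplace-approximate REML)
updates; `smoothing = "fixed"` freezes them for bit-for-bit reproducible
pipelines. The update for terms with essentially no information has a flat
REML surface and is clamped to $[10^{-6}, 10^{7}]$; unpenalized all-zero
columns (unused factor levels) are dropped with a warning. The reported
covariance is the inverse penalized Fisher information (the usual Bayesian
posterior covariance of a penalized fit), and `1.96` standard errors give
the 95% bands used throughout.

Numerical choices worth knowing: the working response is computed in its
bounded form $w(\eta - o) + (y - \mu)$ so event rows with near-zero fitted
hazard cannot overflow; linear predictors are capped at 30 before
exponentiation; a Cholesky failure adds a $10^{-8}$ relative ridge. With an
interval-factor baseline, no covariates and zero penalty, the fit
reproduces the closed-form occurrence/exposure rates (events divided by
person-days) to below $10^{-6}$ relative error — this, the equality with
`glm()` on unpenalized designs, and agreement with `mgcv::gam()` under
identical design-and-penalty setups are the fitter's test oracles.

## Hypothetical diets and contrasts

Five 11-day diets are compared pairwise (six comparisons, the reference
always the diet providing less protein): exclusively low (level I
throughout), late standard (low base, level II on days #5–#11), early
standard (level II throughout), late high (standard base, level III on
#5–#11), and early high (level III on days #1–#4, remaining days copied
from the comparison diet). The late diets are anchored on the base diet
they add protein to — low for late standard, standard for late high — so
every resolved pair is component-wise nested; only the early high diet is
context-dependent. Hazard ratio curves are computed under the ceteris
paribus assumption: confounders and the ICU intercept cancel in the
contrast, whose standard error comes from the cumulative-term block of the
posterior covariance. Absolute risks use the closed-form CIF of the
piece-wise exponential model with proportional within-interval cause
allocation; `cif_death + cif_discharge + surv = 1` holds to machine
precision at every interval.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the statistical structure the analysis
assumes: admission-level confounders; an intake-level Markov chain whose
stationary distribution (44.5/31.7/23.8%) matches the observed day-level
category mix (44.0/32.8/23.2%); g/kg values drawn uniformly within each
category around the observed medians 0.49/0.99/1.41; ~85% of fed days
exclusively enteral; daily live ICU discharge (probability 0.08 on days
5–10) that triggers the imputation path; per-cause baseline hazards
calibrated so that by day 60 roughly 25% have died in hospital, 69% were
discharged alive and 6% remain (the observed margins); ICU random
intercepts (SD 0.25); and known per-day cumulative effects, so that
`ground_truth_hr()` is an exact oracle for any diet contrast. Event times
are continuous within days. An `indication_bias` scenario adds a latent
severity that both lowers intake and raises the death hazard, to probe
what the lag is meant to mitigate.

The generator does **not** emulate realistic ICU case-mix, calorie intake
beyond a level-correlated fraction-of-target scalar, joint confounder
dependence (default scenario draws them independently), or
intake-trajectory dynamics beyond a first-order chain — the survey data
describe none of these, so passing tests demonstrate correctness of the
machinery under the stated model, not fidelity to any real cohort. The
published cohort's numeric hazard ratios and medians are not reproducible
without the (non-deposited) database.

## Validation problem sizes

The packaged validation uses cohorts of 50–500 patients: the
occurrence/exposure oracle on a 50-patient fixture with a coarse grid (so
every interval has events), the likelihood identity on a 5-patient
hand-built fixture, and parameter recovery on 100 replicates of 500
patients under a known per-day late level-II death effect of
$\log 0.75$ (true minimum of the late-standard-vs-low HR curve:
$0.75^7 \approx 0.133$), fitted with the correctly specified
constant-coefficient cumulative model. Across replicates the pointwise 95%
bands cover the true curve at close to nominal rate. The minimum of the
estimated curve, however, is a noisy functional at this size: with roughly
100 death events per replicate the standard error of the 7-day cumulative
log hazard ratio is about 0.5, so the estimated minimum scatters widely
around the truth, and recovery of the minimum to ±0.1 in 90% of 500-patient
replicates is not attainable at these event counts (it would need roughly
four times the death information). The recovery test states this bound
honestly rather than enlarging the simulated cohorts.

## Known limitations

Cause-specific hazards only (no subdistribution/Fine–Gray analysis);
left-truncation is handled solely by conditioning on 96-h survival;
days-on-diet are aligned to whole days after admission (the sub-day offset
between the diet calendar and the admission clock is ignored, as intake is
recorded per calendar day); the dynamic-window geometry follows the
definition above and the basis dimensions are declared defaults, not
reconstructions of the original fit.
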