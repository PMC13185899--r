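---
title: "Estimating phase-dependent nutrient requirements with a regularized tanh neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating phase-dependent nutrient requirements with a regularized tanh neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasereq)
```

## The data model and its assumptions

`phasereq` works on flock-week records: one observation per flock per
week of hen age, with daily nutrient intakes (ME in kcal/bird/day;
digestible lysine, methionine and threonine in g/bird/day) and the
composite reproductive output, chicks produced per hen per week. When
records arrive as dietary composition instead of intakes,
`compute_intakes()` recalculates them as
`dAA = feed [g/d] × conc [g/100 g]/100 × digestibility` and
`ME = feed [g/d]/1000 × ME concentration [kcal/kg]`.

Records are stratified into the three industry production phases —
early (26–32 weeks), mid/peak (33–50) and late (51–62) — and each
phase is analyzed separately. This treats the phase boundaries as
fixed; requirements are population-level associations within a phase,
not causal or per-flock effects (no flock random effects are fitted).

Screening is deliberately mechanical so it is reproducible: hard
physiological bounds per variable (config-exposed defaults, e.g. ME
intake 200–600 kcal/d) reject records with machine-readable reasons,
and an optional per-phase Tukey fence (quartiles ± 1.5 × IQR,
type-7 quartiles throughout) flags — by default does not reject —
statistical outliers. Missing values are flagged
(`"missing:<column>"`) and fitting simply uses complete cases of the
(intake, response) pair; no imputation is attempted.

## The dose–response model

Within a phase, the mean response is a single tanh neuron,

$$\mathrm{Response} = A\,\tanh(c\,\mathrm{Nutrient} + b) + B ,$$

a monotone saturating curve (for $A, c > 0$) whose asymptote
$\mathrm{Response}_\infty = A + B$ is the predicted ceiling under
unlimited supply. Because $(A,b,c,B)$ and $(-A,-b,-c,B)$ describe the
same curve, fits are canonicalized to $A > 0$.

The requirement at fraction $p$ (default $0.95$) of the asymptote has
the closed form

$$\mathrm{Req}_p \;=\; \frac{\operatorname{artanh}\!\big((p(A+B) - B)/A\big) - b}{c},$$

which at $p = 0.95$ reduces to
$(\operatorname{artanh}(0.95 - 0.05\,B/A) - b)/c$. We read "95 % of the
asymptotic response" on the total response scale, $0.95 (A+B)$, because
only that reading reproduces the reduced form algebraically. The
estimate is *valid* only when the canonical curve is increasing
($c > 0$) and the target lies strictly inside the response range
($|(p(A+B)-B)/A| < 1$); otherwise `requirement_at_fraction()` returns
`valid = FALSE` with a reason rather than a number. An independent
bisection solver, `requirement_oracle()`, checks the closed form to
1e-8 in the test suite and is exported for verification. Alternative
fractions (0.90, 0.97, ...) are supported via `p`; they shift the
absolute requirement but not the phase pattern.

## Fitting: scaling, Levenberg–Marquardt, Bayesian regularization

tanh fitting is badly conditioned in original units (ME intakes are
~450, gains ~0.1), so both axes are min–max scaled to $[-1, 1]$ before
optimization and the fitted parameters are back-transformed analytically
afterwards; the two parameterizations agree to 1e-9 by test. The scaled
objective is penalized least squares,

$$F = \beta E_D + \alpha E_W, \qquad
E_D = \tfrac12\sum r_i^2,\quad
E_W = \tfrac12 (A_s^2 + b_s^2 + c_s^2 + B_s^2),$$

minimized by damped least squares (Levenberg–Marquardt on the
$\sqrt{\beta}, \sqrt{\alpha}$-weighted augmented residual vector, with
analytic Jacobian). After each inner solve the hyperparameters are
re-estimated by the evidence approximation with a Gauss–Newton Hessian
$H = \beta J^\top J + \alpha I$:

$$\gamma = 4 - \alpha\,\mathrm{tr}(H^{-1}),\qquad
\alpha = \frac{\gamma}{2E_W},\qquad
\beta = \frac{n-\gamma}{2E_D},$$

iterating until both the objective (relative change < `tol`, default
1e-9) and the hyperparameters (relative change < 1e-6) are stable, or
`max_iter` (300) outer iterations. $\gamma \in [0,4]$ is the effective
number of parameters; on clean, informative data it approaches 4 and
the penalty becomes negligible ($\alpha/\beta \to 0$), which the tests
assert on noiseless data.

Numerical choices worth knowing:

* **Initialization.** $\alpha$ starts at 0.01 (not 0) so $H$ stays
  invertible when a direction is unidentified — e.g. a constant
  response, where the amplitude then shrinks toward zero and the
  requirement is flagged invalid downstream. $\beta$ starts at 1 and is
  capped at 1e12 so noiseless data (where $E_D \to 0$) cannot overflow.
* **Multi-start.** tanh fits have local minima and the sign symmetry,
  so 10 restarts are drawn uniformly from $[-1,1]^4$ in scaled space
  under a seeded generator; the best final objective wins, ties broken
  by RMSE. Bootstrap refits instead warm-start at the full-data
  estimate plus one random restart, the standard resampling shortcut.
* **Determinism.** Every stochastic step (restarts, simulation,
  resampling) derives sub-seeds from a single master seed, so any
  result is a pure function of (data, config, seed).

RMSE is reported as $\sqrt{SSE/n}$ — not $SSE/(n-p)$ — for *both* the
tanh fit and the polynomial benchmarks, so cross-model comparisons are
well defined; with this convention a quadratic can never have higher
RMSE than the nested linear fit.

## Benchmarks, uncertainty, and phase comparison

Linear and quadratic OLS fits (`fit_polynomial()`,
`compare_linear_quadratic()`) report Pearson $r$, RMSE, and per-term
t-test p-values; "quadratic improves" means the squared-term p-value is
below 0.05. Confidence bands are pointwise t-bands for the *mean*
response (not prediction bands; the choice is documented because the
alternative is defensible too).

Requirement uncertainty uses the nonparametric bootstrap: records are
case-resampled with replacement (not residual-resampled — these are
observational field data), the neuron is refitted, and $\mathrm{Req}_p$
recomputed, 100 replicates by default. Replicates that fail to converge
or give an invalid requirement are dropped and counted with their
sub-seeds logged; a run fails if more than half are unusable, and a CI
is only reported from 20 valid replicates upward. CI endpoints are the
canonical percentile-bootstrap order statistics (the $(R+1)p$ rule,
type-6 quantiles, as in `boot::boot.ci`); boxplot quartiles elsewhere
remain type 7. BCa intervals and multiplicity corrections are left as
extension points; pairwise phase tests are reported raw.

Phases are compared by pairing replicate $i$ of one phase with
replicate $i$ of the other (the phases use disjoint records, so any
pairing is valid; index pairing keeps the test deterministic) and
computing the two-sided resampling p-value
$2\min(P(d\le 0), P(d\ge 0))$ with the $(k+1)/(R+1)$ correction, which
floors the p-value at $2/(R+1)$ — with 100 replicates, at about 0.02.
Letters come from the standard insert-and-absorb compact letter
display, assigned in descending order of point estimate. Notched
boxplots summarize the replicate distributions with the classic notch
$\mathrm{median} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$ and a seeded
1,000-replicate percentile bootstrap CI for the mean.

## What the synthetic generator does and does not emulate

The field dataset behind the published analysis (2,685 flock-weeks from
commercial Ross 308 flocks) is not deposited, so validation runs on
synthetic data built to the same statistical skeleton:
`generate`d intakes are uniform over a configured range, the mean
response follows a true tanh curve, and noise is additive, homoscedastic
Gaussian. The twelve presets in `scenario_presets()` pin down what the
study reports — phase sample sizes 515/1,471/699; noise SDs equal to
the printed model RMSEs (ME 0.41/0.12/0.20; dMet — and, per the study's
"nearly identical" remark, dLys — 0.41/0.20/0.21; dThr
0.408/0.212/0.206 chicks/hen/week); true requirements at the printed
point estimates (e.g. dLys 0.95/1.03/0.89 g/d).

Everything else about the curves is *assumed*, chosen once as
plausible for this production system and not revisited: response
asymptotes 4.2/5.6/4.4 chicks/hen/week for early/mid/late; a lower
plateau of 1.5/2.0/1.5 (flocks at low intake still produce some
chicks; plateaus sit > 3.5 noise SDs above zero so the additive
Gaussian model essentially never produces negative counts); curve
midpoints 15 kcal/d (ME) or 0.10 g/d (amino acids) below the true
requirement; intake ranges from 45 kcal/d (0.28 g/d) below to
20 kcal/d (0.06 g/d) above it, so the design covers the full bend of
the S-curve.

Passing the validation suite therefore shows the *method* recovers
requirements under the study's sample sizes and noise — it does not
certify behavior under features of real field data the generator omits:
non-uniform intake designs concentrated near recommended feeding
levels, heteroscedastic or autocorrelated noise, flock-level clustering,
covariate drift over years, or curve shapes far from tanh. Real-data
confidence intervals should be expected wider than the synthetic ones,
because commercial intake designs span much less of the curve.

## Problem sizes used in validation

The test and acceptance runs use the preset sample sizes throughout:
noiseless recovery on all twelve presets (tolerance 1e-4 relative);
stochastic recovery at the ME mid preset over 50 seeds (median
relative error ≤ 2 %); bootstrap coverage at the dLys mid preset over
100 simulated datasets with 50 replicates each (a deliberate
scale-down from the default 100, using the warm-started refits); and a
full four-nutrient pipeline with 100 replicates per phase for the
reported tables. These sizes make the whole suite run in a few minutes
on one CPU while keeping the Monte Carlo error of the checks small
relative to their tolerances.

## Known limitations

* One nutrient at a time: no interactions (amino-acid ratios,
  energy-protein balance) and no covariates.
* The response integrates egg production, fertility and hatchability;
  nutrient effects on the components are not separable here.
* Phase cutoffs are fixed categories of a continuous process.
* The evidence framework assumes the Gauss–Newton Hessian is an
  adequate curvature approximation near the optimum; pathological fits
  fall back on multi-start and are reported as non-converged rather
  than silently accepted.
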