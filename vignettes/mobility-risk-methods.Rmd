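---
title: "Methods: GPS mobility features and short-term STB risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS mobility features and short-term STB risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsrisk)
```

This vignette is the package's own account of its science: the model it
fits, the conventions it adopts where study reports are silent, the
numerical machinery, what the synthetic cohort does and does not emulate,
and the known limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. From raw fixes to daily features

A GPS stream is a sequence of timestamped (lat, lon) fixes per
participant. Three per-day summaries are computed:

* **Dwell.** Each fix carries the time to the next fix, capped at 30
  minutes (`gap_cap_min`), so that unobserved gaps — phone off, sensor
  suppressed — do not credit the last known location with hours of
  presence. The final fix of each local day dwells to midnight, same cap.
* **Location clusters.** Fixes are clustered greedily in time order: a
  fix joins the nearest existing cluster whose dwell-weighted centroid
  lies within 200 m, else opens a new cluster. The procedure is
  deterministic, O(n·K), and matches the 200 m convention used for
  homestay. Published pipelines rarely state their clustering algorithm;
  greedy sequential clustering was chosen for determinism and because the
  downstream features only need dwell totals per place, not optimal
  partitions. The radius is configurable.
* **Home.** The cluster with the largest summed dwell inside the
  02:00–06:00 local window over the whole study period. Ties break by
  larger all-day dwell, then earlier first visit. A participant with no
  night-window fixes has no identifiable home and is dropped from
  homestay analyses, as cohort studies drop participants without usable
  geolocation.
* **Homestay** (hours): dwell summed over fixes within 200 m of the home
  coordinate. **Entropy** (nats): Shannon entropy −Σ pᵢ ln pᵢ of the
  day's dwell fractions across clusters; natural log is used — study
  reports rarely state a base, and since downstream terms are z-scored, a
  base change is absorbed by the scaling. **Distance** (km): summed
  haversine length (Earth radius 6371.0088 km) over consecutive same-day
  fixes.

Two distance filters guard against artifacts: segments implying speeds
above 300 km/h are treated as GPS teleports and skipped, and segments
shorter than 150 m are treated as stationary jitter and skipped. The
jitter filter matters: at a 10-minute cadence with 25 m fix noise, raw
consecutive-fix distances accumulate several spurious km/day (the mean
distance between two jittered stationary fixes is ≈ σ√π ≈ 44 m at
σ = 25 m); with the filter, simulated noisy tracks recover their
generating path length to within 5%. Both filters are configurable and
off in the micro-oracle tests that check exact arithmetic.

Day boundaries are local midnight. Weeks start Wednesday 00:00 local:
the weekly surveys go out on Wednesdays, and midnight alignment keeps the
2–6 am home rule inside a single day bin.

## 2. Weekly panel and the within/between decomposition

Weekly feature values are arithmetic means of available daily values over
Wednesday–Tuesday bins; weeks with fewer than 3 GPS days are marked
missing (the row is retained for bookkeeping). Each feature is then split
into:

* a **within-person term**: the deviation from the participant's own mean,
  divided by the pooled SD of all such deviations in the sample; and
* a **between-person term**: the participant mean, z-scored across
  participants' means.

The z-scoring denominators are a convention choice (reports say only
"person-mean-centered and z-scored"): pooled-sample denominators keep one
unit — "1 SD of weekly change" — comparable across participants, which is
what an odds ratio per 1 SD should mean. Participants with fewer than two
feature-bearing weeks have no estimable within term and are flagged.

Outcomes: a **suicidal event** week has ≥ 1 merged event dated inside it.
Emergency-department visits and hospitalizations within 7 days *after* an
attempt by the same participant are merged into that attempt (keeping the
attempt's date); attempts never merge with each other, and merging is
idempotent. **Clinically meaningful ideation** is a responded weekly
survey with ideation frequency ≥ 4 (1–5 scale) or an endorsed plan;
unanswered weeks are missing outcomes and contribute no ideation rows (no
imputation). A survey delivered on a Wednesday reports on the week just
ended, so survey date `d` maps to the week containing `d − 1`.

The lag-L panel pairs the outcome at week T with within-person terms from
week T − L (between terms are constant within participant);
`weeks_since_baseline` = T enters as a covariate. By construction no row
references feature data from the outcome week or later when L ≥ 1; a
property test asserts this on simulated panels. The reversed-direction
builder pairs the event indicator at T − 1 with a feature term at T as a
Gaussian outcome, fitted by ordinary least squares, for the bidirectional
check.

## 3. The random-intercept logistic model

The analysis model is

$$\mathrm{logit}\, P(y_{it}=1) = \mathbf{x}_{it}^\top \beta + u_i,
\qquad u_i \sim N(0, \sigma_u^2),$$

with the marginal likelihood obtained by integrating each participant's
Bernoulli likelihood over $u_i$. The package implements this likelihood
directly rather than delegating to a mixed-model package, so that it can
be oracle-tested against brute-force integration; the established
implementation (`lme4::glmer`, 25-node AGQ) serves as an independent
cross-check in the test suite, agreeing to ~1e-5 in coefficients on
fixture panels.

Numerics:

* **Adaptive Gauss–Hermite quadrature**, 25 nodes by default. Each
  group's integral is re-centered at the posterior mode of $u_i$ (found
  by a safeguarded Newton iteration) and scaled by the curvature there;
  the quadrature sum is accumulated in log space. 25 vs 51 nodes moves
  coefficients by < 1e-6 on fixture panels; nodes/weights come from the
  Golub–Welsch eigen-decomposition and are verified against an
  independent implementation.
* **Parameterization** $(\beta, \ln \sigma_u)$ for unconstrained
  optimization. If $\hat\sigma_u$ collapses below 1e-4 the model
  degenerates to plain logistic regression, which is handled by an
  analytic branch (and reproduces `glm` coefficients to 1e-6).
* **Optimization**: BFGS from a deterministic start (plain-logistic
  $\beta$, $\sigma_u = 0.5$), then Newton polish using the analytic score
  — the gradient of the exact marginal log-likelihood is the posterior
  expectation of the complete-data score, evaluated with the same
  quadrature nodes — and a Hessian from central differences of that
  score. The convergence flag requires gradient norm < 1e-6 and final
  step < 1e-8; in practice the polish reaches gradient norms near 1e-12.
* **Inference**: the coefficient covariance is the fixed-effect block of
  the inverse observed information at the optimum; CIs are Wald,
  $\exp(\beta \pm z_{0.975}\,\mathrm{SE})$ — the convention that
  reproduces symmetric published log-odds intervals. P-values are
  two-sided Wald.
* **Separation fallback**: if any |β| exceeds 15 on z-scored columns
  (quasi-separation, common with rare events at short lags), the model is
  refitted with a ridge penalty (strength 4) on non-intercept
  coefficients, started from the origin, and flagged `penalized`. A
  deterministic penalized refit was chosen over a Bayesian refit so the
  fallback is dependency-free and reproducible; it is clearly marked in
  all output.

## 4. Predictive validation

**Leave-future-out.** Each participant's panel weeks are split at the
midpoint of their own observed span (spans differ, so a per-participant
midpoint rather than a calendar date; the training half is "the first
half of follow-up" for everyone). One model per feature card — all-geo,
homestay-only, baseline-only (SSI, site, sex, age, device), homestay +
baseline, all-geo + baseline — is fitted on pooled training halves with
the random intercept; held-out weeks are scored with **fixed effects
only**, so a participant's own event history cannot leak into their risk
score. AUC is the Mann–Whitney statistic with midrank ties (identical to
trapezoidal ROC integration; constant scores give exactly 0.5), with a
percentile bootstrap CI over resampled test rows (2000 resamples by
default, unstratified, seeded). Test halves with no positive rows are
reported as undefined rather than fabricated.

**Between-person.** Features averaged over the first 28 days (requiring
≥ 12 observed days — a floor added so one good afternoon cannot stand in
for a month) predict whether a participant has any event (or any
ideation week) afterwards, using ordinary logistic regression on one row
per participant over repeated 70/30 train/test splits. Splits with no
positive test participant are redrawn and counted. The reported AUC is
the mean over repetitions (the summary statistic was unstated in the
motivating design; the mean is used and the 2.5/97.5 percentiles over
repetitions give the uncertainty band). Repetition r uses the r-th
pre-drawn sub-seed of the master seed, so rep 1 is identical whether 1 or
10 000 repetitions are requested.

A subtlety the test suite documents: repeated splits of a *single*
label-permuted dataset do not average to AUC 0.5 — a finite dataset
retains its chance feature–label association across splits — so the
permutation null is evaluated over fresh permutations.

## 5. The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
with known ground truth:

* ~186 participants × ~26 weeks (defaults), enrolled on a common
  Wednesday;
* daily homestay fraction following a logit-scale AR(1) process
  (ρ = 0.4) around a participant-specific level; remaining time
  distributed over ≥ 1 anchor locations (≥ 2 × 200 m from home, pairwise
  ≥ 500 m) in contiguous blocks, so daily distance has a meaningful true
  track length; fixes every 10 minutes with 15 m isotropic jitter
  (25 m in the noisy-track oracle); the 02:00–06:00 window is at home on
  95% of days, keeping the night-window home rule identifiable;
* whole days of GPS missing completely at random with probability 0.25
  (emulating ~75% day-level availability); weekly survey response with
  probability 0.41;
* weekly events from the generative inverse of the analysis model:
  Bernoulli with log-odds `event_intercept + Σ β·x(T−1) + u_i`, where the
  design terms are built by the same decomposition the analysis uses,
  the default within-person homestay effect is ln 2 per SD, other
  feature effects are 0, σ_u = 0.6, and `event_intercept = −4.7` puts the
  marginal weekly rate near 1%. Configurations implying a marginal rate
  above 20% are refused as outside the rare-event regime. Event dates are
  uniform within their generating week (timeline-dated events carry
  day-level noise anyway), with companion ED/hospitalization records
  0–7 days after ~35% of attempts so the merging rule is exercised.
  Ideation weeks are generated from an intercept (−2.75, ≈ 6% of
  responded weeks) plus the same random intercept;
* baseline covariates (SSI, site, sex, age, device) are drawn with
  realistic margins but are *null* predictors by default — the generator
  makes no claim that demographics predict events.

What it does **not** emulate: multiple homes or moves; indoor/outdoor or
transport-mode structure; informative missingness (a hook exists in the
design but the default is MCAR, consistent with reports that acuity was
unrelated to missingness); seasonal or school-calendar rhythms; the
clinical safety workflow. Passing tests on this cohort therefore show
the *pipeline arithmetic and estimator calibration* are right, not that
real adolescent mobility follows an AR(1) or that real effect sizes equal
the simulated ones.

## 6. Problem sizes and test design

The simulation suites run at sizes chosen to balance Monte-Carlo
resolution against desk-scale runtimes:

* parameter recovery: 200 replicates at 186 × 25 weeks, event intercept
  −4.2 (marginal rate ≈ 1.5%, inside the ~1–2% band; the higher of the
  plausible rates was fixed a priori to keep rare-event small-sample bias
  well under the Monte-Carlo tolerance). Checks: mean $\hat\beta$ within
  2 MC SEs of ln 2; 95% Wald coverage in [0.92, 0.975];
* type-I error: 400 replicates with the homestay effect set to 0;
  rejection rate of the within-homestay Wald test required in [3%, 7%];
* leave-future-out power and null coverage: 50 + 50 scaled replicates at
  120 × 16 weeks, ~4% event rate, 500-fold bootstrap;
* feature oracles: enumerated micro-fixtures and small GPS cohorts with
  zero jitter/missingness where daily homestay must equal the generative
  fraction within one fix interval and home inference must land within
  200 m of every true home.

## 7. Known limitations

* Homestay is computed from per-fix distance to the home coordinate, not
  from cluster membership; near the 200 m boundary the two differ for
  jittered fixes.
* The within/between decomposition uses each participant's *sample* mean;
  with few weeks this under-dispersion slightly attenuates within-person
  contrasts (negligible at ≥ 20 weeks, visible below ~6).
* $\hat\sigma_u$ is biased toward 0 in rare-event panels of this size
  (≈ 0.45–0.55 recovered for a true 0.6); fixed-effect inference is
  calibrated regardless, as the coverage suite shows.
* Wald CIs can be optimistic for coefficients near separation; the ridge
  fallback bounds the damage but its CIs are conditional on the penalty.
* Bootstrap resampling of test rows is unstratified by participant;
  rows from the same participant are positively correlated, so CIs may
  be mildly narrow. A stratified option is a natural extension.
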