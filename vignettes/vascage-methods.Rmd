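---
title: "Methods: vascular age estimation, panel expansion, and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular age estimation, panel expansion, and survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Chronological age (CA) is the strongest single predictor of cardiovascular
disease, but two people of the same CA can carry very different vascular
systems. `vascage` estimates a *biological vascular age* (BA) from three
non-invasive measurements — brachial-ankle pulse wave velocity (baPWV, a
stiffness measure), the ankle-brachial index (ABI, an obstruction and
calcification marker), and mean arterial pressure (MAP) — and summarizes
the discrepancy as the normalized cardiovascular age acceleration

$$\eta = \frac{CA - BA}{CA}.$$

Negative $\eta$ means the vasculature looks older than the calendar; the
normalization by CA puts a 5-year excess at age 40 and at age 70 on
different footings, reflecting that the same absolute excess is a stronger
signal earlier in life.

## The estimator

Within a healthy training split, stratified by sex:

1. Skewed markers (TG, FBG, HbA1c, ESR, NLR) are natural-log transformed.
   The base is immaterial — it is absorbed by the z-score — and natural log
   is the package's fixed choice.
2. All markers are z-scored; the means and SDs are **frozen** and reused
   verbatim on every other split, so scores are comparable across splits.
3. The z-scored markers are rotated by PCA (eigendecomposition of their
   covariance, which equals the correlation on this scale). All components
   are retained; each eigenvector's sign is fixed so its largest-magnitude
   loading is positive, making fits reproducible. BA is invariant to this
   convention (negating an eigenvector negates $t_j$, $k_j$, $q_j$
   jointly and cancels).
4. For each component score $t_j$, OLS on CA yields slope $k_j$,
   intercept $q_j$, and residual standard error $s_j$ ($n-2$ denominator).
5. The Klemera-Doubal combination
   $$BA = \frac{\sum_j (t_j - q_j)\,k_j/s_j^2}{\sum_j (k_j/s_j)^2}$$
   is algebraically the precision-weighted mean of the per-component
   inverse predictions $(t_j - q_j)/k_j$ with weights $k_j^2/s_j^2$. With
   one component it reduces to the inverse regression $(t-q)/k$. The
   anchored Klemera-Doubal variant with a CA term is deliberately not the
   default; the plain combination above is what this pipeline estimates.

**Numerical guards.** The combination divides by $k$-derived weights, so a
component with essentially no age trend would contribute an exploding
inverse prediction with a vanishing weight — numerically hazardous.
Components with $|k_j| < 10^{-6}$ (standardized-PC units per year) are
dropped with a warning; $s_j = 0$ (an exactly linear score, which occurs
in the noise-free limit) is floored at $10^{-8}$ and flagged in the
parameters. A duplicated marker column is rejected outright at the PCA
step; merely collinear inputs (e.g. the noise-free limit, where every
marker is an exact linear function of CA) are tolerated — their degenerate
components carry no age slope and die at the slope floor, and BA still
reproduces CA exactly, which the test suite asserts to $10^{-8}$.

## Preprocessing

MAP is derived as $DBP + (SBP - DBP)/3$ (the printed formula read with the
standard clinical bracketing). Records lacking age, outside 20–70 years,
carrying an exclusion diagnosis flag, or missing more than half the marker
panel are excluded with a logged reason. Remaining missing cells are
completed by chained random-forest imputation (30 sweeps, 10 trees per
fit, run separately per sex, with age, the other markers, and the
chronic-disease flags as predictors). Observed cells are never altered and
the procedure is fully seeded. Imputation happens on the natural/log
scale *before* standardization; the source analysis does not state its
ordering, and this one is declared rather than inferred. A single
completed dataset is produced (the "30 iterations" are chained sweeps,
not multiple imputations), matching how the downstream pipeline consumes
one table.

## Panel expansion

Candidates (BMI, TC, HDL-C, LDL-C, TG, FBG, HbA1c, ESR, NLR, heartbeat)
are screened on the chronic-disease-healthy split: within each age group
(< 50, ≥ 50 years), markers are tested across $\eta$ tertiles, and a
candidate passes only if $p < 0.05$ in **both** groups (intersection
rule). The screen's test defaults to Jonckheere-Terpstra, a monotone-trend
test that matches the "related to η" intent; the ANOVA/Kruskal-Wallis
difference test is available as a configuration switch, and both are
always stored.

Expansion is greedy: each remaining candidate is added to the current
marker set, the entire pipeline is refitted on the training split, $\eta$
is scored on the CVD-healthy case-control split, and the age-adjusted
logistic OR per SD of $-\eta$ is computed. The best candidate is accepted
iff its *point* OR strictly exceeds the incumbent's; ties to four decimals
resolve to the earlier candidate in the supplied order. A 100-replicate
participant bootstrap is recorded at every trial, but selection uses the
point OR — the reproducible choice when the source is silent on whether
the bootstrap mean or the point estimate drove selection; both are kept in
the trace so either reading can be inspected. Fitting errors (e.g. a
constant candidate column) are recorded in the trace and the candidate is
skipped.

A consequence of the strict-improvement rule worth knowing: when a tried
candidate is *exactly* uninformative, the refitted point OR differs from
the incumbent's by estimation noise alone, so acceptance is close to a
coin flip per candidate, and trying many null candidates at once inflates
acceptance (a best-of-$k$ effect). The test suite quantifies this with a
single-candidate null set; users screening large panels should rely on
the intersection screen to keep the candidate set short.

## Survival validation

On the follow-up cohort (CVD-free at baseline), the battery computes:

* **Cox models** (Efron ties): continuous exposure $-\eta$, so the HR is
  "per 1 decrease" of $\eta$ and values above 1 mean faster aging is
  riskier; and tertile exposure with Q1 (highest $\eta$) as reference.
  Both crude and age-adjusted. Tertiles are cut at the empirical 1/3 and
  2/3 quantiles with the half-open convention (ties at a cut join the
  higher-$\eta$ group).
* **Log-rank** across tertiles, and 1 − Kaplan-Meier cumulative-incidence
  curves truncated at the 10-year horizon.
* **Restricted cubic splines** (5 knots at the 0.05/0.275/0.50/0.725/0.95
  quantiles, truncated-power natural-spline basis, linear beyond the
  boundary knots). Nonlinearity is the joint Wald test on the nonlinear
  basis coefficients. The **age cutoff** is the smallest age on a
  half-year grid from which the spline-predicted log-HR (referenced to
  the cohort median age) stays positive with its pointwise Wald lower
  95% bound above zero. Because the reference is the median, the rule
  localizes change points near mid-distribution sharply (within about a
  year in simulations) and finds change points far above the reference
  with a conservative bias of a few years; the rule is this package's
  declared operationalization of a "turning point", not a claim about
  the source analysis's unstated rule.
* **Trend tests**: one-way ANOVA or Kruskal-Wallis (chosen by a per-group
  Shapiro-Wilk screen at $\alpha = 0.05$; both always stored) plus
  Jonckheere-Terpstra. JT uses an exact null distribution for $n \le 30$
  without ties — computed via the Mann-Whitney convolution decomposition,
  which equals full permutation enumeration — and a tie-corrected,
  continuity-corrected normal approximation otherwise.
* **Agreement**: Pearson $r$ of BA vs CA and the through-origin slope
  $\sum BA \cdot CA / \sum CA^2$ as a proportional-agreement measure.
* **Subgroup HRs** across user-supplied factor thresholds, with empty or
  event-free strata reported as non-estimable rather than failing.

No multiple-testing correction is applied anywhere; raw p-values are
reported, and this is a deliberate mirror of the analysis style the
package implements.

## The synthetic-cohort generator

Real examination data of this kind are not publicly deposited, so the
package ships a generator that encodes the statistical structure the
analysis assumes, making every stage testable:

* ages uniform on 20–70, per sex;
* a latent per-individual vascular-aging acceleration $a_i \sim
  N(0, \sigma_a^2)$ **in years**, so that "true acceleration" has the
  same units as $BA - CA$ and recovery tests are interpretable;
* each marker follows a sex-specific linear trend in *effective* vascular
  age $CA + c_m a_i$ with Gaussian residuals, exponentiated for the five
  skewed markers; by default only the vascular markers (baPWV, ABI, SBP,
  DBP) load on $a_i$ ($c_m = 1$);
* incident CVD over a 10-year administrative-censoring window from a
  proportional-hazards model with constant baseline hazard
  ($\lambda_0 e^{\beta_{age} CA + \beta_a a_i}$; exponential by default
  for closed-form oracles, Weibull shape exposed as an option);
* prevalent CVD at baseline from a logistic model in CA and $a_i$ (needed
  for the case-control split; this is generator plumbing, not a claim
  about the source data);
* chronic-disease flags from threshold rules (ABI < 0.9, ABI ≥ 1.4,
  BMI ≥ 28, SBP ≥ 140, DBP ≥ 90, FBG ≥ 7.0) with optional label noise;
* missing-completely-at-random marker cells — the simplest mechanism
  sufficient to test the imputation contract.

**Default magnitudes.** Trend defaults put marker means and spreads in
physiologic ranges (baPWV ≈ 1400 cm/s, SBP ≈ 127 mmHg, ABI ≈ 1.11 at age
45). Residual SDs were fixed by an a-priori precision argument: the
age-equivalent noise of a marker is $sd/|slope|$ (≈ 8 y for baPWV at
100/12, ≈ 12.5 y for MAP, ≈ 20 y for ABI), and the inverse-variance
combination across the three vascular markers gives a combined noise of
roughly 6.5 years. Against a latent acceleration SD of 5 years this
predicts $\mathrm{corr}(-\eta, a_i) \approx 0.55$–0.6, so the
acceleration-recovery property is identified but not trivially so. These
values were fixed before the test suite was run and not revisited.

**What the generator does not emulate:** longitudinal repeat visits,
informative missingness, measurement error correlated across markers
beyond the shared $a_i$, non-proportional hazards, competing risks, and
secular or cohort effects. Passing tests therefore demonstrate that the
pipeline's machinery is correct and well-calibrated under its own
assumptions — not that those assumptions hold in any particular clinical
population.

## Problem sizes and determinism

The shipped tests use cohorts of 300–3000 participants, 200 replicates
for Cox coverage, 2000 for log-rank size, 500 for spline-calibration, and
50 for expansion null behavior — sizes at which the Monte-Carlo bounds in
the assertions are meaningful while the whole suite stays fast. Every
stochastic stage (generation, imputation, bootstrap) takes an explicit
seed, and the end-to-end pipeline is byte-identical across reruns with
the same seeds, which the suite asserts on serialized model and report
JSON.

## Known limitations

* Single imputation, not multiple imputation with pooling.
* The expansion search is strictly greedy-forward on one case-control
  split; no cross-validation, no penalization, no exhaustive subsets.
* The age-cutoff rule is sensitive to where the change point sits
  relative to the cohort median (see above).
* $\eta$ is undefined at $CA = 0$ and unstable at very low CA; the
  pipeline's inclusion window (20–70 years) keeps it well-behaved.
* No competing-risks or time-varying-covariate support.
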