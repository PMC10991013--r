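---
title: "Methods: psychometric evaluation of a passive spatial-navigation assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometric evaluation of a passive spatial-navigation assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vienna)
```

## The assessment and its scoring model

VIENNA is a passive desktop virtual-reality assessment of spatial
navigation for middle-aged and older adults. Each of 12 main trials shows a
first-person video of a character exploring a virtual hallway while an
allocentric (top-down) map of the same environment stays on screen; the
participant indicates the door at which the video ended. Solving a trial
requires translating between the egocentric view and the allocentric map,
spatial updating (extrapolating the traveled path), and perspective
rotation (re-orienting after the character turns). Trial complexity rises
over four turn types: no turn, single turn, double turn, and a full
180-degree turn.

The scoring rubric is a three-class partition of each trial's doors:

* the **correct door** scores 2 points;
* doors **parallel or adjacent** to the correct one score 1 point and are
  typed as **spatial updating errors**;
* the door **opposite** the correct one scores 1 point, typed as a
  **perspective rotation error**;
* any other door scores 0 (`"other"`).

`item_config()` encodes one trial's geometry (door count, correct door,
one-point door sets), `score_response()` applies the rubric, and
`score_participant()` / `score_cohort()` aggregate to the 0-24 total score
and the two auxiliary error counts. A missing response to a configured main
item is scored 0 with error type `"other"` and a warning; the published
administration reported no premature terminations, so no refusal code
exists. Practice trials carry `is_main = FALSE` and never enter totals.

## Item difficulty relative to chance

Because items differ in door counts and one-point sets, raw item means are
not comparable. The chance expectation of an item with $d$ doors, of which
$u + r$ score one point, is

$$E = \frac{2 + u + r}{d},$$

the mean score of a uniformly guessing participant
(`expected_item_score()`, exact arithmetic). Item difficulty is then the
ratio $\bar{M}/E$ of the empirical mean to this expectation
(`difficulty_ratio()`): higher values mean the cohort outperforms guessing
by a larger factor, i.e. easier items. `item_type_difficulty()` averages
the ratio within turn types; on the published cohort this yields the
gradient 6.25 (no turn), 6.01 (single), 4.48 (double), 2.38 (full turn).

Two rounding conventions matter when reproducing published tables. All
package functions keep full precision and round only in report writers
(half-up, two decimals). The published ratios, however, were computed from
means that had already been rounded for the report, and the type averages
from those two-decimal ratios; the acceptance script applies the same
report-time chain when rebuilding the published values.

## Wilson's e as corrected item-total correlation

Item scores are ordinal (0/1/2) with massive ties, so Pearson correlations
with the total score are inappropriate. Wilson's $e$ classifies all
$n(n-1)/2$ observation pairs as concordant ($C$), discordant ($D$), tied on
$x$ only ($T_x$), tied on $y$ only ($T_y$), or tied on both, and is

$$e = \frac{C - D}{C + D + T_x + T_y},$$

excluding only doubly-tied pairs from the denominator. With no ties it
reduces to Kendall's $\tau_a$; an $O(n^2)$ pair-count oracle guards the
contingency-table implementation in the test suite. The *corrected*
item-total correlation (`corrected_item_total()`) correlates each item with
the total minus that item (rest score), so an item is never correlated with
itself. A zero-variance item yields $e = 0$: every pair is tied on the
item, leaving $C = D = 0$ while the $T_x$ pairs keep the denominator
positive — matching the published convention of printing 0.00 for the item
solved by all participants.

## Polychoric ordinal alpha

Internal consistency on ordinal items uses the polychoric correlation
matrix: each pair of items is modeled as a discretized bivariate standard
normal. Estimation is two-step (`polychoric_corr()`): thresholds are fixed
at the normal quantiles of the cumulative margins (`latent_thresholds()`),
then the latent correlation maximizes the multinomial log-likelihood over
$[-0.999, 0.999]$. Two-step estimation is the standard choice at cohort
sizes near 80 — faster than joint maximum likelihood and practically
indistinguishable. Numerical notes:

* bivariate-normal rectangle probabilities use 64-node Gauss–Legendre
  quadrature of $\int \varphi(x)\,\Phi\!\big((k-\rho x)/\sqrt{1-\rho^2}\big)dx$
  (absolute accuracy about $10^{-10}$);
* empty interior cells get no continuity correction; cell probabilities are
  floored at $10^{-12}$ inside the log-likelihood;
* a perfectly monotone table belongs at the bound, so the boundary
  likelihood is compared explicitly against the interior optimum;
* pairwise estimation can break positive semi-definiteness at small $n$;
  negative eigenvalues are clipped at $10^{-8}$ and the matrix rescaled to
  unit diagonal, with a message.

`ordinal_alpha()` applies the Cronbach form
$\alpha = \frac{k}{k-1}\left(1 - \frac{k}{S}\right)$ ($S$ the matrix sum),
equal to $k\bar{r}/(1+(k-1)\bar{r})$ for compound symmetry.
`alpha_pipeline()` always excludes zero-variance items (their thresholds
are undefined) and optionally items at or below a variance threshold
(default 0.05 in `run_pipeline()`, mirroring the published low-variance
variant). The confidence interval is a percentile bootstrap over
participants (default 1000 resamples, seeded): the publication does not
state its CI construction, so a simple, assumption-light choice was made;
published CI endpoints depend on the raw data and are not reproduction
targets.

## Distribution diagnostics and outlier rules

`shape_statistics()` reports the adjusted Fisher–Pearson (sample-size
corrected) skewness $G_1$ and excess kurtosis $G_2$ with their exact
normal-theory standard errors

$$SE(G_1) = \sqrt{\tfrac{6n(n-1)}{(n-2)(n+1)(n+3)}}, \qquad
  SE(G_2) = \sqrt{\tfrac{24n(n-1)^2}{(n-3)(n-2)(n+3)(n+5)}};$$

this estimator pair reproduces the published $z$ pairs at $n = 79$. A
variable counts as normal when both $|z|$ values are strictly below 3.29,
the conventional threshold for medium samples (`normality_flag()`); the
flag selects Pearson vs Spearman coefficients downstream.

Two outlier rules coexist, as both appear in the evaluation workflow.
`sd_rule_outliers()` flags values beyond $\pm 2.5$ SD — appropriate for the
approximately normal total score. For skewed battery scores,
`adjusted_boxplot()` uses medcouple-adjusted fences: with $MC \ge 0$,
$[Q_1 - 1.5e^{-4MC}\mathrm{IQR},\; Q_3 + 1.5e^{3MC}\mathrm{IQR}]$, and the
mirrored exponents for $MC < 0$, reducing exactly to Tukey's rule at
$MC = 0$. The medcouple (`medcouple()`) is the median of
$h(x_i, x_j) = \frac{(x_j - m) - (m - x_i)}{x_j - x_i}$ over pairs of
distinct observations with $x_i \le m \le x_j$; pairs of observations both
equal to the median use the signed $-1/0/+1$ kernel indexed by their
position among the ties. The self-pair of a unique median observation is
excluded — some implementations include it, which changes tiny samples
(e.g. it turns the medcouple of 1, 2, 3, 4, 100 from 0.48 into 0); the
conventions coincide as $n$ grows. Quartiles use linear interpolation
(`quantile` type 7), one of several conventions the fence literature leaves
open. The MAD is reported unscaled by default (no 1.4826 factor), matching
the published descriptive table where MAD can exceed SD on discrete scores;
`mad_constant` makes it configurable.

## Associations, composites, and multiple testing

`association_battery()` runs the correlation battery of the total score
against demographic, questionnaire and cognitive variables: coefficient
type per the joint 3.29 rule, partial correlations controlling for age, and
partial correlations controlling for an average-performance composite.
`average_performance_composite()` z-standardizes each remaining test,
aligns directions via a sign map (so higher always means better), and
averages non-missing components per participant, excluding the navigation
score and the test under evaluation. Missing values are never imputed —
they are systematic refusals, not random gaps — so every analysis is
pairwise-complete and reports its own $n$. Benjamini–Hochberg correction is
applied per correlation column by default; whether the publication pooled
all tests into one family is not stated, so the family definition is an
argument (`family = "pooled"`). Group comparisons use the pooled-variance
$t$ test gated by Levene's check on deviations from group means, and
`ttest_from_summary()` reproduces published comparisons from printed
summaries alone. `clogg_z()` compares two standardized coefficients by
$Z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$.

## Regression and predictor reduction

`forced_entry_ols()` enters all predictors simultaneously; predictors are
z-standardized by default so coefficients are per-SD (the published
coefficient scale), with the outcome left raw. `reduce_by_p()` implements
the two-stage reduction: retain predictors with $p < .10$, refit; if the
liberal rule would drop nothing, tighten to $p < .05$; stop when the
nested-model ANOVA (`nested_anova()`,
$F = \frac{\Delta SSR/\Delta df}{SSE_{full}/df_{full}}$) shows a
significant loss (the predecessor is returned) or when all retained
predictors are significant. The verbal description of this rule in the
source publication is self-contradictory (it says predictors with $p$
*below* .1 were excluded, yet its reduced model *kept* exactly those); the
implementation follows the construction actually used. `aic_backward()`
cross-checks via AIC-based backward selection.

One property deserves honesty: *exact* active-set recovery of such
$\alpha$-threshold procedures is capped. Each truly null predictor ends
with $p < .05$ — and is therefore retained — with probability near .05, so
with five nulls the exact-recovery rate is bounded near
$(1-.05)^5 \approx 0.77$ (empirically ~0.83 at $n = 200$ with strong
effects), no matter how strong the true effects are. Recall of true
predictors, by contrast, is essentially perfect in that regime. The test
suite asserts the attainable properties; a stricter 90% exact-recovery
assertion is retained in the acceptance suite and documents this ceiling
by failing.

## The synthetic cohort generator

Raw participant data are not published, so every stage is exercised on
synthetic cohorts (`simulate_cohort()`) whose generative model mirrors the
study conditions:

* **ages** uniform on 50–85 years (the published range; published mean 67.8
  is close to the uniform midpoint);
* **latent navigation ability** $\theta = \beta_{age} z(age) +
  \sqrt{1-\beta_{age}^2}\,\varepsilon$, standard normal marginally, with
  $\beta_{age} = -0.55$ (the published age correlation of the total score
  is about $-.54$; item-level noise attenuates the realized correlation to
  about $-.44$);
* **door choices** via a logistic item response model
  $P(\text{correct}) = \text{logit}^{-1}(a(\theta - b_j))$ with shared
  discrimination $a = 1.2$ and item difficulties $b_j$ whose type means are
  constrained non-decreasing over no/single/double/full turns (per-item
  monotonicity would contradict the published pattern, where one
  single-turn item was solved by everyone and one double-turn item was the
  hardest overall);
* **error routing**: an error lands on a one-point door with item-specific
  probability $w_j$ (defaults informed by the published one-point vs
  zero-point frequencies), split between rotation and updating doors by
  weights $0.7\,e^{\kappa\cdot\text{rot}}$ vs $0.3\,e^{\kappa\cdot\text{upd}}$,
  where the two deficit traits each correlate $-0.4$ with $\theta$ — the
  generative analogue of rotation errors tracking perspective-taking and
  updating errors tracking spatial working memory;
* **covariates**: each battery variable loads on $\theta$ and on
  standardized age with unit total variance
  (`default_covariate_spec()`), with missingness rates mirroring the
  systematic refusals (3/79, 4/79, 1/79 for the depression scale, mental
  rotation, and perspective-taking tests).

Door geometries are unpublished; `default_item_bank()` is a synthetic
stand-in whose chance expectations match the published per-item $E$ values
at two decimals and in which every item has at least one updating and one
rotation door. The difficulty vector of `default_vienna_profile()` was
calibrated once so that, across many seeds at $n = 79$, the mean total is
about 19.7 (published 19.43), the within-cohort SD about 2.9 (published
2.61), updating errors are right-skewed with median 0–1 and fewer than a
quarter of participants above one (published: 10 of 79), and no cohort
shows floor effects; it was then frozen. Draws use fixed sub-seeds per
block (ages/traits, item responses, covariates, missingness), so extending
the covariate battery never perturbs the item draws, and stored scores
always regenerate exactly from stored door choices via the scoring module.

What passing on synthetic cohorts does **not** show: the generator is
unidimensional by construction (plus two routing traits), has logistic
rather than probit response curves, uniform rather than empirical age
distribution, and independent noise across covariates beyond their shared
loadings. Real data could violate any of these — most relevantly through a
multi-factor item structure, which the publication itself suspects but
defers.

## Problem sizes and runtime choices

Simulation-based tests use cohort sizes and replicate counts chosen to make
sampling noise negligible relative to the asserted tolerance: polychoric
recovery at $n = 5000$ (tolerance 0.05), threshold convergence at
$n = 20000$, elimination properties over 40–100 replicates at $n = 200$,
calibration over 200–500 cohorts of $n = 79$, and difficulty-ordering
recovery over 50 cohorts of $n = 500$ with difficulty spacing 0.4 (adjacent
item means then differ by several standard errors, making full-order
recovery the expected outcome). Bootstrap CIs default to 1000 resamples in
`alpha_pipeline()`; pipeline-level reports use 200 by default, which is
ample for two-decimal reporting.

## Reproducing the published quantities

`scripts/acceptance.R` rebuilds, from the shipped printed-frequency table
and printed summaries alone, every published quantity that is derivable
from them (item means, variances, difficulty ratios and their type
averages, the total-score mean, the pilot $t$ test, the shape-$z$ values),
and computes the simulation-based surfaces under a caller-supplied seed.
Quantities that require raw participant data — the published correlation
and regression coefficient tables, and the published alpha CIs — are
deliberately out of reproduction scope.
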