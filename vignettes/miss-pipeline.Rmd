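---
title: "Scoring midwifery integration and linking it to perinatal outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring midwifery integration and linking it to perinatal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missr)
library(dplyr)
```

## The instrument

US jurisdictions regulate midwives very differently: the three credentials
(CNM, CM, CPM) face different licensure, scope-of-practice, prescriptive
and reimbursement rules in each state, and these rules shape whether
midwives are integrated into the maternity-care system across hospital,
home and birth-center settings. The Midwifery Integration Scoring System
(MISS) condenses a jurisdiction's regulatory environment into a single
weighted composite: 50 items across seven domains (scope of practice,
autonomy, governance, referral & medications access, patient safety,
quality, access across birth settings), each with ordered response options
carrying point values, scaled so that the optimal response on every item
sums to 100. Higher totals mean fuller integration.

Two readings of a printed instrument are supported. A rubric file may
carry pre-computed point values per option (as transcribed instruments
do), in which case the validator enforces only the structural invariants
and the sum-to-optimum constraint, with a transcription tolerance of 0.5
points; or it may carry only importance weights (0 = not important ... 4 =
essential) and within-item favourability ranks, in which case
`derive_points()` constructs the points by the proportional convention

$$\mathrm{points}_{ik} = c\, w_i\, r_{ik}, \qquad
  c = \frac{T}{\sum_i w_i \max_k r_{ik}},$$

which is the simplest rule that (a) is monotone in both the item weight
and the option rank, (b) is scale-invariant in the ranks, and (c) hits the
target optimum $T$ exactly. The construction is a package convention: the
published description states that item scores are weighted and summed but
not the algebraic form, so the form is fixed here explicitly and
documented as such.

The packaged `canonical_rubric()` is a labelled synthetic stand-in: the
full published instrument has no public accession, so six sample
indicators whose option values are public are transcribed verbatim, and
44 placeholder items preserve the instrument's structure (50 items,
optimum exactly 100, seven domains, 2--5 ordered options per item). Every
structural claim the package tests holds for this stand-in exactly as it
would for the real instrument; no substantive claim about any real
jurisdiction can or should be read off it.

```{r rubric}
rubric <- canonical_rubric()
rubric
score_profiles(optimal_profile(rubric), rubric)$total
```

## Scoring, ranking, quartiles

`score_profiles()` sums the selected options' points per jurisdiction and
partitions the same sum across domains. Strict mode refuses unanswered
items; the `impute_lowest` alternative scores an unanswered item at its
minimum-point option, the conservative reading that an unverifiable
condition is maximally restrictive.

Ranking is competition ranking on descending totals (ties share the
minimum rank of the block; display order within a tie is alphabetical).
Quartile categories follow the convention of four equal percentile bands:
a value's percentile is $100 \cdot (\#\,\text{strictly below})/n$ and the
bands are $[0,25)$, $[25,50)$, $[50,75)$, $[75,100]$, labelled very low,
low, moderate, high. On $n$ distinct values with $n$ divisible by 4 the
four categories are exactly equal-sized; the estimator is deliberately the
simplest one with that property, since the published convention names the
bands but not the percentile estimator.

## Workforce density and access

Density is midwives per 1000 births, computed separately for the two
credential groups reported on US birth certificates (CNMs/CMs; CPMs and
other direct-entry midwives). Access is the proportion of all births
attended by each group in each of three settings, with two aggregates:
all midwife-attended births, and midwife-led community births (home plus
freestanding birth center). Percent change in community-birth rates
between two periods is relative change of the rate itself.

## The inference stack

State-level outcome distributions are typically skewed, while composite
scores tend to be approximately normal; `normality_check()` (Shapiro-Wilk)
documents that gate, and association is then measured by Spearman's rho:
the Pearson correlation of mid-rank (tie-averaged) ranks. Two-tailed
p-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, with
$\rho = \pm 1$ mapped to $p = 0$; for $n \le 10$ an exact enumeration
p-value is available. The implementation is verified in the test suite
against a definition-level oracle (ranks by exhaustive sorting, covariance
by explicit sums) on all 720 permutations of six distinct values and on
randomly tied vectors, and cross-checked against `cor(method =
"spearman")`. Correlations use pairwise-complete observations and report
the n per cell; significance is flagged at the two-tailed 0.05 and 0.01
levels with no multiple-testing correction, mirroring the reporting
convention of state-level ecological tables in this literature.

The hierarchical (block-entry) regression asks how much outcome variance
integration explains beyond racial composition: the percent of
non-Hispanic Black births enters in block 1 and the raw MISS total in
block 2, and the increment is tested with

$$F_{\mathrm{change}} =
  \frac{\Delta R^2 / q}{(1 - R^2_{\mathrm{full}})/(n - p - 1)}
  \sim F(q,\, n - p - 1)$$

under the null of no block-2 effect. The underlying least-squares solver
is QR-based with a hard rank check (rank deficiency is an error, never a
silent pseudo-inverse), with one deliberate exception: if block 2 exactly
duplicates information already in block 1, the fit reports
$\Delta R^2 = 0$, $F = 0$ rather than failing, since "no additional
variance" is the correct answer there. The MISS score enters untransformed
(a `standardize` option re-scales both predictors for coefficient
comparability without changing the variance partition), regressions are
unweighted by default with a case-weights option, and deletion is
listwise within each outcome model. Residual diagnostics report the
Shapiro-Wilk p-value of the standardized residuals and the correlation
between standardized predicted values and standardized residuals (zero by
construction for OLS with an intercept; reported as a sanity check).

```{r pipeline}
study <- simulate_study(sim_config(seed = 1))
head(study$scores, 5)
correlation_table(study$scores, study$records) |>
  filter(exposure == "miss_total") |> head(4)
hierarchical_table(study$scores, study$records)
```

## What the synthetic generator emulates

No public accession exists for the per-state response profiles or the
linked vital-statistics extracts, so the package ships a generator that
emulates the *structure* of that data: a cross-section of jurisdictions
(default 51, the 50 states plus DC) in which a single latent integration
level $\theta_j \in [0,1]$ drives both the regulatory item responses and
the midwifery workforce, while outcomes follow the same two-block
structure the regression fits.

* **Item responses** follow a latent-threshold (cumulative-logit) rule:
  for an item with $K$ ordered options and equally spaced thresholds
  $\tau_k = (k-1)/K$, the probability of reaching at least option $k$ is
  $\mathrm{logit}^{-1}\!\big(a(\theta_j - \tau_k)\big)$ with
  discrimination $a$. Any rule monotone in $\theta$ would satisfy the
  generator's contract; the cumulative-logit form was chosen because it is
  the standard ordered-categorical model and has closed-form category
  probabilities, which the calibration below exploits. At extreme $a$ the
  response degenerates to the top (bottom) option for $\theta$ at 1 (0),
  pinning the composite to 100 (0).
* **Defaults** were fixed once on realism grounds: $\theta \sim
  \mathrm{Beta}(4, 6)$ and $a = 4$ give composite totals that are
  approximately normal with a state-like spread (roughly 15--80, SD about
  14, median in the low 40s), matching the observed property that
  composite integration scores across US states are normally distributed
  and span only part of the 0--100 range. Percent non-Hispanic Black
  births is $100 \cdot \mathrm{Beta}(1.6, 8.4)$ (mean 16%, long right
  tail); births are log-uniform between 6,000 and 500,000; midwife
  headcounts are Poisson with mean $\mathrm{rate} \cdot \theta \cdot
  \mathrm{births}/1000$ at 1.5 CNMs/CMs and 0.6 CPMs per 1000 births at
  full integration; attendant-by-setting counts are Binomial with
  probabilities rising in $\theta$ and community births near 1.5% of
  births at mid-range integration. Outcome intercepts sit near national
  2014-era rates and effect directions mirror the associations the
  instrument was designed to detect, with magnitudes giving moderate
  state-level rank correlations.
* **Outcomes** are
  $y_j = \beta_0 + \beta_{\mathrm{black}}\,\mathrm{black}_j +
  \beta_{\mathrm{miss}}\,(\mathrm{MISS}_j/100) + \varepsilon_j$ with
  Normal noise, clamped to the outcome's valid range; clamping is logged
  and a warning recommends reparameterising when it touches more than 10%
  of draws (clamping, rather than a truncated distribution, keeps the
  generating equation transparent for the variance calculations below).
* **Determinism**: profiles and vital records consume separate seeds
  derived from the master seed, so regenerating one block never perturbs
  the other; the whole pipeline is byte-identical under a fixed seed.

What the generator does **not** emulate: spatial correlation between
neighbouring states, demographic structure beyond one race-composition
covariate, measurement error in vital registration, or any fitting of the
generator to real 2014 marginals. Passing tests therefore demonstrate the
pipeline's statistical correctness and calibration, not any empirical
claim about real jurisdictions.

## Calibration and the analytic variance share

Two simulation checks anchor the inference stack. Under a null
integration effect ($\beta_{\mathrm{miss}} = 0$) at 51 jurisdictions, the
F-change rejection rate at $\alpha = 0.05$ across 2000 replicate
vital-record draws must sit near the nominal level (the suite requires
0.03--0.07). For power, a planted effect of one outcome-SD
($\beta_{\mathrm{miss}}$ scaled so the integration component's SD equals
the noise SD) at 200 jurisdictions must be detected in at least 90% of
100 seeds, with the median $\Delta R^2$ within $\pm 0.05$ of the share
implied by the generating equation,

$$\Delta R^2_{\mathrm{pop}} =
  \frac{\beta_m^2 V_m}{\beta_m^2 V_m + \beta_b^2 V_b + \sigma^2},$$

where $V_b$ is the closed-form Beta variance of the race covariate and
$V_m$ is the variance of MISS/100 under the latent model. $V_m$ has no
closed form (the composite is a sum of ordered-categorical item scores),
so it is evaluated by numeric quadrature over the latent Beta density
using the closed-form cumulative-logit category probabilities — an
analytic route through the generating equation that never touches the
sampled data. The blocks are independent streams, so the variances add.

## Numerical choices and degenerate inputs

* Sum-to-optimum tolerance: $10^{-9}$ for derived rubrics, 0.5 for
  transcribed ones (configurable).
* Point values serialise as full-precision decimal strings, so rubric
  files round-trip bit-exactly.
* Spearman $\rho$ is clipped into $[-1, 1]$ against floating-point
  overshoot before the t transform; constant vectors are errors
  (undefined correlation), as are constant responses in $R^2$.
* Quartiles require $n \ge 4$; Shapiro-Wilk requires $3 \le n \le 5000$.
* Problem sizes in the shipped checks — 720 permutations at $n = 6$,
  1000 tied vectors, 100 random designs, 2000 null replicates at
  $n = 51$, 100 recovery seeds at $n = 200$ — were chosen as the smallest
  sizes at which each property is sharp (the null rejection rate has
  Monte-Carlo SE $\approx 0.5$ percentage points at 2000 replicates).

## Known limitations

The analysis is ecological: associations at the state level need not hold
for individuals, and nothing here supports causal claims. The packaged
rubric is a synthetic stand-in, so composite totals computed from it are
not comparable to published state scores. The correlation table applies
no multiple-testing correction, by design, to mirror the field's
reporting convention; users scanning 27 cells should interpret isolated
0.05-level stars accordingly.
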