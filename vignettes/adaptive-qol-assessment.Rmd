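---
title: "Adaptive quality-of-life assessment, feedback, and acceptability: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive quality-of-life assessment, feedback, and acceptability: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catqol)
```

## What this package models

`catqol` implements the computational machinery of a six-condition
experiment on quality-of-life (QoL) assessment: respondents complete
either a fixed-length questionnaire or a computerized adaptive test
(CAT), crossed with three feedback conditions (none, graphical bar
charts, or graphical charts plus tailored text). Afterwards they rate
the assessment on a short acceptability scale, whose between-condition
differences are analysed with ordinal effect sizes. Because raw survey
data of this kind are typically not redistributable, the package pairs
every analysis component with a seeded synthetic-data generator, so the
full pipeline is reproducible end to end.

## The measurement model

Item responses are modelled with Masters' partial credit model (PCM), a
Rasch-family model for ordered polytomous items. An item with step
thresholds $b_1, \dots, b_m$ (logit units) and categories $0..m$ has

$$P(X = k \mid \theta) \;=\;
  \frac{\exp\!\sum_{j \le k} (\theta - b_j)}{\sum_{c=0}^{m}
  \exp\!\sum_{j \le c} (\theta - b_j)},$$

with an empty sum for $k = 0$. We chose the step-threshold ("single
parameter" Rasch) form deliberately: it keeps the item score a
sufficient statistic, makes observed and expected information coincide,
and matches how polytomous QoL banks are usually calibrated. Item
information is the conditional variance of the category index,
$\mathrm{Var}(X \mid \theta)$, which also equals
$\partial E[X\mid\theta] / \partial\theta$.

### Trait estimation

`estimate_theta_mle()` maximizes the joint log-likelihood of a response
set by bounded one-dimensional search (tolerance $10^{-6}$) on
$\theta \in [-4, 4]$. The likelihood is strictly concave unless the
summed score sits at an extreme, so the maximizer is unique whenever it
is interior. All-minimum and all-maximum patterns have no finite MLE;
we clamp them to the respective bound and flag `converged = FALSE`.
The $\pm 4$ bound is a pragmatic choice: it is wide enough that
interior estimates are never distorted, yet keeps the standard error
finite so a 0–100 score can always be reported. The SE is
$1/\sqrt{\sum_i I_i(\hat\theta)}$ over administered items.

### The adaptive loop

`run_cat()` administers items one at a time: select the unadministered
item of the domain with maximum Fisher information at the provisional
estimate (ties broken by item id for determinism), obtain the
response, re-estimate, and stop at the first of

* SE `< se_stop` (default **0.45**, evaluated once at least
  `min_items_per_domain = 2` items are answered — the SE after a single
  item rarely means anything),
* domain bank exhausted,
* `max_items_per_domain` reached.

Maximum-information selection starting from $\theta_0 = 0$ (the
population mean, since nothing is known at session start) is the
standard CAT criterion. The SE rule is applied *per domain*, each
domain's CAT run independently and the administered counts summed —
the only interpretation that yields four domain scores with controlled
precision. One knowingly tolerated edge case: a bank smaller than
`min_items_per_domain` can exhaust with an SE already under the
threshold while still being labelled `bank_exhausted`.

### Norm-referenced scores

`theta_to_domain_score()` standardizes $\hat\theta$ against a
reference-population mean and SD per domain and maps
$z$ linearly onto the 0–100 reporting scale (0 = worst, 100 = best QoL)
as $50 + (100/6)\,z$, clipped to $[0, 100]$, so $\pm 3$ reference SDs
span the scale. Only the 0–100 range is externally fixed; the slope is
a package choice and is configurable through the norm parameters. The
synthetic reference population is standard normal per domain, so norms
default to mean 0, SD 1.

Fixed-length forms are scored by `score_fixed_form()` the conventional
way: reverse-keyed items recoded ($x \mapsto m+1-x$ on a $1..m$ scale),
the domain mean of non-missing items taken when at most 20% of the
domain's items are missing (never imputed beyond that), then mapped
linearly to 0–100. The guideline 4–20 intermediate is returned as an
extra column; it differs from the 0–100 endpoint only by composition of
linear maps.

## Feedback generation

`render_feedback()` is a pure function from domain scores and a
condition to a feedback bundle: no bars or text for `none`, one 0–100
horizontal bar per domain for `graphical`, and additionally one
tailored message per domain for `graphical_text`. Messages are chosen
by banding the score against the domain's population-average score:
within ±5 points (boundaries inclusive) is "average", below is
"lower", above is "higher". The half-width is configurable; the
templates interpolate the numeric score and domain name, and the
renderer fails loudly when a (domain, band) template is missing. The
band boundaries and template wording are representative of tailored
PROM feedback, not a reproduction of any instrument's copyrighted text.

## Acceptability psychometrics

The evaluation statistics are implemented from first principles and
each is tested against an independent oracle:

* **Cliff's delta** is computed exactly over all $n_x n_y$ pairs, with
  a 95% CI from the consistent variance estimator (normal quantile,
  truncated to $[-1,1]$).
* **Wilcoxon rank-sum**: for pooled $n \le 20$ the exact conditional
  distribution of the midrank sum is enumerated over all group
  assignments, with the two-sided P as twice the smaller tail (capped
  at 1); above that, the tie-corrected normal approximation with a 0.5
  continuity correction. Likert data are tie-heavy, so the tie
  correction is not optional. Note that with ties the exact null
  distribution is *not* symmetric, so the tail-doubling and
  distance-from-mean definitions of a two-sided P genuinely differ;
  the package uses tail doubling, the convention of `wilcox.test`.
* **P-value convention**: `classify_p()` labels $P < .005$ significant
  and $.005 \le P < .05$ suggestive, a reproducibility-oriented
  convention; no further multiplicity adjustment is applied, mirroring
  the experimental design the package emulates.
* **Loevinger's H**: pairwise $H_{ij} = 1 - F_{ij}/E_{ij}$ with
  polytomous category-weighted Guttman errors ($F$ observed, $E$
  expected under independence given the margins); item and scale
  coefficients are error-sum ratios. Step popularities are sorted in
  decreasing order with ties broken by item order then category — a
  documented convention, since tied steps make the weighting
  order-dependent. The implementation is verified against the
  covariance-ratio identity $H_{ij} =
  \mathrm{cov}(X_i,X_j)/\mathrm{cov}_{\max}$. The automated item
  selection procedure is the greedy AISP variant at lower bound .3
  (without significance screening). Scales with $H < .3$ are weak and
  $H > .5$ strong.
* **Cronbach's alpha** uses the standard variance decomposition with
  $n-1$ denominators.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed and
are not tuned per analysis.

* **Sample**: 1454 respondents allocated to the six conditions in
  proportion to target analysis sizes (226, 247, 219, 223, 211, 260),
  so that after attention filtering — failures drawn Bernoulli with
  rate 68/1454, independent of condition — the expected analysed sizes
  equal those targets.
* **Acceptability items**: each respondent has a latent acceptability
  $a \sim \mathrm{Logistic}(\mu_c, 1)$; item $k$'s 0–4 response is
  $\sum_j \mathbf{1}[a + \varepsilon_k > c_{kj}]$ with logistic noise
  (scale 0.95) and fixed per-item cutpoints. The cutpoints were chosen
  once so the control condition shows positively skewed items with
  means near 3.2, 3.3, 2.1 and 2.9 (total 11.5, SD 2.9) and the whole
  sample yields Cronbach's alpha near .77 and scale H near .52 — the
  regime the acceptability instrument is meant to operate in.
* **Effect calibration**: the finite 0–16 support admits exact
  computation of the total-score pmf per condition (quadrature over the
  latent, convolution over items), so each condition's shift $\mu_c$ is
  calibrated by monotone root search until the *population* Cliff's
  delta against the control equals its target (default per-arm targets
  0.09, −0.11, 0.01; the two graphical-plus-text arms share one shift
  calibrated so their pooled delta against the pooled no-feedback arms
  is 0.22). Calibration is verified by brute-force delta computation
  over the support; unattainable targets raise an error reporting the
  achievable range.
* **Viewing times**: log-normal per feedback condition with medians
  115, 132, 124 and 147 s and log-SD 0.6 — right-skewed, and implying
  pairwise deltas close to the ones the time comparisons are meant to
  exhibit. Times are absent in no-feedback conditions.
* **Appraisal items**: fixed categorical distributions with agreement
  rates near 82% / 93% (graphical accuracy / clarity) and 82% / 95%
  (text accuracy / clarity).
* **Item banks**: per domain, 25 five-category items with difficulty
  centers evenly spaced on $[-2, 2]$; each item's four thresholds are
  the center plus offsets spanning ±0.25, jittered with SD 0.15. This
  dispersion was calibrated once so a four-domain adaptive run at
  `se_stop = 0.45` administers about 18 items in total against the
  24-item fixed comparator — the regime in which measuring item
  reduction is meaningful.

What the generator does **not** emulate: real item content, real
population norms, differential item functioning, respondent dropout,
response styles (e.g. straight-lining), or any dependence of attention
failure on condition. Passing tests therefore demonstrate correctness
of the estimators and the pipeline under a well-specified ordinal
response model — not robustness to the messiness of real survey data.

## The pipeline

`run_study()` chains the stages deterministically from a master seed:
generate the survey, filter attention failures, compare every condition
against the fixed-length/no-feedback control (total and the four items:
delta, CI, exact-or-approximate Wilcoxon P, verdict), compute the
pooled feedback contrasts, assess the scale (Mokken H, alpha), tabulate
appraisal agreement and viewing times (the time table uses the
fixed-length/graphical arm as its reference), simulate the adaptive
arm at the analysed sample size to measure items administered and the
percentage reduction versus the 24-item form, score the fixed arm on
0–100, and render an example feedback bundle. Report rounding follows
the conventions of the tables it mirrors (percentages to one decimal);
underlying fields are kept at full precision.

## Numerical choices and problem sizes

Quadrature for the population pmf uses a logistic grid of half-width 16
at step 0.05; root searches use `uniroot` at tolerance $10^{-7}$, well
inside the ±0.01 calibration contract. Tests run the heavier
simulations at sizes chosen to keep the whole suite fast while leaving
clear statistical margins: trait-recovery and CAT-behaviour checks use
500 simulated respondents, scale-coefficient limits use 5000, effect
recovery uses 50 replicates at the full study size, and the type-I
calibration uses 200 replicates. Statistical assertions use 3–4
standard-error bands derived from the nominal sampling distributions,
never from observed runs.

## Known limitations

* Item parameters are inputs; the package does not calibrate banks from
  data, and offers no 2PL/graded-response or Bayesian (EAP/MAP)
  scoring.
* The Wilcoxon exact branch enumerates up to pooled $n = 20$;
  in-between sample sizes rely on the normal approximation, which with
  extreme tie patterns can drift from the permutation P.
* The AISP is the greedy variant; it can differ from genetic-search
  partitions on borderline data.
* Loevinger's H inherits the documented tie-break convention for
  equally popular item steps.
* The 0–100 mapping clips at ±3 reference SDs; respondents beyond that
  range are reported at the scale ends.
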