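# catqol

Simulation and analysis of computerized adaptive quality-of-life (QoL)
assessment experiments.

Patient-reported outcome measures (PROMs) are widely used in research
and care, but respondents can find long questionnaires burdensome and
uninformative. Two remedies are often proposed: **computerized adaptive
testing (CAT)**, which picks each next item from a calibrated bank
based on the respondent's provisional trait estimate and stops once the
estimate is precise enough; and **immediate feedback** — per-domain
score charts, optionally contextualized by tailored text. `catqol`
implements the full computational core of an experiment evaluating
both: the adaptive assessment engine, fixed-length scoring, feedback
generation, the ordinal psychometrics used to compare experimental
conditions, and a seeded synthetic-data generator that stands in for
raw survey data that cannot be redistributed.

The package is aimed at psychometricians and health-services
researchers who want a tested, reproducible reference implementation of
this design — to power simulations, analyse their own acceptability
surveys, or study how stopping rules and feedback policies interact.

## The models at the core

**Measurement.** Item responses follow Masters' partial credit model:
for an item with step thresholds `b_1..b_m`,

    P(X = k | θ) ∝ exp( Σ_{j≤k} (θ − b_j) ),   k = 0..m.

Traits are estimated by bounded maximum likelihood on θ ∈ [−4, 4];
`SE(θ̂) = 1/√ΣI_i(θ̂)` with `I_i` the PCM item information
(`Var(X|θ)`). The adaptive loop selects the unadministered item with
maximum information at the provisional estimate and stops when the SE
drops below 0.45 (after at least 2 items), the bank is exhausted, or an
item cap is reached. Scores are reported on a norm-referenced 0–100
scale: `score = clip(50 + (100/6)·(θ̂ − μ_ref)/σ_ref, 0, 100)`.

**Evaluation.** Between-condition differences on the 0–16
acceptability total are quantified with Cliff's delta
(`δ = P(X>Y) − P(X<Y)`, computed exactly over all pairs, CI from the
consistent variance estimator), tested with tie-corrected Wilcoxon
rank-sum tests (exact enumeration for pooled n ≤ 20), and labelled
significant at P < .005, suggestive at P < .05. Scale quality is
assessed with Loevinger's H (polytomous weighted Guttman errors, greedy
AISP at lower bound .3) and Cronbach's alpha.

## Worked example

One adaptive session against a synthetic 100-item bank, scored and fed
back:

```r
library(catqol)
set.seed(42)
bank <- generate_bank(synth_config()$bank_spec, seed = 42)
cfg <- cat_config(norms = list(physical = list(mean = 0, sd = 1)))
session <- run_cat(bank, pcm_responder(theta = -0.8), cfg, "physical")
print(session)
#> Adaptive session, domain physical: 4 items, stopped (se_reached)
#>   final theta -0.412 (SE 0.418)

score <- theta_to_domain_score(session$final, cfg, "physical")
print(score)
#> physical: 43.1 / 100 (z = -0.41, cat)

fb <- render_feedback(c(physical = score$score_0_100), "graphical_text",
                      norms = c(physical = 50))
print(fb)
#> Feedback bundle (graphical_text)
#>   physical       #########             43.1
#>   [physical/lower] Your score of 43 on this scale indicates that your
#>   physical quality of life is lower than average. ...
```

The session needed 4 of 25 physical items to reach SE < 0.45; the
respondent's simulated trait (−0.8) is recovered as −0.41 ± 0.42,
which maps to 43 on the 0–100 scale — within the ±5-point "average"
band's lower boundary, so the tailored text uses the lower-band
wording.

Comparing two ordinal samples:

```r
x <- c(3, 4, 4, 2, 4, 3, 4); y <- c(2, 3, 1, 2, 3, 2, 2)
print(cliffs_delta(x, y, p_value = wilcoxon_rank_sum(x, y)))
#> Cliff's delta = 0.755 (95% CI 0.413 to 1.000), n = 7 vs 7
#>   Wilcoxon P = 0.02214 (suggestive)
```

A full synthetic experiment — 1454 respondents, six conditions,
attention filtering, effect-size tables, scale analysis, adaptive-arm
simulation — runs in well under a minute:

```r
report <- run_study(synth_config(), seed = 1)
print(report)
#> Synthetic QoL assessment experiment
#>   enrolled 1454, excluded 71 (attention check), analyzed 1383
#>   acceptability scale: Loevinger H = 0.50 (medium), alpha = 0.75
#>   pooled graphical_text vs pooled none: delta = 0.21 (0.14 to 0.28), P = 3.07e-08 (significant)
#>   pooled graphical vs pooled none: delta = 0.08 (0.01 to 0.16), P = 0.0282 (suggestive)
#>   adaptive test: mean 17.9 items (SD 3.8) vs 24 fixed -> 25.3% reduction
```

`summary(report)` adds the per-condition effect table, appraisal
percentages and viewing-time comparisons; `report_to_json()` serializes
everything.

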