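---
title: "Methods: simulating and analysing metacognitive bias through treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing metacognitive bias through treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metacogtrack` implements a complete treatment-study design for
metacognitive bias: an adaptive perceptual task, simulated observers, a
synthetic three-arm cohort with two timepoints, transdiagnostic
questionnaire scoring, data-quality exclusions, and the repeated-measures
statistical pipeline. This vignette records the model, its assumptions, and
the design decisions taken where the design space was genuinely open.

## The staircase

Difficulty is the dot difference between two stimuli, manipulated in log
space. A **two-down one-up** rule makes the task easier by the scheduled
log-step after every error and harder after two consecutive correct
responses; its equilibrium accuracy solves $p^2 = 1/2$, i.e.
$p^\* = \sqrt{0.5} \approx 0.707$, so all observers perform near 71%
regardless of perceptual ability — the property that makes mean confidence
comparable across people.

Parameters (`staircase_config()`): 210 trials in 5 blocks; start log
difference 4.2; steps 0.4 / 0.2 / 0.1 for trials 1–5 / 6–10 / 11 onward;
dot range 6–81 (log 1.79–4.39); confidence scale 1–6. Decisions taken where
the procedure is conventionally underspecified:

* **Step indexing.** The step schedule is indexed by session trial number
  (1-based), not by block or by update count: "the first five trials" reads
  most plainly as trials 1–5.
* **Counter discipline.** The consecutive-correct counter resets after
  *every* step, in either direction, and after every error — the standard
  Levitt convention. The counter is therefore always 0 or 1.
* **Clamping and rounding.** Difficulty is clamped in log space to
  $[\ln 6, \ln 81]$ after every update; the displayed dot difference is
  `exp(log_diff)` rounded half-up and clamped to [6, 81]. (Note
  `round(exp(4.2)) = 67`.)
* **One continuous staircase.** Nothing resets at block boundaries.
* **No accuracy feedback.** Observers only see which side they chose, so
  simulated observers must not condition on correctness; none do.

Stimulus rendering (base dot counts, layout, timing accuracy) is not
simulated: no analysis depends on it, and no base count is specified for
the task. The fixation/stimulus/feedback durations are carried in the
config for provenance only.

The staircase is validated against an independent oracle: once the step
settles at 0.1, the process is a Markov chain over (difficulty grid,
counter); the test suite computes its stationary accuracy by power
iteration and checks simulated sessions against it, and against the
analytic asymptote $\sqrt{0.5}$.

## The observer model

Human participants are replaced by a type-1/type-2 signal-detection
observer. On a trial with log difference $d$, evidence $e \sim N(d,
\sigma)$; the choice is correct iff $e > 0$, so accuracy is
$\Phi(d/\sigma)$ — continuous and strictly increasing in $d$, which is all
the staircase requires to converge. Confidence is the count of five ordered
criteria (defaults $-0.25, 0.20, 0.65, 1.15, 1.75$ on the $|e|/\sigma$
scale) exceeded by $|e|/\sigma$, plus one; the criteria are shifted down by
a per-person **confidence bias** $b$ and optionally jittered. As
$b \to +\infty$ every rating is 6; as $b \to -\infty$, 1. Response times
are log-normal (median 1 s) and enter analyses only as session means.

`calibrated_observer(equilibrium_log_diff)` sets
$\sigma = d^\*/\Phi^{-1}(\sqrt{0.5})$ so the psychometric function crosses
the staircase equilibrium at a chosen difficulty. The default equilibrium
3.58 places the settled staircase near a dot difference of ~40 and
session-mean accuracy near 0.71.

## The synthetic cohort

`cohort_design()` encodes the generative study conditions: three arms
(defaults 649 / 82 / 88), two timepoints, latent dimensions
(anxious-depression AD, compulsivity-and-intrusive-thought CIT, social
withdrawal SW) standard-normal at baseline with correlations
(AD–CIT 0.4, AD–SW 0.5, CIT–SW 0.3), arm-specific mean improvement at
follow-up, and a confidence bias coupled to the dimensions:

$$b_0 = \beta_0 + \beta_{AD}\,AD + \beta_{CIT}\,CIT + \varepsilon,\qquad
\Delta b = \tau_{arm} + \gamma\,(\Delta AD - E[\Delta AD]) + \eta.$$

Questionnaire items invert the scoring rule: each of the 209 clinical items
responds as its scale midpoint plus half its span times the item's weighted
latent signal plus noise, rounded and clipped to its ordinal range. The
instrument structure (nine scales totalling 209 items, five WSAS items
0–8, two embedded catch items with mandated answers) matches the study
battery; the synthetic 209 x 3 weights matrix is a labelled stand-in with
realistic sparsity — real published weights are consumed from a
user-supplied file of the same format and are never embedded.

**Calibration.** Defaults were chosen once, analytically, so that a default
cohort reproduces the magnitudes reported for this design in the
literature: mean confidence ≈ 3.8 (between-person SD ≈ 0.85), mean dot
difference ≈ 42 at baseline falling to ≈ 40 with practice
(`practice_sigma_ratio = 0.952` shrinks perceptual noise at follow-up, so
difficulty increases while accuracy stays pinned), standardised baseline
confidence slopes ≈ −0.09 (AD) and +0.11 (CIT), standardised time effects
on confidence ≈ 0.17 / 0.31 / 0.11 across the three arms (the control
effect sized to be non-significant at n = 88), latent treatment effects
sized so the scored-AD time effects land near −0.32 (iCBT) and −0.61
(antidepressant) after item rounding/clipping and measurement attenuation,
and a change–change correlation ≈ −0.12. Conversion between bias units and
confidence points uses the measured criterion-slope (≈ 1.7–1.9 rating
points per bias unit near the scale centre); conversions between latent
and scored dimensions account for the ≈ 0.96 (levels) and ≈ 0.76 (change
scores) reliability of the weighted sums under default item noise.

**What the generator does not emulate.** Item scales are generic ordinals,
so absolute questionnaire totals are not comparable to the real
instruments; careless responding is independent across catch items (the
real correlation between failing two catches is not modelled); attrition,
dropout, practice effects on confidence criteria, engagement dynamics and
program content are out of scope; no observer fails the task wildly enough
to trigger the accuracy exclusion under defaults (exclusion machinery is
exercised by planted fixtures in the tests). Passing tests therefore show
that the pipeline is correct and calibrated under this generative model,
not that the model captures every feature of real cohorts.

## Task metrics and exclusions

Per session: mean confidence (the metacognitive bias measure), mean dot
difference (task difficulty; lower = harder), mean accuracy, mean RT, and
the larger choice-side proportion. Exclusions follow the published rules as
phrased: accuracy *strictly below* 0.60 or *strictly above* 0.85, or one
side chosen on *strictly more than* 95% of trials; boundary values are
retained, and `closed_bounds = TRUE` flips to the closed-interval reading
in one argument. Catch-item failures are reported but never exclude.
Split-half reliability correlates mean confidence on odd- versus
even-indexed trials (1-based) across sessions; raw confidence is used (the
residualised variant is not implemented). Completers need a retained
session and complete dimension scores at both timepoints.

## Scoring

Dimension scores are plain weighted sums over the 209 items. Centring
subtracts the *baseline* sample mean per dimension from both timepoints —
so baseline means are exactly zero and within-person change scores are
offset-invariant. Weights apply to raw item responses by default; a
`standardise_items` flag supports weight sets defined on z-scored items.
Per-instrument totals are simple sums used for exploratory per-scale
analyses.

## The statistical pipeline

* **Standardisation.** Continuous regressors and outcomes are z-scored
  (sample SD, n−1). Categorical regressors are dummy-coded and the dummies
  are *not* z-scored by default — a deliberate deviation from a fully
  literal "all regressors standardised" reading, chosen for
  interpretability of group contrasts; `z_score_dummies = TRUE` restores
  the strict reading. Time is coded 0/1 and never z-scored, so the time
  coefficient is the standardised within-person change.
* **Change models.** Random-intercept models (`lme4`, maximum likelihood)
  with Wald normal-approximation p-values; no estimator or df method is
  canonical for this design, and at two timepoints the time effect is
  algebraically the paired-difference estimate (a test asserts this). The
  normal approximation is mildly anticonservative at small n (rejection
  ≈ 0.06 at 40 participants), which the type-I suite's tolerance band
  acknowledges.
* **ANOVA.** Group x time (x covariate) F tables use Type-II sums of
  squares on the long observation-level model, with denominator df = total
  observations − parameters (e.g. 1632 for 819 participants x 2
  timepoints), matching the reporting convention for this design.
* **Exact contingency tests.** Pearson chi-square without continuity
  correction. The Freeman–Halton test enumerates every table with the
  observed margins depth-first (last cell of each row and the last row are
  forced), summing probabilities not exceeding the observed table's within
  a relative tolerance of 1e-7 — the convention of standard
  implementations, adopted so ties resolve identically to the reference
  `fisher.test` cross-check. An enumeration guard (product of free-cell
  ranges) raises an error suggesting the Monte-Carlo mode, which draws
  margin-fixed tables via `r2dtable`; the demographics table falls back to
  a seeded Monte-Carlo estimate automatically for infeasible tables (e.g.
  gender x three arms at full cohort size). Enumerated probability mass is
  returned and must equal 1 to 1e-9.
* **Summary-statistic tests.** Welch's t with Welch–Satterthwaite df,
  one-way ANOVA from group moments, and Tukey–Kramer studentised-range
  post-hocs are computed from closed forms and validated against raw-data
  references on moment-matched vectors.
* **Power.** Required n for detecting a correlation uses the Fisher-z
  approximation, searched for the smallest integer n ≥ 4 reaching the
  target power; a simulation-based oracle in the tests brackets it to ±2.
* **Multiplicity.** No multiple-comparison adjustment is applied anywhere
  except the Tukey post-hoc for the three-arm age comparison, mirroring
  the study's stated policy.
* Whether the three baseline dimension slopes come from one joint model or
  three separate ones is not canonical; the pipeline fits the joint model
  (all three dimensions plus covariates) by default, and the per-dimension
  variant is a one-line call to `cross_sectional_regression()`.

## Reproducibility and problem sizes

One master seed expands into labelled substreams (one per arm, one per
participant, one per session), so growing an arm never reshuffles existing
participants, and a persisted `run_config()` reproduces a run exactly. The
test suite uses a 500-session operating-point check, a 649-observer
recovery cohort at the full default arm sizes, and 500 null-replicate
cohorts of 50 participants per arm with 30-trial sessions for the type-I
calibration — sizes chosen to keep Monte-Carlo error well inside the
asserted bands while the whole suite runs in minutes on one core. The null
cohorts zero every coupling and arm effect *and* the person-level
confidence-bias variance, giving exchangeable observations under which each
test's nominal 5% level applies. This matters for the observation-level
ANOVA convention: with person-level heterogeneity present (a nonzero random
intercept), pooling between- and within-person variance makes its F test
conservative for within-person terms (the group x time interaction can
reject far below 5%) and optimistic for between-person main effects — an
inherent property of that reporting convention, not of this implementation,
and the reason the change analyses proper use random-intercept models.

## Known limitations

The observer is stationary within a session (no fatigue, lapses, or
sequential dependencies), confidence criteria are symmetric around the
evidence axis, and RT carries no information about difficulty or accuracy.
Latent change is modelled as a shifted Gaussian rather than a treatment
response distribution; arms share one perceptual noise level per timepoint.
The Freeman–Halton enumeration is exponential in table size by nature —
large sparse tables need the Monte-Carlo mode. Mixed-model p-values use the
normal approximation rather than Satterthwaite/Kenward–Roger df; at the
cohort sizes this package targets the difference is negligible, but it is a
known approximation at very small n.
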