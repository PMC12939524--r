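---
title: "Comparing a synovial-fluid probability score with physician standard of care: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing a synovial-fluid probability score with physician standard of care: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pjiscore)
```

## The problem

Periprosthetic joint infection (PJI) is a severe complication of hip and
knee arthroplasty. Its diagnosis is hard precisely where it matters most:
culture-negative and criteria-inconclusive cases, where physicians show
high indecision and a tendency to overdiagnose once forced to commit.
`pjiscore` implements, end to end, the statistical machinery used to
compare a machine-learning synovial-fluid probability score against
physician standard of care (SOC) on a cohort of clinical vignettes:

1. a synthetic vignette-cohort generator and two-stage rater simulator,
   so every downstream stage can be exercised and tested without access
   to restricted patient data;
2. a desk-scale surrogate of the two-stage probability score (Gaussian
   mixture, then logistic regression), with constant-value imputation and
   triage / forced-call thresholding;
3. agreement statistics against a clinical reference diagnosis — overall,
   positive and negative percent agreement (OPA/PPA/NPA) with Wilson
   intervals, Gwet's AC1 with bootstrap intervals, pooled multi-rater
   estimates and Stage-I indecision rates;
4. decision curve analysis (net benefit), a cost-derived threshold
   probability, and net-benefit improvement with bootstrap intervals;
5. a decision-analytic model of misdiagnosis costs with a Monte-Carlo
   patient-level cross-check.

Throughout, the *clinical reference* is a binary expert-adjudicated
diagnosis (`PJI` / `aseptic`), and the ternary criteria class
(`infected` / `inconclusive` / `aseptic`) is a separate, configurable
consensus-criteria score.

## The agreement model

For a binary strategy with confusion tally $(tp, fp, fn, tn)$, $n$ total:

$$\mathrm{OPA} = \frac{tp + tn}{n}, \qquad
  \mathrm{PPA} = \frac{tp}{tp + fn}, \qquad
  \mathrm{NPA} = \frac{tn}{tn + fp}.$$

OPA is exactly the prevalence-weighted mix of PPA and NPA — this identity
is enforced by a property test. Confidence intervals for these
proportions use the Wilson score interval; it is implemented in closed
form and cross-checked in the tests against `prop.test(correct = FALSE)`.

Chance-corrected agreement uses Gwet's AC1,

$$\mathrm{AC1} = \frac{p_a - p_e}{1 - p_e}, \qquad
  p_e = 2\bar\pi(1 - \bar\pi),$$

where $p_a$ is the observed agreement and $\bar\pi$ the mean of the two
marginal positive proportions. Unlike Cohen's kappa, $p_e$ stays
well-behaved at the extreme prevalence typical of suspected-PJI cohorts.
AC1 intervals are percentile bootstrap over case resampling
(`B = 2000` by default; neither the resampling unit nor `B` is dictated
by convention, so both are arguments). For pooled multi-rater statistics
every rater × vignette response counts as one observation (summed
confusion counts); bootstrap resampling for pooled statistics resamples
*vignettes* with all raters' calls attached, preserving within-case
correlation. Response-level resampling is available but not the default.

## Decision curve analysis

Net benefit at threshold probability $p_t$ is
$\mathrm{NB}(p_t) = tp/n - (fp/n)\, p_t/(1-p_t)$, with `treat_all` and
`treat_none` as reference policies. A threshold that reflects economic
rather than purely clinical preferences is derived from misdiagnosis
costs as $p_t^\ast = C_{FP}/(C_{FP} + C_{FN})$; at the default costs
($75{,}000$ and $62{,}375$ USD) this gives $p_t^\ast \approx 0.55$.

Two choices deserve explanation:

* **Fixed-call mode is the default for the score strategy.** A
  probability score can enter a decision curve either by re-thresholding
  the continuous score at each $p_t$ or by holding its binary forced
  call fixed across the grid. The package defaults to the fixed-call
  reading, which treats the score's validated 20-point cutoff as *the*
  decision rule being evaluated; score-thresholding is available via
  `score_threshold = TRUE`.
* **Two interventions-avoided conversions.** The standard conversion of
  a net-benefit difference into avoided interventions per 100 patients
  multiplies by $(1-p_t)/p_t$. A reciprocal-odds variant (multiplying by
  $p_t/(1-p_t)$) is also exposed, explicitly labelled non-standard,
  because published summaries sometimes print numbers in that direction;
  the two coincide only at $p_t = 0.5$.

## The misdiagnosis cost model

A hypothetical cohort of $N$ suspected cases at prevalence $\pi$ has
$N_{PJI} = \mathrm{round}(N\pi)$ infected cases. A strategy with given
PPA/NPA produces

$$N_{FN} = \mathrm{round}\big(N_{PJI}(1-\mathrm{PPA})\big), \qquad
  N_{FP} = \mathrm{round}\big((N - N_{PJI})(1-\mathrm{NPA})\big).$$

A false negative is costed as an equal-weight mixture of a repeat
diagnostic episode (\$1,000) and delayed operative management
(\$123,750), i.e. \$62,375 expected; a false positive as an unnecessary
two-stage septic revision (\$75,000). All rounding of expected counts is
*half away from zero*: this is the only rule consistent with every
published tally the model is checked against, and `round_counts = FALSE`
reports the unrounded expectations. Currency totals are accumulated in
integer cents. The conventional inputs are the printed, rounded PPA/NPA
values (e.g. 0.929/0.966), matching how such cohort projections are
usually quoted; full-precision inputs are equally valid arguments.
`monte_carlo_costs()` simulates the same cohort patient by patient and
is required by the tests to agree with the closed form within 1%.

## What the synthetic generator emulates

The generator's defaults encode the study conditions the analysis
assumes:

* **Composition is deterministic.** Exactly
  $\mathrm{round}(n \times 0.153)$ cases are PJI for every seed, and the
  borderline (criteria-inconclusive) aseptic subgroup likewise has a
  fixed count (10.9% of the cohort). Fixed composition makes tallies
  exactly reproducible, mirroring a fixed vignette set.
* **Biomarker availability** defaults to the observed rates of routinely
  collected markers (alpha-defensin 99.6%, SF-WBC 97.8%, SF-PMN% 96.7%,
  SF-RBC 63.5%, CRP 86.9%, research-only markers 0%), with independent
  per-biomarker Bernoulli missingness — only marginal availability is
  known, so no joint missingness structure is imposed.
* **Class distributions** are log-normal for counts and concentrations,
  scaled beta for percentages; alpha-defensin has an aseptic mode near
  0.2 (the reference central tendency) and a septic mode well above 1;
  antigen markers are baseline noise plus a per-pathogen Bernoulli spike
  in septic cases. The borderline subgroup has moderately elevated CRP
  and SF-PMN% so that it lands in the 2–5 point band of the default
  criteria table while remaining clinically aseptic and
  culture-negative. Parameters live in configuration, not code; they
  were chosen once to produce clear septic/aseptic separation with a
  realistically occupied intermediate band, and the availability and
  band-occupancy rates are verified by calibration tests (n = 5000 and
  n = 2740, within three binomial standard deviations).
* **Culture** is positive in septic cases with sensitivity 0.70,
  negative in aseptic cases, performed at all in 97% of cases, and the
  borderline subgroup is constrained culture-negative.
* **CRP units.** The generator emits CRP in mg/dL (threshold 1 mg/dL in
  the default criteria table) and tags the unit in `crp_unit`. The three
  built-in false-negative fixtures reproduce reported values whose unit
  was not annotated at source; they are tagged `"unspecified"` and the
  fixtures are used for scoring behaviour, not for unit-sensitive
  criteria claims.
* **Rater simulation.** Stage II is drawn first, so that each rater's
  expected PPA/NPA equal the profile targets; Stage I is `undecided`
  with a class-specific rate and otherwise equals Stage II, so a decided
  Stage I can never flip. The rate on criteria-inconclusive vignettes is
  the group rate (0.383 academic, 0.483 community, 0.475 infectious
  disease); the rate elsewhere is solved so the overall expectation
  matches each rater's observed overall indecision. By default the
  per-rater, per-stratum error and undecided *counts* are fixed at their
  rounded expectations with random placement (`mechanism =
  "fixed_counts"`), extending the deterministic-composition philosophy
  to the raters and reproducing pooled tallies exactly; fully
  independent Bernoulli responses are available via
  `mechanism = "bernoulli"`.

What the generator does **not** emulate: real biomarker covariance
(markers are drawn independently within class), case-mix drift between
institutions, rater learning or fatigue, and any correlation between a
rater's errors and specific biomarker patterns. Passing calibration
tests therefore show that the *pipeline* recovers the parameters it was
given — not that the synthetic data are clinically realistic in joint
distribution.

## The surrogate score

The deployed probability score this package surrogates was trained on
tens of thousands of clinical samples; that model is proprietary and out
of reach. The surrogate keeps its architecture — unsupervised Gaussian
mixture on scaled biomarker panels, then a logistic map to a 0–100
probability scale, no culture input — and its decision thresholds, but
is fitted to the package's own synthetic cohorts. Its only contract is
architectural fidelity and strong discrimination on its own training
distribution (held-out AUC at least 0.95 in the tests); its scores carry
no clinical meaning.

Numerical choices:

* **Scaling**: log10(x+1) on counts/concentrations (SF-WBC, SF-RBC,
  CRP), identity on percentages and signal ratios, then
  standardization. Configurable via `log_features`.
* **Imputation before scaling** with fixed raw-scale constants (the
  published central-tendency values, e.g. alpha-defensin 0.196, SF-WBC
  843, A280 0.643), so the published imputed values are reproduced
  exactly. Features constant after imputation (never-observed markers)
  are excluded from both stages.
* **Mixture**: diagonal-covariance (`mclust` model `"VVI"`), `k = 2` by
  default (a septic/aseptic reading; the deployed model's component
  count is not public). `k = 1` degenerates cleanly to a plain logistic
  model. Responsibilities are recomputed from stored parameters via
  log-sum-exp, so a model serialized to JSON scores identically after
  reload.
* **Stage 2** regresses the label on component responsibilities plus the
  scaled features. On well-separated synthetic classes the fit is
  near-separable; coefficients are large and scores saturate, which is
  expected and harmless for threshold-based use.
* **Thresholds**: `low < 20`, `equivocal = [20, 80)`, `high >= 80` —
  the high band is closed on the left, matching the "greater than or
  equal to 80" convention — and the forced call is `PJI` iff
  `score >= 20`, so forced `PJI` exactly when triage is not low.

Two empirical caveats discovered while validating the surrogate, both
encoded in the tests rather than hidden:

* **Monotonicity** of the score in alpha-defensin and SF-WBC along an
  aseptic-to-septic path holds up to a numerical ripple of order 1e-4
  score points deep in the saturated tail (posterior responsibilities
  are not globally monotone along a straight path); the test asserts
  non-decrease with a 1e-3 tolerance.
* **The permutation null of held-out AUC is not centred at 0.5** for
  this architecture. The unsupervised cluster axis survives label
  permutation, and the logistic stage's small-sample bias on the highly
  skewed responsibility predictor gives a systematically signed
  coefficient; any consistent sign is amplified by the near-separable
  geometry into extreme AUC values. The package therefore validates
  discrimination the standard way — the real-label AUC must exceed
  every value of an 8-refit empirical permutation null — instead of
  testing the null against 0.5.

## Reproducing the reference comparison

`reproduce_study()` recomputes, purely from in-built summary tallies
(no synthetic data), the headline numbers of the comparison: the
agreement rows of both strategies, the expected false-negative cost, the
economic threshold, the cohort cost model for both strategies with the
per-case savings, and the net-benefit improvement at the economic
threshold with a bootstrap interval. Because only tallies are published,
case-level bootstrap data are reconstructed by placing each rater's
error counts uniformly at random across vignettes (seeded); the
resulting intervals assume independent error placement across raters,
which is the weakest assumption available without the raw survey data.

```{r, eval = FALSE}
reproduce_study(boot_B = 2000, seed = 1)
```

## Problem sizes and determinism

Default sizes were chosen to keep every analysis comfortably
desk-scale: surrogate training cohorts of 1000–2000 vignettes,
evaluation cohorts of 274 (the reference design), bootstrap `B = 2000`
for reported intervals, 10,000 Monte-Carlo replicates for the economics
cross-check, and 20 seeds for the parameter-recovery study. Every
random draw descends from one user-facing seed through fixed-purpose
sub-streams (labels, biomarkers, culture, missingness, raters,
bootstrap), so adding raters does not perturb the cohort and identical
configurations give byte-identical outputs.

## Known limitations

* Biomarkers are conditionally independent within class; no attempt is
  made to model the covariance of real synovial-fluid panels.
* The default criteria rule table is a minimal configurable stand-in for
  a consensus scoring system (single-culture major criterion; four
  weighted minor criteria); users comparing against a specific published
  revision should supply their own `icm_rule_table()`.
* The cost model is U.S.-payer based, undiscounted, with no test-harm
  term and no QALYs; savings do not generalize to other cost structures.
* The surrogate's scores are meaningful only relative to its own
  synthetic training distribution.
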