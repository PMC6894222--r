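---
title: "Methods: building sensory-motor deficit scales for CIA cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building sensory-motor deficit scales for CIA cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arthrism)
```

## The problem

In the collagen-induced arthritis (CIA) mouse model, disease severity is
graded by eye: joint swelling and redness scored 0–10 per paw, summed to
0–40 per mouse. The score is cheap and ubiquitous but operator-dependent,
and it says nothing directly about what the disease does to the animal's
sensory and motor function. Behavioral assays measure that — thermal
withdrawal latency for pain-like sensitivity, open-field traveled distance
for global locomotion, paw print area for gait — but they are slow and
equipment-bound. This package quantifies the statistical link between the
two, and packages it as an instrument: a linear scale that predicts the
relative sensory and motor deficit from the clinical score alone.

## The model

For each functional modality we pool all (clinical score, value) pairs —
across groups (untreated, treated, controls), experiments and time points —
and fit one ordinary least-squares line

$$\mathrm{value} = \beta_0 + \beta_1 \cdot \mathrm{score} + \varepsilon .$$

Association strength is reported separately as Spearman's rank correlation
(average ranks for ties), because score grids are discrete and the
monotone-association question is nonparametric, while the prediction
question is served by the parametric line. The line's value at score 0,
$\beta_0$, is the *reference*: the theoretical readout of an unaffected
animal under the pooled conditions. The relative functional deficit at
score $s$ is then

$$D(s) = \frac{\beta_0 - (\beta_0 + \beta_1 s)}{\beta_0} \times 100
       = -100\,\frac{\beta_1}{\beta_0}\, s ,$$

which is linear and exactly 0 at $s = 0$ by construction. Expressing the
score as a percentage of its maximum ($s\% = 100\,s/s_{\max}$) gives each
modality a single summary number, the deficit slope
$-\beta_1 s_{\max}/\beta_0$ in percent deficit per percent of maximal
score. The fitted slopes, one per modality, *are* the scale; prediction is
multiplication, inversion is division, and both round-trip exactly.

Assumptions worth stating plainly: the score–function relationship is
treated as linear over the observed score range (the deficit scale is a
re-parameterisation of a straight line, nothing more); pairs pooled across
days and mice are treated as exchangeable for the purpose of the fit, so
the OLS standard errors ignore the repeated-measures correlation within
mice; and the reference is an extrapolated model quantity, not the naive
group mean — the two coincide only if the line is right.

### Score pairing

Paw-level modalities (latency, print area, skin temperature) are paired
with the *same-side hind paw* score (0–10); whole-mouse modalities
(traveled distance) pair with the total score (0–40). Whether a hind-paw
readout should pair with its own paw's score or with the two-paw sum
(0–20) is genuinely ambiguous in the field's reporting; pair counts in
published work are consistent with per-paw units, so `per-paw` is the
default and `pairing = "summed-hind"` provides the alternative. Front-paw
functional readouts are generated by the simulator but not consumed: hind
paws carry the behavioral assays.

### Raw or naive-relative values

Group-level longitudinal comparisons require naive-referenced ratios
(`relativize()`: each value divided by the naive-group mean at the same
experiment and day) so that independent experiments can be pooled. For the
pooled regression itself both spaces are supported (`space = "raw"` or
`"relative"`); raw is the default since the published regressions plot raw
parameter values. References are computed *within* experiment — pooling is
achieved by the ratio, not by mixing denominators — and naive animals are
relativized against their own group mean, which mean-centers them at
exactly 1. Score-like modalities (clinical score, histology) are never
relativized: they already live on a common semi-quantitative grid, and a
healthy histology mean of 0 would make the ratio undefined.

## Scoring definitions

* **Total clinical score**: exact integer sum of 4 paw scores, max 40.
* **Arthritic**: endpoint total strictly greater than 10. The strictness
  matters: a mouse at exactly 10 is not arthritic.
* **Incidence**: 100 × arthritic / immunized, over the untreated immunized
  set.
* **AI (arthritis improvement) score**: for a treated mouse,
  `100 × (ref − total) / ref` where `ref` is the untreated group's mean
  endpoint total. Mimics the ACR20/50/70 construction. Negative AI (worse
  than the untreated mean) is reported as-is. The endpoint defaults to the
  last scored day in the data (`endpoint_day` parameter), reconciling
  datasets whose final clinical day differs from the final functional day.
* **Responder classes**: poor below 20, high at or above 70, mild between.
  The published bands ("< 20", "20 < AI < 70", "> 70") leave the points 20
  and 70 unassigned; we close the bands on the left so every finite AI has
  exactly one class and the more-improved class wins at a boundary. The
  cuts are a parameter (`boundaries = c(20, 70)`).
* **Histology score**: sum of three 0–3 subscores (synovial inflammation,
  bone erosion, cartilage erosion), max 9 per paw.

## The synthetic-cohort generator

No public CIA dataset exists, so the generator is first-class, tested
code, and its defaults *are* the study conditions the analysis assumes:

* **Design**: 3 independent experiments, groups per experiment
  naive = 8, CFA = 5, untreated CIA = 8, MTX-treated = 8 (totals 24 / 15 /
  24 / 24); measurement days 14 (pre-boost baseline), then 28, 35, 42, 49
  weekly.
* **Incidence**: each immunized mouse develops arthritis with probability
  0.875; non-developers stay at score 0.
* **Severity trajectory**: zero before a Gaussian onset day
  (mean 30, SD 3, truncated after the day-21 boost), then a logistic rise
  (rate 0.5/day, midpoint 6 days after onset) to a per-paw ceiling drawn
  uniformly from 5–10 — the simplest monotone saturating shape consistent
  with published severity curves, which show onset around day 28 and a
  plateau by day 49. Clinical scores are the severity rounded half-up to
  the integer grid (a fixed rounding rule keeps runs bit-reproducible).
* **Treatment response**: MTX mice draw a responder class (poor / mild /
  high with probabilities 6/23, 6/23, 11/23, matching the reported
  subgroup sizes) and a multiplicative severity attenuation uniform in
  [0.8, 1.0], [0.3, 0.7] or [0.0, 0.2] respectively — ranges chosen so the
  induced AI-score distribution lands mice across the three bands.
* **Functional ground truth**:
  `value = baseline × (1 − true_slope × score / max_score) + N(0, sd)`,
  with the paired score as defined above. Defaults: latency 10 s baseline,
  slope 0.26, SD 1.2 s (clipped to the 20 s heat-source cutoff); distance
  4000 cm / 10 min, slope 0.55, SD 450 cm; print area 40 mm², slope 0.55,
  SD 5 mm²; skin temperature 25.6 °C with slope −0.12 (the negative
  "deficit" makes the raw value *rise* ≈12% at maximal score, matching the
  inflammation direction — note the sign convention: positive slopes are
  losses); paw swelling 2.05 mm, slope −0.24. The sensory/motor slope pair
  (0.26 vs 0.55) encodes the finding the scale exists to express: motor
  deficits respond about twice as strongly to the score as sensory ones.
  Noise SDs are set so that noiseless-mean differences at the disease peak
  are a few SEM at the default group sizes, the regime typical of the
  published group comparisons.
* **Determinism**: every mouse owns a private RNG stream derived from
  `(seed, mouse index)`, so adding mice never perturbs existing ones, and
  identical configurations are bitwise-reproducible.

What the generator deliberately does **not** emulate: biomechanical gait
(print area is an abstract linear-in-score quantity); mechanical (Von
Frey) and static weight-bearing readouts, which are unsuitable for
bilateral arthritis; within-mouse serial correlation of the noise;
bell-shaped (non-monotone) time courses such as the transient skin
temperature peak — in the generator, temperature tracks the score, not the
day; and drop-out/death. Passing tests therefore demonstrate correctness
of the *analysis machinery* under the stated linear-plus-noise conditions,
not that real CIA data are this well-behaved; with real data the pooled
correlations are expected to be substantially weaker.

## Numerical choices

* OLS via `stats::lm`; Spearman r via `stats::cor`; the two-sided p-value
  for r uses the large-sample t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df ($|r|=1$ maps to $p=0$). The
  test suite cross-checks both against brute-force normal equations, an
  exhaustive average-rank oracle, and an exact permutation null at small n.
* Degenerate samples (zero variance in the functional values) report
  slope 0, r = 0 and a `degenerate` flag instead of failing, so batch runs
  survive pathological simulations; zero variance in the *scores* is an
  error, since no line is identified.
* Deficit-slope confidence intervals use the delta method on
  $-\beta_1 s_{\max}/\beta_0$ with the OLS coefficient covariance.
* Deficits are never clamped to [0, 100]: a positive regression slope
  (skin temperature) legitimately yields negative "deficits" (gains), and
  scores outside the fitted range extrapolate with a flag and warning
  rather than an error.
* Tie-break and rounding: clinical scores round half-up (`floor(x + 0.5)`),
  fixed for determinism.
* CSVs are comma-separated UTF-8 with header rows and empty fields for
  missing values; scale JSON stores doubles with 17 significant digits so
  a serialize–load round trip reproduces predictions bitwise. No artifact
  carries a timestamp, making pipeline runs byte-identical for a fixed
  seed.

## Problem sizes

The default cohort (87 mice, 3 experiments) yields 870 hind-paw pairs per
paw-level modality and 435 whole-mouse pairs, enough for stable fits in
seconds. The parameter-recovery suite uses 100 replicate cohorts of 201
mice each and checks that the 95% delta-method intervals cover the
generator's true deficit slopes in at least 90 of 100 replicates; the
responsiveness-ratio recovery check uses a 450-mouse cohort so the
estimator's sampling error is well inside the ±0.1 band being asserted.
The binomial incidence check uses 10,000 immunized mice (3 standard
errors ≈ 1 percentage point).

## Known limitations

* The scale is strictly linear; saturating or threshold score–function
  relationships would need a different model, and extrapolation beyond the
  observed score range is flagged but not validated.
* Pooled OLS ignores the repeated-measures structure, so p-values and CIs
  are anti-conservative on real longitudinal data; a mixed-effects
  extension is out of scope.
* Predictions are point-valued; no uncertainty intervals are attached
  (a bootstrap over mice would be the natural addition).
* The AI score compares only to the untreated-group endpoint mean, not to
  each mouse's own baseline — faithful to the ACR-mimicking construction,
  but worth knowing when interpreting responder classes.
* Skin temperature is generated and normalized but excluded from the
  default three-modality scale, mirroring the established instrument;
  any modality present in a scale file is accepted at prediction time.
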