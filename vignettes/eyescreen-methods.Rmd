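---
title: "Methods: digitized micropattern assays and probability-based irritation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digitized micropattern assays and probability-based irritation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyescreen)
```

## The measurement model

The unit of observation is an 80 µm circular micropattern carrying a small
colony of human corneal epithelial cells (about 4.5 ± 2 cells). Keeping
colonies below ~10 cells is what makes a 50%-of-cells binary readout
meaningful: with a handful of cells per pattern, "at least half responded"
is a robust, nearly analog-free statistic, and a chip yields hundreds of
such binary observations per condition — enough to support logistic
regression, which needs on the order of ten events per parameter.

Two mechanisms are read out per compound:

* **Apoptosis.** Caspase-3/7 intensity is measured per cell (nucleus mask
  dilated by 2 px to capture perinuclear signal) and expressed as the
  relative excess over the mean of the vehicle-control cells on the same
  chip, \((I - \bar I_{ctrl})/\bar I_{ctrl}\). A cell is positive when
  this exceeds 0.20; a micropattern is positive when at least 50% of its
  cells are.
* **TRPV1 activation.** Each cell's Fluo-4 trace is normalized by
  subtracting its own intensity at the first frame (baselines are highly
  heterogeneous across cells, so a per-cell offset is the only defensible
  normalization), then summed over the 20 frames following compound
  addition (~4 s at 5 fps). A strictly positive integrated peak area marks
  a responding cell; the same 50% rule makes the pattern call. The
  fixed short window deliberately captures both sharp agonist-like
  transients and the slower, broad transients typical of surfactant
  irritants, while staying ahead of slow drift.

Pattern outcomes at concentration \(C\) (nM) are modelled per assay as
Bernoulli draws from \(P(C) = \mathrm{logistic}(\beta_0 + \beta_1 C)\),
fitted by maximum likelihood (IRLS). The two assay probabilities are
combined as the union of non-mutually-exclusive events,
\(P_A + P_T - P(A \cap T)\).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| apoptosis threshold | 0.20 | relative excess | the assay's defining cutoff; strict (`>`) at the boundary |
| pattern rule | ≥ 0.5 | fraction of cells | inclusive at exactly 50%; `strict = TRUE` gives the `>` reading |
| integration window | 20 | frames | ~4 s post induction at 5 fps |
| mask dilation | 2 | px | captures cytoplasmic caspase / Fluo-4 around the nucleus |
| min nucleus area | 20 | px | rejects specks at the default ~1 µm/px scale without losing real nuclei; configurable |
| ROI search | 500 iterations, ±10 px | — | rigid integer shift; origin always evaluated first |
| dose scale | linear nM | — | published slopes are quoted per nM on the linear scale; `log10_dose = TRUE` available |
| confidence level | 0.95 | — | Wald band on the linear predictor, delta method |

## Design choices where the procedure was open

* **"Auto-threshold" = Otsu.** The binarization method for the nuclei
  channel is a standard bimodal default and behaves like ImageJ's
  IsoData family on bright-nuclei/dark-background images. A constant
  image yields an empty mask plus a warning rather than an error.
* **Connectivity.** Nuclei components use 8-connectivity. The available
  labeller in EBImage is 4-connected, so components are derived from the
  8-neighbour pixel graph with igraph instead.
* **Touching nuclei are not split.** Small colonies on 80 µm patterns are
  sparse by design; a watershed step would add failure modes without
  changing counts in this regime.
* **ROI registration is one global rigid shift.** Plate misplacement is a
  rigid translation, so a single integer offset is searched, uniformly in
  ±10 px, with ties broken by the first-encountered maximum and the
  nominal origin tried first (an aligned chip therefore always reports
  (0, 0)). Because nuclei are confined strictly inside the pattern
  circles, the foreground-in-ROI score can plateau over a few
  neighbouring offsets; registration is identifiable only up to that
  plateau, which is harmless downstream because every plateau member
  keeps all nuclei inside their ROIs. Tests compare the random search to
  an exhaustive enumeration at the score level for this reason.
* **The 20% rule.** The normalization is implemented as relative excess
  \((I-\bar I_{ctrl})/\bar I_{ctrl} > 0.20\) — the only reading under
  which "20%" is unit-free. The threshold is configurable for users who
  want a different cutoff.
* **≥ 50% vs > 50%.** The inclusive rule is the default (a 2-of-4 pattern
  is positive); the strict variant is available via `strict = TRUE`.
* **Zero integrated area scores 0.** Only a *positive* area is evidence
  of influx; the measure-zero boundary case is assigned to the negative
  class.
* **Intersection rule.** \(P(A \cap T)\) is not identifiable from
  marginal fits; the default is the independence product
  \(P_A P_T\), which reproduces the worked combined probabilities for
  both reference compounds. Any alternative can be supplied as a
  function and is validated against the Fréchet bounds.
* **Slope-zero assays.** A concentration-independent response (e.g. a
  flat TRPV1 probability) has no identifiable slope and no IC50;
  `irritation_profile()` therefore accepts a constant probability in
  place of a fit, and `ic50()` raises an explicit error when
  \(\beta_1 \le 0\).

## Numerical notes

* Fitting is `glm(binomial)` IRLS (tolerance 1e-8, 100 iterations) with
  covariance from the inverse observed information. Degenerate designs —
  one distinct concentration, or all-identical outcomes — are rejected
  up front with explanatory errors. Separation is flagged when the
  linear predictor exceeds 1000 logit units or the information matrix is
  numerically singular.
* Predictions are clamped to the open interval (0, 1) so that downstream
  probability algebra never sees exact 0/1 from floating-point
  saturation.
* The integrated peak area is a rectangular sum with dt = 1 frame. The
  only downstream use is its sign, which is identical to a trapezoidal
  rule on these windows; frame units avoid a silent rescale by the frame
  interval.
* Frames are numbered from 0 (the baseline frame); the integration
  window is frames `induction_frame + 1 … induction_frame + 20`, so a
  trace must extend at least 21 frames past a 0-based induction index.
* Mask dilation uses a Euclidean closed-disc structuring element (all
  offsets with \(dr^2 + dc^2 \le d^2\)), clipped at image borders.
* CSV writers emit 15 significant digits; JSON is written at full
  precision. Write→read round-trips are exercised in the tests.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has checkable ground truth.

* **Cell counts** per pattern follow a rounded normal, truncated below at
  one cell. Only the first two moments of the real count distribution are
  reported anywhere (4.5 ± 2 for primary hCECs); the law itself is a
  stand-in chosen to match those moments while guaranteeing no empty
  pattern (an empty pattern has no 50% readout).
* **Nuclei** are non-overlapping Gaussian-profile discs (σ = radius,
  truncated at the radius) placed by rejection sampling inside each
  pattern circle. The truncation keeps the dimmest nucleus pixel at
  ~0.61 of peak, so with a dark background the Otsu cut falls in the
  empty gap and noiseless segmentation recovers the rendered discs
  *exactly* — this is what makes the round-trip tests exact rather than
  approximate.
* **Caspase intensities** are uniform over each nucleus disc: control
  level for normal cells and 1.4× control for apoptotic cells — safely
  above the 1.2× level that the 20% rule needs to separate classes by
  construction. With pixel noise the separation is merely very probable
  rather than certain.
* **Calcium time-lapses** render uniform-intensity discs following each
  cell's true trace (baseline ~ normal with configurable CV, plus a
  sharp `exp(-(u-1)/5)` or broad gamma-shaped `(u/10)e^{1-u/10}`
  transient). Uniform discs make re-measurement over the exact mask
  reproduce the true trace identically in the noiseless case. Defaults
  correspond to 5 min at 5 fps with induction after 1 min.
* **Binary dose-response tables** are direct Bernoulli draws from a
  configured logistic law — the cleanest possible ground truth for the
  fitting code.

Not emulated: photobleaching, illumination gradients, cell motion during
acquisition, cytoplasm rendering, optical blur between nuclei, or
debris. Passing tests on synthetic chips therefore demonstrate the
*correctness of the computation* given images that satisfy the stated
assumptions (bright separated nuclei on dark background, rigid grid
shift); they do not certify segmentation performance on degraded real
microscopy, where flat-field correction or nucleus splitting might be
needed upstream.

In the end-to-end pipeline (`run_pipeline()`), ground-truth apoptosis is
drawn at the *pattern* level from the configured logistic law, with
unanimous colonies: this realizes the law the fit is meant to recover
exactly, so the manifest's fitted coefficients can be compared directly
with the generating ones. Per-cell Bernoulli fractions are available
through `simulate_chip_image()` for property checks (e.g. monotonicity of
the positive-pattern fraction in the per-cell probability).

## Problem sizes

The test suite and the acceptance script are sized to be thorough but
quick: segmentation-at-scale uses one noiseless 25 × 40 chip (1000
micropatterns, ~4500 cells); parameter recovery uses 500 patterns per
concentration over each compound's tested range; the Wald-coverage study
uses 500 Monte-Carlo fits of 3000 observations; oracle-equivalence checks
(grid-search likelihood, exhaustive ROI offsets, brute-force window sums)
run on deliberately small instances where exhaustive enumeration is
feasible. The full suite runs in well under a minute.

## Known limitations

* Chips are treated as exchangeable: no chip- or well-level random
  effects, so overdispersion across biological repeats is not modelled.
* Wald bands are first-order asymptotic; profile-likelihood intervals
  would behave better near separation but are not provided.
* The independence intersection is an assumption, not an estimate; if
  cell-level joint outcomes were recorded, \(P(A \cap T)\) could be
  estimated directly.
* Linear-in-C logit is the published parameterization and is kept as the
  default even though log-dose models are more common in pharmacology;
  both are available, but curves fitted on different scales are not
  comparable parameter-by-parameter.
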