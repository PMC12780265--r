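---
title: "Intermediate reasoning for BCR prognostication: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intermediate reasoning for BCR prognostication: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostir)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The prognostic problem

Five-year biochemical recurrence (BCR) after radical prostatectomy —
serum PSA above 0.2 ng/mL on two consecutive evaluations — is the binary
outcome. The established predictor is the Gleason score (sum of the two
most prevalent histologic patterns, each 3–5; clinically 6–10), but it is
discrete, observer-dependent, and incomplete: patients with identical
Gleason grades can carry very different risks. Whole-slide images contain
additional signal, but feeding hundreds of image features straight into an
outcome model overfits and breaks under domain shift (different specimen
types, scanners, staining across institutions).

The pipeline's answer is an *intermediate reasoning step*: compress the
image features into a single clinically anchored score, and let only that
score (optionally with PSA) enter the final outcome model.

## Stage 1: patch composition and the visual codebook

Slides are tiled on a stride lattice (0-based, half-open
`[x0, x0 + patch)` intervals; right/bottom remainders are dropped rather
than padded — the simplest convention exactly consistent with
non-overlap). Codebook training uses `stride = patch_size` (disjoint
patches); inference may use `stride < patch_size` (overlapping patches,
all tallied, no deduplication). The patch edge defaults to 128 px for
real imagery — pixel geometry is a free knob because magnification alone
does not fix it — and tests/examples use 16 px to keep synthetic slides
small.

A patch is *background* unless the fraction of its pixels with HSV
saturation above `s_min = 0.08` and value below `v_max = 0.95` exceeds
`f_min = 0.5`: unstained glass is near-white (low saturation, high
brightness), H&E-stained tissue is not. The thresholds are conventional
starting points for H&E masks; only tissue patches enter every downstream
tally.

The default embedding is a handcrafted 20-dimensional descriptor
(per-channel mean/SD, an 8-bin magnitude-weighted gradient-orientation
histogram, six radial log-power spectrum bins). When patch-level outcome
labels are available, a linear discriminant (BCR-positive vs negative) is
fitted on the descriptors and appended as a 21st coordinate — preserving
in miniature the contract of a penultimate network representation trained
on outcome labels, at desk scale. The backend is pluggable: any
deterministic patch-to-vector map can replace the default.

The codebook is k-means (Lloyd, via `stats::kmeans`) with k-means++
seeding and `n_restarts = 5`, best within-cluster sum of squares kept;
`k = 100` by default (an empirical choice at clinical scale; tests use
`k = 10`). Embedding columns are z-scored before clustering and the
transform is stored with the codebook: without this, a supervised
discriminant coordinate (within-class variance 1) dominates the Euclidean
metric over raw color moments (scale ~0.05) and clustering follows the
outcome label instead of texture. Assignment is nearest centroid in the
stored metric, ties broken by the lowest cluster index — tie-breaks and
the metric are pinned because reproducibility requires it, not because
the alternatives are wrong.

Per-cluster **impact scores** are the smoothed fraction of a cluster's
patches originating from BCR-positive patients,
`(n⁺ + s)/(n⁺ + n⁻ + 2s)` with `s = 1`: 0.5 is neutral, smoothing keeps
scores strictly inside (0, 1) and defines a value for empty clusters.
Feature display uses size `|0.5 − impact| + 2.5`; slide feature maps
carry each tissue cell's impact and a high/low flag at the 0.5 threshold.

## Stage 2: the reasoning-oriented score

The nine clinically observed pattern pairs map to a base scale 2–10:

```{r}
reasoning_scale()
```

The order refines Gleason by pattern composition and is deliberately not
monotone in the Gleason score (8 (5+3) ranks above 9 (4+5)); the mapping
is immutable. Training samples are shifted +1 (BCR-positive) or −1
(negative), spanning 1–11. The adjustment uses the observed outcome and
therefore exists only at training time; at inference the score is
predicted from composition. Targets are min-max scaled by their
*theoretical* range — (s−1)/10 for the reasoning scale, (g−6)/4 for the
Gleason comparison target — so the scaler is data-independent and
identical across cohorts; an empirical min/max would couple the scaler to
the training sample and silently shift external predictions. The Gleason
comparison regresses the numeric score (not grade groups), matching the
grading system used throughout.

The intermediate regressor is ridge, `min ‖y − Xw − b‖² + λ‖w‖²` with an
unpenalized intercept, solved by QR on the λ-augmented design. λ is
chosen from the log-spaced grid 10⁻³…10³ by 5-fold inner cross-validated
MSE (the method statement fixes "ridge" but not the penalty or selection
rule; a grid plus inner CV is the standard completion). Predictions are
returned unclipped for ranking — clipping would flatten exactly the
extreme patients a ranking metric cares about — with a clipped copy for
display.

## Stage 3: BCR prediction and recalibration

Five designs are compared: Gleason score only; the k compositions
directly; the ML-predicted Gleason score; the ML-predicted reasoning
score; PSA plus the reasoning score. The final model is *linear*
regression on the binary label — kept linear to match the method it
implements — with a logistic recalibration (outcome on linear score,
fitted on training data) bolted on so that Brier scores, calibration
curves and decision curves operate on genuine probabilities; by the
logistic score equations the mean recalibrated probability equals the
training incidence ("updating" to incidence). Both intercept+slope and
intercept-only recalibration are provided; intercept+slope is the default
because the linear score's scale is arbitrary. AUROC is computed on the
raw linear score and is invariant to the strictly monotone recalibration,
so configuration comparisons never depend on it. PSA enters untransformed
by default (a log option exists); the composition-only design falls back
to ridge with λ = 1 when n ≤ k, where plain least squares is undefined.
A design whose columns are all constant degenerates to the
incidence-probability model rather than erroring, and outcome-named
columns in any design are a hard error.

## Evaluation protocol

Internal validation is stratified 3-fold cross-validation (stratified
because unstratified folds can lose an outcome class at small n; the
protocol statement itself does not specify). All fitting — intermediate
regressors, final models, recalibration — happens inside the training
folds; pooled out-of-fold predictions feed the metrics. External
validation fits once on the training cohort and applies the frozen bundle
to each external cohort; any patient-id overlap between training and test
(including duplicated ids within a cohort, which make fold disjointness
uncertifiable) aborts the run.

AUROC is the Mann–Whitney probability with ties counted ½. Bootstrap CIs
resample patients with replacement, redrawing resamples that lose an
outcome class (keeping the iteration count exact; the bias is negligible
at cohort sizes used); percentile 2.5/97.5 bounds are reported — the
reference protocol states only "bootstrap", so the simplest interval is
used, 10,000 iterations at clinical scale and a few hundred in tests.
Calibration uses ten equal-width bins (deciles-of-probability rather than
deciles-of-rank; the choice is not specified upstream and equal-width
bins make the curve independent of the score distribution). Decision
curves use the threshold grid 0.05–0.60 by 0.05 — a clinically relevant
range for recurrence decisions, unquantified upstream. Fisher's exact
test (via `stats::fisher.test`, the minimum-likelihood two-sided rule)
and the Wilcoxon rank-sum test characterise cohorts; the Wilcoxon uses
exact enumeration over group assignments for n ≤ 10 (valid under ties,
where the classical exact null is not) and the continuity-corrected
normal approximation otherwise.

## The synthetic generator: what it emulates, and what it does not

The generator stands in for multi-institution clinical cohorts:

```{r}
cfg <- cohort_config()
str(cfg[c("n_patients", "gleason_probs", "psa_mu", "psa_sigma",
          "beta0", "beta_grade", "beta_psa", "beta_hidden",
          "hidden_sd", "dirichlet_conc")])
```

* **Gleason pattern pairs** are drawn from a nine-category distribution.
  Published per-combination frequencies are not available, so the default
  reflects a typical surgical cohort (3+4 and 3+3 dominant, primary-5
  patterns rare).
* **PSA** is log-normal with meanlog 2.2, sdlog 0.6, matching a cohort
  mean ≈ 10.9 and SD ≈ 7.3 ng/mL.
* **Outcome**: `P(BCR) = logistic(β₀ + β_g·base + β_p·log PSA + β_h·h)`
  with a latent "hidden" histologic signal `h ~ N(0, 1)`. The defaults
  (β₀ = −3.7, β_g = 0.35, β_p = 0.9, β_h = 2.2) were calibrated — before
  any pipeline run, using the analytic target-direction oracle
  `AUROC(base + E[±1 | patient]) − AUROC(base)` — to land at the
  published operating points: prevalence ≈ 0.48, Gleason-only external
  AUROC ≈ 0.60–0.65, and a reasoning-vs-Gleason external gap ≈ 0.1. The
  hidden signal must be this strong because the ±1 outcome adjustment is
  small against the 2–10 base range, so only ≈ 2p(1−p)·β_h of it reaches
  the score direction.
* **Composition**: cluster probabilities are
  `Dirichlet(conc · softmax(w₀ + z_grade·grade_loadings + h·impact_loadings))`
  with multinomial patch counts (200–400 per patient). Grade loadings
  make the Gleason patterns visible in composition (as they are in real
  tissue — without them the ML-predicted-Gleason configuration would be
  structurally impossible); impact loadings carry the partially
  independent hidden signal. `conc = 200` leaves realistic
  patient-to-patient composition noise.
* **Domain shift**: external cohorts multiply the Dirichlet concentration
  (default ×0.5 — noisier compositions) and offset stain colors, changing
  marginal input statistics while the outcome mechanism (all βs) is
  untouched — the setting in which a well-specified pipeline should
  transfer and an overfitted one should not.
* **Slides**: each cluster is one texture family (H&E-like stain color
  interpolated purple→pink, oriented sinusoidal grating, pixel noise) on
  a near-white background, laid out as a shuffled patch grid with exact
  ground truth.

Deliberately **not** emulated: nuclear morphology and stain physics,
longitudinal PSA trajectories, censoring and time-to-event structure, and
scanner-native slide formats. Passing tests therefore demonstrate that
the pipeline recovers the signal structure it assumes — not that the
default embedding suffices for real histology, where a learned backend
would replace it through the same contract.

## Reproducibility

All randomness flows from one integer run seed. Each stochastic stage
derives its own seed via `derive_seed(seed, offset)` — an affine hash
reduced modulo 2³¹−1, with a fixed documented offset per stage — so a
stage's output is reproducible regardless of how many random numbers
earlier stages consumed, and the whole pipeline is bit-for-bit
reproducible per seed (the manifest written by the command-layer echoes
the resolved configuration and file checksums).

## Problem sizes

Cohort sizes default to 170 (internal) and 71/39 (external), mirroring
the clinical cohorts the generator emulates; the headline synthetic
experiment averages external AUROCs over 25 run seeds. The test suite
runs the same machinery at reduced size — k = 10 clusters, 16-px patches,
cohorts of 8–120, bootstrap of a few hundred — chosen so the full suite
exercises every stage, including the image path, in well under a minute.

## Known limitations

* The default embedding is a fixed descriptor; on real slides its
  separation power, not the pipeline logic, would be the binding
  constraint.
* The impact score uses patch counts pooled over patients, so patients
  contributing many patches weigh more; no per-patient normalisation is
  applied because the upstream definition pools patches.
* Linear-probability final models can produce out-of-range raw scores;
  all probability metrics use the recalibrated map, and the raw score is
  used only where only ranking matters.
* The 1–11 scale treats the ±1 outcome shift as exchangeable across base
  grades; no ordinal-likelihood or monotonicity machinery is attempted.
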