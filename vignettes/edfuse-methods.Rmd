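---
title: "Event-driven multimodal deterioration prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven multimodal deterioration prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edfuse)
```

## The prediction problem

Emergency-department (ED) patients generate clinical data irregularly: a
triage assessment at arrival, vital signs re-measured whenever a nurse deems
it necessary, a laboratory panel for some patients, a chest radiograph for
about two thirds, free-text fields (chief complaint, patient information,
EKG reports) for varying subsets, and — for monitored patients — dense
vital-sign streams. The task `edfuse` addresses is *event-driven,
multi-horizon* risk prediction: every time new data arrive for a patient, the
model re-predicts whether one of four deterioration outcomes (in-hospital
cardiac arrest, circulatory shock, advanced airway management, ICU admission)
will occur within 1 h, 2 h, ..., 12 h of that moment.

Two design constraints follow. First, predictions must be possible at *any*
data-update time, with whatever subset of features happens to exist —
no fixed-width feature vector, no imputation. Second, the timing of each
observation is informative and must reach the model.

## Windows and labels

Each admission is cut into *prediction windows*: one window per distinct
data-acquisition time, from admission (t = 0, the triage window) up to —
strictly before — the outcome onset for positive cases, or up to discharge
otherwise. A record updated three times after admission therefore yields four
windows. Each window carries a 12-element binary label vector: element *h* is
1 iff the outcome occurs inside the half-open interval
\((t_{\mathrm{ref}},\, t_{\mathrm{ref}} + 60h]\) minutes. An onset exactly on
a horizon boundary counts as positive; labels are monotone non-decreasing in
*h* by construction. Note that negative windows arise from positive cases
too: an early window of a patient who deteriorates 20 hours later has an
all-zero label vector.

Windowing multiplies negatives far beyond the case-level imbalance, so two
sampling regimes are provided and used during training only:

* **window-wise oversampling** — minority windows are re-drawn with
  replacement until the positive:negative ratio reaches a target (default
  1.0). Suited to large cohorts.
* **case-wise balancing** — each mini-batch is assembled from several
  positive-source and several negative-source admissions, with a per-record
  cap (default 4 windows per batch) so a single long stay cannot dominate a
  batch. Suited to small cohorts, where oversampling would fill batches with
  copies of a handful of windows.

## The set embedding (one token per observation)

Every observation in a window becomes one token of width `d_model`,

\[ e^i \;=\; e^i_{\text{time}} + e^i_{\text{value}} + e^i_{\text{feature/modality}}, \]

where the *time* embedding applies a `Linear -> tanh -> Linear` MLP to the
(scaled) difference between acquisition time and the prediction reference
time; the *value* embedding is modality-specific (below); and the
*feature/modality* embedding is a lookup-table row — one row per sparse
feature, one shared row per non-sparse modality, plus a reserved UNK row for
feature ids unseen at training time. Features that were never measured simply
contribute no token; the variable-length token set is the entire input.
Deleting one observation deletes exactly one token, which is also what makes
post hoc ablation exact (see below).

Value embedders by modality:

* **sparse tabular** (vitals, labs, triage codes): the scalar, standardized
  by training-split mean/sd, through `Linear -> tanh -> Linear`. The
  standardization statistics are computed on the training split only and
  frozen into the model object.
* **dense vitals** (monitor streams; 5 channels in fixed order RR, SBP, HR,
  DBP, SpO2): two 1-D convolutions over time (kernel 3 / stride 2, then
  kernel 3 / stride 1; channels 5 → 16 → `d_model`) with ReLU after each.
  Each output step is assigned the acquisition time of the *last* input
  sample in its receptive field — a declared convention, since any single
  time must summarize a receptive field. Blocks shorter than 7 samples
  (the two-layer receptive-field minimum) yield no tokens.
* **image**: a backbone maps the grayscale array to a fixed-length feature
  vector, followed by a trained linear projection to `d_model`. The backbone
  is a pluggable contract; the bundled stand-in is a deterministic 4×4
  grid-pooling encoder (16 features). Only the *latest* radiograph in a
  window is embedded. Loading a large pretrained vision backbone behind the
  same contract is a documented extension.
* **text** (chief complaint, patient information, EKG report; one token per
  field): a text backbone produces per-position vectors with a designated
  summary vector, which is linearly projected to `d_model`. The bundled
  stand-in is a seeded bag-of-words encoder (mean of fixed word embeddings),
  so permuting non-summary positions provably leaves the output unchanged.

## Fusion and the classifier head

The token set (N × `d_model`) enters a transformer encoder *without
positional encoding* — temporal information already lives inside every token
via the time embedding, and the set has no meaningful order. Attention is
masked so tokens attend only within their own window; padded/foreign
positions are excluded, which makes the batched forward pass exactly equal to
the window-at-a-time forward pass (tested). The fused representation is the
masked mean over the window's tokens. Mean pooling was chosen because it
preserves the permutation symmetry that dropping positional encoding implies;
the pooling reduction is a genuinely open design point, recorded here as
such.

The head is `Linear -> BatchNorm -> ReLU -> Linear -> sigmoid` with 12
outputs, one per horizon, trained with mean binary cross-entropy over
horizons. Inference uses the running batch-norm statistics, so a single
window's prediction never depends on batch composition. The 12 sigmoid
outputs are *not* forced to be monotone across horizons; the labels are
monotone and the model learns the ordering.

Training uses Adam (default learning rate `1e-3` at desk scale), the
configured imbalance sampler, and per-epoch validation logging of
per-horizon AUROC/AUPRC, macro averages, and their sum. Both the sum and the
macro-AUPRC are logged; checkpoint selection uses the highest validation
macro-AUPRC, the rule suited to rare-event precision. Transformer
depth/width defaults (`layers = 2`, `heads = 4`, `d_model = 256`) are
configuration, not architecture: the desk-scale experiments in the tests and
the acceptance script use `d_model` 16–32 with one layer, which trains in
minutes on one CPU.

## Logistic-regression baseline

The comparison suite fits one binomial GLM per horizon — 12 binary models —
on fixed-width rows built with the classical recipe: carry-forward (latest
observation at or before the window's reference time), then training-mean
fill for never-observed features. Step 1 (triage) uses triage variables and
initial vitals, excluding DBP for its collinearity with SBP; Step 2 adds
follow-up vitals, mental status, labs, and follow-up-minus-initial vital
deltas. Free text is excluded. Mental status is encoded ordinally
(alert = 0 ... coma = 4), a choice this package makes explicitly since
standard encodings vary. The GLMs are fitted by IRLS with the iteration cap
raised to 1000; no penalty is applied (the package documents its own
default here: with thousands of windows per horizon and ~20 features,
maximum likelihood is stable, and unpenalized fits are what the
parameter-recovery tests presume). Horizons whose training labels are
single-class are marked degenerate and excluded from macro averages with a
warning.

## Evaluation and interpretation

AUROC uses the midrank statistic; AUPRC is average precision — the
step-wise precision-recall integral without interpolation, the convention
stated here because interpolated variants differ. Both are validated in the
test suite against O(n²) brute-force enumerations to 1e-9. Confusion
metrics (sensitivity, specificity, precision, F1) are reported at a
configurable threshold, default 0.5, since the choice is otherwise
unstated; macro averages are unweighted means over the 12 horizons, with
single-class horizons excluded and flagged.

**Ablation importance.** For each feature (or whole modality) the tokens of
that feature are deleted — never zero-filled, because zero is a legitimate
observed value — and the model is re-scored on the subset of test cases in
which the feature was observed at least once. Importance is the macro-AUROC
/ macro-AUPRC drop, `full − ablated`, on that subset.

**Sequence-length analysis.** Windows are stratified by token count into
quantile bins and scored per bin, probing whether accumulating more events
improves prediction.

**Time-resolution experiment.** For monitored cohorts carrying dense blocks
on a 1-minute base grid, the circulatory-shock model is trained and scored
once per discretization interval (e.g. 1, 10, 30, 60 min), the dense blocks
being downsampled to each interval (rows at minutes 0, k, 2k, ...;
`ceiling(t/k)` rows). The reference configuration discretizes at 10-minute
intervals.

## The synthetic cohort generator

Hospital event streams cannot ship with a package, so every downstream stage
is exercised on a simulator whose *statistical shape* matches the reference
cohort: irregular vital-sign re-measurement (exponential gaps, mean 60 min),
laboratory testing in ~72% of cases, chest imaging in ~66%, EKG report text
in ~44%, lognormal lengths of stay with ~85% of stays under 12 h, and
low case-level outcome prevalences (defaults 0.2% IHCA, 0.9% advanced
airway, 2.6% circulatory shock, 3.5% ICU admission).

Outcome times come from a *planted hazard*: an inhomogeneous first-event
process with piecewise-constant intensity
\(\lambda(t) = \lambda_0 \exp(\beta^\top z(t))\), where \(z(t)\) are risk
features read off the simulated trajectory (systolic hypotension depth,
tachypnea, heart-rate trend, latest lactate, mental-status code) between
observation knots. Onset times are drawn by exact inversion of the piecewise
cumulative hazard, and \(\lambda_0\) is calibrated per outcome on the
simulated trajectories so the achieved prevalence hits the configured
target (a fixed baseline can be supplied instead, in which case the achieved
prevalence is reported). This is the simplest process whose risk genuinely
depends on the evolving trajectory, which is exactly what makes
"more data → better prediction" testable. Severity also tilts the
chief-complaint/EKG template vocabulary toward high-risk phrases and
brightens the central blob of the procedural 16×16 images, so the text and
image stand-ins have real signal to find. Dense monitor blocks are generated
on a 1-minute grid with a fast autoregressive component whose amplitude
grows with severity, making recency genuinely informative for the
time-resolution experiment.

What the simulator does *not* emulate: real physiology (no pharmacology, no
circadian structure), realistic radiographs or prose, inter-feature
correlations beyond the shared severity factor, and measurement artifacts.
Passing tests on this cohort demonstrate that the pipeline's mechanics —
windowing, embedding, fusion, training, evaluation, ablation — behave as
specified on data with the right shape; they say nothing about clinical
performance on real patients.

`planted_signal_cohort()` is a sharper fixture for ablation recovery: the
hazard depends on a *single* sparse feature (observed for every case) and
every other feature is independent noise, so that feature must rank first in
a correct importance analysis.

## Experiment scale and fixed conditions

The package's own experiments (test suite and acceptance script) run at desk
scale, chosen once and kept fixed:

* Learnability / null-control: a 2,000-case planted-signal cohort
  (signal in lactate, drawn at triage for every case, beta = 3; outcome
  prevalence 20%, the regime of the monitored reference sub-cohort rather
  than the full retrospective one). The planted-*signal* fixture is used
  rather than the full trajectory hazard because a calibrated baseline
  intensity at a fixed prevalence necessarily assigns part of the outcome
  mass to baseline (unpredictable) events: the learnability question —
  can the model find a strong effect — needs positives that are
  predictable in principle. A label-shuffled copy of the same cohort is
  the chance-level control. Model size 24 hidden dimensions, 1 encoder
  layer, 2 heads.
* Ablation recovery: 3 seeds, 600-case planted-signal cohorts.
* LR parameter recovery: 20,000 directly generated windows, 3 features.
* Sequence-length curve: a 700-case latent-risk cohort
  (`planted_signal_cohort(..., carrier = "repeated")`): the hazard level is
  constant per case and expressed only through repeated noisy systolic
  blood-pressure measurements, so a window with more observations permits a
  better estimate of the latent level by construction — the property the
  curve is meant to detect, planted explicitly. The drifting-trajectory
  hazard is unsuited to this experiment: its late-stay regime is
  memoryless (drift plateaus, onsets arrive exponentially), so the
  longest-window stratum measures extrapolation rather than accumulated
  information, and its stratum AUROC is unstable.
* Time-resolution: 250-case monitored cohorts (dense blocks on all cases,
  150-min span), intervals 10 and 60 min, case-wise balanced batches.

Numerical choices: probabilities are clamped at 1e-7 in the loss; layer
norm and batch norm use eps 1e-5; batch-norm running statistics use momentum
0.1; attention scores are max-shifted before softmax; Adam uses the standard
(0.9, 0.999) moments. Degenerate inputs are contracts, not silent paths:
empty windows, single-class metrics, too-short dense blocks, negative time
deltas and non-finite values all raise typed errors or documented warnings.

## Known limitations

* The image and text backbones are deterministic stand-ins honoring the
  encoder contracts; swapping in large pretrained encoders is plumbing, not
  research, but is not done here.
* One model per outcome task; no parameter sharing across the four outcomes
  (the reference design is ambiguous on sharing, and separate models are
  the simpler reading).
* No competing-risk treatment across outcomes and no continuous-time
  survival labels — horizons are binary classifications by design.
* Case-level bootstrap confidence intervals are provided as an extension
  point only; correlated-AUROC comparisons (DeLong) are out of scope.
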