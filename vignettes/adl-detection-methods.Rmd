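---
title: "Methods: multi-label ADL detection from smartphone and ambient sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label ADL detection from smartphone and ambient sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlsense)
```

## The pipeline and its assumptions

`adlsense` detects twelve Activities of Daily Living — preparing drink,
preparing meal, toileting, eating, using computer, watching tv, walking,
showering, organizing, using phone, room transition, other — from a
smartphone worn on a neck lanyard, optionally complemented by ambient
sensors. Detection is *densely labeled multi-label* sequence classification:
every 6-second step carries an independent binary decision per class, so
parallel activities (eating while watching TV) are first-class citizens
rather than label noise.

The pipeline is hybrid. The phone's raw accelerometer is never fed to the ADL
model directly; instead a small CNN first condenses each 6-second window into
a probability vector over low-level activities (lying down, on table,
sitting, standing, walking — and optionally running), and those probabilities
become ADL features on a 3-second grid. The assumptions this encodes:

* **Low-level motion is a sufficient statistic of the phone's view of the
  body.** Posture and ambulation carry most of what a chest-worn phone can
  say about an activity; the CNN compresses away device-specific signal
  detail, making the downstream model transferable across phones.
* **The phone is not always on the person.** A stationary phone reports the
  table it lies on, not its owner. The phone-on-table detector (below)
  explicitly models this state instead of letting it corrupt the wearable
  ground truth.
* **Labels are incomplete and partly wrong.** Self-reported intervals are
  jittered, merged, and missing. The loss masks unlabeled time rather than
  discarding it, because the LSTM needs continuous context even where no
  gradient flows.

## Stage 1: low-level recognition

**Phone-on-table detection.** Over 1-second windows the phone is flagged
stationary when |mean a_z| > 9 m/s² (flat, screen up or down) *and* every
per-axis standard deviation is < 0.7 m/s². The inequalities are strict, so
boundary values fail. The thresholds only make sense in m/s² (gravity ≈ 9.81
passes the 9 m/s² bound); a `units = "g"` switch rescales them for feeds in
g. Windows with fewer than two samples have no standard deviation and are
flagged `FALSE` with a warning. Flagged windows overrule the wrist-worn
minute labels: we apply the overruling at minute resolution and relabel a
minute "on table" when at least half of its detector windows are flagged —
the temporal granularity of overruling was an open choice, and a majority of
the minute is the most defensible reading given that the wearable labels are
per-minute objects.

**Wearable label chain.** The wrist-worn stream delivers a probability vector
over five classes every 7.5 s. "Label smoothing" is implemented as a
centered temporal mean filter over the probability vectors (default kernel 3,
edges truncated) — the simplest smoothing consistent with probabilities as
inputs; the exact recipe was unspecified upstream, so the kernel is exposed.
Minutes aggregate by argmax of the mean vector over their eight steps, with
ties broken by the declared class order for determinism. Minutes with no
wearable data stay missing rather than being imputed: ground truth is not
fabricated. Running minutes are discarded before CNN training (the class is
both rare and irrelevant to the target ADLs).

**The CNN.** Input windows are 6 s at a nominal 32 Hz = 192 samples — the
rate is inferred, since 192 samples over 6 s force it; jittered streams are
linearly interpolated onto the grid when timestamp jitter exceeds 10 % of the
nominal interval. The architecture is seven 1-D convolutions (defaults: two
32-filter/kernel-5 layers then five 16-filter/kernel-3 layers), max pooling
of size 2 after every second convolution (three pools, 192 → 24), dense
layers of 32 and 16, and a softmax head. Pooling placement was not pinned
down by the source description beyond "we apply max pooling"; any placement
consistent with the printed layer counts is configurable, and every-second-
layer is the default because it spreads the temporal compression evenly. The
output head is configurable between 6 classes (with "on table") and 5
(running dropped) — the upstream description is internally inconsistent on
this point ("5 classes" vs. a "6 values long vector"), so both are supported
and tested.

Each training window takes the label of the minute containing its center;
windows whose minute is missing are excluded. Augmentation applies one random
3-D rotation per window (angles uniform within ±15° per axis, composed
X·Y·Z — "small" was unquantified, and 15° covers realistic lanyard sway)
plus Gaussian noise (default σ = 0.1 m/s²). The objective is categorical
cross-entropy with inverse-frequency class weights, optimized with Adam
(default learning rate 1e-3): the original objective was unstated, and
balanced weighting mirrors the ADL stage's balancing philosophy.

**Participant-grouped validation.** `make_cv_split()` reproduces the
evaluation protocol: 10 participants held out, the remaining 21 partitioned
into 4 validation folds of sizes 6/5/5/5, no participant on both sides of a
fold.

## Stage 2: features

All features live on a 3-second grid; a 10-minute window is a 200 × F matrix.

* **Low-level probabilities** (6 columns): the CNN's output, carried forward
  onto the grid.
* **Phone usage** (binary): reconstructed active-use intervals. Foreground
  app events are filtered against a system-utilities list (keyboard,
  launcher, ...; a default ships in `inst/extdata/system_utils.txt`), `Off`
  entries are inserted at screen `off`/`locked` events (`on`/`unlocked` do
  not end usage), the list is sorted, each entry ends at its successor's
  timestamp, and `Off` entries are dropped. A re-notification of the app
  already in the foreground does not start a new interval.
* **Steps** (count) and **ambient light** (mean lux per bin; empty bins carry
  the last value, 0 before any sample). Raw lux is unbounded, so model input
  is `log1p(lux)/log1p(10000)` clipped at 1 — a fixed 10,000-lux ceiling
  (bright daylight) keeps the feature in [0, 1]; the scaling was our choice,
  as unbounded inputs destabilize training.
* **Time since fridge / appliance use**, normalized over 12 h:
  `min(t − t_last, 43200)/43200`. Appliance power (cooking plate, cooking
  hood, kettle, coffee machine, TV) is used purely as a binary switch: a
  trigger at every upward crossing of the power threshold and — by default —
  throughout any above-threshold period, so an appliance counts as "just
  used" while it is on (rising-edge-only is available). With no prior event
  the feature is 1.0: an appliance unused for ≥ 12 h is indistinguishable
  from never-used at the cap.
* **Room location** (one-hot over the room registry plus `unknown` before any
  event) and **room lights** (binary, last state carried forward, default 0).

Eight presets combine these groups: `probs_only`, `probs_phone_steps`,
`probs_appliances`, `probs_all_phone`, `probs_location`, `all`,
`all_except_location`, `ambient_only`. A preset requiring a missing modality
fails with an error naming it.

## Stage 3: the sequence model and its loss

Windows are 10 minutes with a 2-minute stride — long enough to span related
activities (cooking, then eating, with a toilet break in between), with
enough overlap that each activity is seen in several temporal contexts. The
network is: LSTM over the 200 steps returning the full sequence → skip
connection concatenating the LSTM output with the raw input → pointwise
convolution (16 filters, kernel 1, rectifier) → max pooling of size 2
(time 200 → 100) → pointwise convolution (12 filters, kernel 1, sigmoid).
Gaussian noise is applied to the input features during training only, and the
skip connection concatenates the *noisy* input (the LSTM and the convolution
stack see the same data — the alternative orderings were unspecified
upstream; this one keeps train/inference consistency trivial). There are no
normalization layers. With `use_lstm = FALSE` the LSTM and skip connection
disappear, leaving a pointwise baseline with no temporal context — the
control for what sequence memory buys.

**Label pooling 200 → 100.** Labels live on the 3-second grid but predictions
on the 6-second output grid; the reconciliation was never specified, so each
output step pools its two label rows by per-class max (an activity present in
either half is present) and its weights by mean (a half-labeled step counts
half). Max/mean is the only pooling that neither invents nor destroys
positive labels.

**The loss.** Mean over the 12 classes of a balanced binary cross-entropy,
weighted along time:

$$\mathrm{loss} = \frac{1}{12}\sum_{c}\frac{\sum_t w_t\left[w^+_c Y_{tc}(-\log p_{tc}) + w^-_c(1-Y_{tc})(-\log(1-p_{tc}))\right]}{\max(\sum_t w_t,\ \varepsilon)}$$

with predictions clipped to [1e-7, 1 − 1e-7]. The class weights
`w⁺ = L/(2P)`, `w⁻ = L/(2(L−P))` (L = total labeled weight, P = positive
labeled weight) satisfy `w⁺P + w⁻(L−P) = L`; the balancing mechanism was
named but not specified upstream, and this balanced-inverse-frequency form is
ours. Classes never seen positive get `w⁺ = 1` plus a warning. A fully
unlabeled window contributes exactly 0, and perturbing predictions at
zero-weight steps leaves the loss bit-identical — both properties are tested,
as is the analytic gradient of every layer against finite differences.

Training uses Adam; the reference protocol is 350 epochs at batch size 1024,
and both are configuration values (the tests use reduced epochs at desk
scale). Optional l1/l2 penalties act on the weight matrices. Sigmoid outputs
binarize at 0.5 by default (threshold exposed — the choice was unstated
upstream). At inference, overlapping windows' probabilities for the same
absolute step are arithmetically averaged (up to 5 overlaps at the 2-minute
stride). A random hyper-parameter search (`hyperparam_search()`) draws
learning rate, LSTM units and l1/l2 log-uniformly and dropout/noise
uniformly, scoring by mean validation loss over the 4 folds, and persists the
full trial log.

## Evaluation

Metrics are computed on the 6-second output grid, restricted to steps with
positive label weight — unlabeled truth is unknowable, matching the loss
masking. For each class: precision, recall (TPR), TNR, balanced accuracy
`(TPR+TNR)/2`, micro-F1 (precision and recall pooled over the positive and
negative class, which reduces to accuracy for a binary task), macro-F1 (mean
of the two per-class F1 values), and binary log loss. A class with no
positive step reports recall as missing, never 0, and participant-level
aggregation excludes missing cells from that cell's mean.

The joint 13 × 13 confusion matrix flattens each step's prediction and label
sets into pairs: exact matches first; remaining members of both sets
cross-matched in seeded-random order (recorded seed; the randomness moves
counts only among off-diagonal cells, never the diagonal or the margins —
tested across 100 seeds); leftovers pair with the *false negative* column or
*false positive* row. Pair count per step is `max(|preds|, |labels|)`, a
deliberately conservative accounting.

## The synthetic world

`generate_session()` does not imitate real signal statistics; it emulates the
*structure* of a real recording so the pipeline's plumbing and learning
behavior can be tested offline:

* **Accelerometer signatures** are separable by construction: walking = 2 Hz
  oscillation of amplitude 3 m/s²; running = 3 Hz, 6 m/s²; sitting, standing
  and lying differ in gravity orientation (with |mean a_z| kept below
  9 m/s² for sitting/standing so they never trip the on-table detector);
  on-table = clean (0, 0, 9.81) with σ = 0.05 m/s². Per-participant
  oscillation amplitudes vary by ±20 %.
* **Streams** follow the real cadences: accelerometer 32 Hz, phone light
  1 Hz, wearable probabilities every 7.5 s (Dirichlet-softened one-hots,
  concentration 20 — realistically soft without modeling a real wearable),
  appliance power every 15 s, event streams as events.
* **Activity semantics** drive the ambient channels: cooking opens the fridge
  and powers the cooking plate and hood, drink preparation runs the kettle or
  coffee machine, TV time powers the TV, showering/toileting happen in the
  bathroom/toilet with the light on, phone use emits app and screen events.
* **Self-report pathologies** are generated by `corrupt_labels()`: uniform
  boundary jitter, probabilistic merging of adjacent entries into multi-label
  entries, and dropped entries. Zero noise is the identity.
* **The default day** fixes two temporal dependencies on purpose: eating
  always directly follows preparing a meal, and under a location-only feature
  set eating and using the computer have *identical* instantaneous features
  (sitting in the living room). Only a model with temporal memory can
  separate them, which is what the LSTM-vs-baseline test measures. Segment
  durations are realistic per activity (1.5–8 min) with 15–30 s room
  transitions, giving ~50–70-minute sessions.

A green end-to-end test therefore establishes that the implementation learns
what is learnable in this stated world — location-anchored activities to
balanced accuracy ≥ 0.8 on held-out participants, order-dependent activities
better with the LSTM than without. It does **not** establish performance on
real recordings, where signatures overlap, the wearable model errs, and
labels lie; reproducing published real-data metrics requires the original
dataset and multi-hour training, which is documented as out of desk scale.

## Numerical choices and degenerate inputs

* Timestamps are seconds since session start as doubles; epoch-millisecond
  inputs are rebased by the reader. Duplicate timestamps keep the last sample
  (retransmission convention). Windows are half-open `[start, start + w)`
  everywhere, so edges are never double-counted; the window-count formula is
  guarded with a 1e-9 slack against floating-point division.
* Parameters initialize Glorot-uniform; the LSTM forget-gate bias starts
  at 1. All randomness (initialization, shuffling, augmentation, dropout,
  the flattening's cross-matching) flows through R's RNG, so a fixed seed
  reproduces training bit-for-bit on a single-threaded BLAS.
* Argmax ties break toward the earlier class in declared order; max-pooling
  ties route the gradient to the earlier time step.
* Probability rows are validated to sum to 1 within 1e-6; loss inputs
  containing NaN raise errors rather than propagating.
* Streams shorter than one window yield empty results (with a warning at
  session level), never errors; an all-running label set or an all-unlabeled
  window set raises an explicit error.

## Known limitations

* The networks run on the CPU in plain R. This is fine at the package's desk
  scale (thousands of windows) but a real 31-participant campaign at 350
  epochs would want a compiled backend.
* `hyperparam_search()` is random search, not model-based optimization; the
  trial log makes swapping in a smarter proposer straightforward.
* The usage-interval reconstruction inherits the platform quirks it is built
  on: phones that never emit `locked` events inflate usage, and participants
  who decline app logging contribute constant-zero phone-usage features.
* Gyroscope, magnetometer, proximity and keyboard-stroke features, humidity /
  tap-water / cupboard sensors, on-device deployment, and attention
  mechanisms are out of scope.
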