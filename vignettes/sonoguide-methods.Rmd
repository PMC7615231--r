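---
title: "Joint probabilistic gaze and probe guidance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint probabilistic gaze and probe guidance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acquiring a fetal biometric standard plane with a handheld ultrasound probe
is a two-handed, two-eyed skill: the sonographer reads the image, shifts
their gaze between anatomical structures, and steers the probe toward the
target orientation, each signal informing the other. `sonoguide` models the
two decision processes jointly: given synchronized streams of video-frame
features, 2-D gaze points, and probe orientations (unit quaternions from an
IMU) sampled at 6 Hz, it predicts probability distributions over the *next*
gaze movement and the *next* probe rotation.

Four guidance policies are supported, combined pairwise (one gaze + one
probe policy per model):

* **OG** — one-step gaze shift: the displacement s_t = g_t − g_{t−1} of
  the normalized gaze point, modeled as a bivariate Gaussian
  (mean, two standard deviations, correlation: 5 head outputs).
* **MG** — multi-step gaze centers: gaze points in a sliding window of
  F = 5 frames (about 1 s) are clustered into at most L = 3 fixation
  centers; the per-center displacement over F frames is modeled as an
  L-component bivariate Gaussian mixture (6L head outputs, including the
  component-weight logits).
* **OP** — one-step probe rotation r_t = q*_{t−1} q_t, modeled as a 4-D
  Gaussian over quaternion components (4 mean + 10 Cholesky entries = 14
  head outputs).
* **SP** — rotation to the standard plane, r_t = q*_{t−1} q_T against the
  fixed target orientation q_T; same 14-dimensional parameterization.

SP+MG (both global policies, with no local step action for imitation) is
rejected at configuration time. Probabilistic outputs matter here: scanning
styles differ between and within sonographers, so the model predicts
densities, draws 100 trajectories, and averages them into a point guidance
signal, rather than committing to a single fixed path.

## Architecture

Each frame contributes three modality vectors: a 1,920-channel image
representation (a 640-channel 7×9 encoder feature map, average-pooled to
640×1×3 and flattened), the 2-D gaze shift, and the 4-D rotation. Each is
embedded to 128 channels by an FC → batch-norm → ReLU block. A 3-node graph
over (image, gaze, probe) carries an adaptive adjacency A = A^soft + M:
the soft term scores pairs of embeddings through two 256-dimensional linear
projections (softmax-normalized per row), and M is an unconstrained
learnable 3×3 mask initialized at zero so training starts from the pure
feature-similarity graph. The mask is a single parameter shared across
time steps — nothing in the model conditions it on t, so a per-step mask
would have no mechanism to differ. Messages into the gaze and probe streams are
spatial graph convolutions with the sigmoid *inside* the sum over source
nodes — each message channel lies in (0, 3) — with a separate input kernel
per GRU gate. Both streams run a GRU with 128 hidden channels whose input
transforms are these graph messages; each stream keeps its own recurrent
kernels and biases (nothing suggests the two heterogeneous signals should
share them), and the image node carries no recurrent state of its own.

The two hidden states are coupled by a bidirectional pathway with
channel-wise weights α (gaze) and β (probe), squashed by a sigmoid from
free parameters initialized at 0 (so both streams start half-coupled):

h^s_t = α(1−z^s)⊙h^s_{t−1} + αz^s⊙h̃^s + (1−α)z^r⊙h^s_{t−1} + (1−α)(1−z^r)⊙h̃^s

and the probe update is the exact mirror (s ↔ r, α ↔ β). For every channel
the coefficients on (h_{t−1}, h̃) sum to exactly 1, and α = 1 recovers the
standard GRU update; the mirrored form is the only symmetric completion
that preserves this convex-combination identity, which is why we use it.
With the pathway disabled (ablation switch `bidirectional = FALSE`) each
stream reduces to an independent graph-convolutional GRU, identical to
forcing α = β = 1.

A single linear head per stream emits the raw density parameters. Squashing
transforms are a design choice (the distributions are given, the transforms
are not): means of gaze shifts through sigmoid(x) − 0.5 so they stay on the
normalized screen; standard deviations through exp; correlations through
tanh; mixture weights through softmax; the 4-D covariance through a
Cholesky factor with softplus diagonal (floored at 1e-4). The quaternion
mean is *not* hard-normalized: unit norm is encouraged only by the training
prior η(1 − ‖μ‖)², and normalization is applied only when a sampled or
averaged prediction is composed with an orientation.

## Training objective and conventions

The loss sums over prediction steps t ∈ [t0, T]:

L = Σ_t ( −λ_s log P_s − λ_r log P_r + η(1 − ‖μ^r_t‖)² ),

with λ_s = λ_r = 1 (the two likelihoods share a scale) and η = 50 (the
prior is a hard constraint relative to them). Training is teacher-forced:
ground-truth gaze shifts and rotations are the inputs at every step, and
the prediction for step t is produced from inputs up to t − 1, so targets
never leak. Windows of 32 continuous frames are cut at random from each
sequence every epoch; the warm-up index t0 = 6 (1 s at 6 Hz) gives the
recurrence time to observe before predictions count. Under MG, gaze targets
exist only where a full F-frame window precedes both endpoints of the
center displacement (t ≥ t0 + F on an unbroken trace); other steps are
masked out of the gaze term.

Quaternion conventions: Hamilton product, scalar-first components, and
canonical sign (q_w ≥ 0, ties broken by the first nonzero component)
applied to all relative-rotation inputs and targets, so the double cover
never flips a regression target mid-sequence. Angles are in degrees
throughout evaluation.

Cross-window fixation-center correspondence for MG is obtained by seeding:
the first window of a sequence is clustered to the exactly optimal
partition (windows are five points, so enumeration is cheap), and every
subsequent window runs Lloyd iterations seeded from the previous centers,
so index l refers to the same fixation across windows. Sorting or optimal
assignment were the alternatives; seeding was chosen because it is the
only scheme that is stable when two centers approach each other.

### Optimization

AdamW (decoupled weight decay 1e-4) with the stepwise schedule:
learning rate 0.001 multiplied by 0.01 every 8 epochs as the package
default. Optional global gradient-norm clipping (`clip_norm`) is
available for probe-dominated training, where the likelihood
occasionally produces steep steps when a predicted covariance
momentarily undershoots a residual; it is off by default because
rescaling persistently large early gradients also distorts the adaptive
moment estimates that the spread parameters rely on to traverse their
log scale. An optional Polyak average of the parameters (`ema_decay`)
can damp iterate noise; it is likewise off by default. Two initialization choices
matter for short training budgets and are defaults of the model, chosen at
design time: output heads start near zero (weights scaled by 0.01) so the
initial densities sit at their decoded bias values, and the probe head's
mean bias starts at the identity rotation — the natural prior for 6 Hz
probe motion, and a starting point on the unit sphere so the norm prior
cannot amplify an arbitrary initial direction. Batch normalization in the
embedding blocks is computed over the pooled batch × time rows of each
training window (the same distribution its running statistics summarize
for evaluation), and the running estimates are warm-started at the first
batch's statistics.

The desk-scale experiments in the test suite and the acceptance script use
a higher learning rate (0.01) than the package default: with a few hundred
optimizer steps, an adaptive step of roughly the learning rate per
parameter must be able to traverse the 2–4 units of raw-parameter distance
that the log-scale spread parameters need, which 0.001 cannot do at that
scale. This is a property of the short schedules, decided from that
arithmetic; the default schedule is unchanged.

## The synthetic scan simulator

No public dataset of synchronized clinical video/gaze/probe streams
exists, so the package ships a simulator that reproduces the statistical
structure the model assumes, and all quantitative claims in the test suite
are claims about this synthetic family:

* **Probe**: starts 30° from a uniformly random target orientation;
  each coarse step closes a constant fraction (default 8%) of the
  remaining geodesic — or a constant angular step in the `"fixed"`
  approach mode — perturbed by 0.5° (sd) of angular noise about a random
  axis. Within 10° (the fine stage) alternate steps back away by up to 1°,
  emulating the forward-and-backward refinements near the plane; with
  noise off, the last frame settles within 1° of the target.
* **Gaze**: a latent fixation index over 1–3 plane-specific anchor centers
  switches with probability 0.15 per frame; gaze is the current center
  plus isotropic jitter (sd 0.02 normalized units, about 6 px on a
  288-pixel-wide screen), clamped to the screen. Centers drift toward
  their anchors as the probe closes in.
* **Features**: a fixed, seeded random linear embedding of harmonic
  encodings of the angle-to-target, the plane one-hot, and the gaze
  position, plus Gaussian noise (sd 0.1). A linear probe recovers the
  angle from noiseless features with R² > 0.99, so the features are
  informative the way encoder output would be.

Sequence defaults are 60 frames (10 s at 6 Hz). One global seed fans out
to per-sequence seeds through a counter, so any sequence is reproducible
alone. What the simulator does **not** model: real anatomy and speckle,
fetal motion, sonographer-specific scanpath idiosyncrasies, probe
translation, or freeze/annotation events. Tests passing on this family
show the machinery is correct and identifiable under the model's own
assumptions — not that clinical performance is reproduced.

## Evaluation

Probe guidance is scored by rotation direction: a predicted step counts as
correct if applying it does not increase the angular distance to the
guidance target (the next orientation under OP, the plane under SP) — a
non-strict rule, so the identity step is never wrong. Frames are staged by
the angle to the standard plane (coarse > 10° ≥ fine) and binned in
10°-wide bins over 0–30°. The continuation baseline reuses the previous
true rotation and is exactly right on noiseless monotone approaches. Gaze
is scored in pixels (ℓ2 after de-normalization), with a best-of-N variant
over the sampled trajectories, and by five saliency metrics comparing the
rendered predicted density against an empirical map of the real gaze
points (sum of 8-px Gaussians — roughly 1° of visual angle — normalized to
unit mass): SIM (histogram intersection), CC (Pearson), KLD (target in the
numerator, prediction in the denominator, ε = 1e-7, the saliency-benchmark
convention), AUC-Judd (thresholds at fixation saliency values; fraction of
all pixels above threshold as the false-positive rate), and NSS (z-scored
map averaged at fixations). Fixations are every gaze sample in the
trailing F-frame window of the evaluated step. Per-sequence scores average
frames within a stage; summaries report mean ± sd across sequences.

## Experiment sizes

The packaged experiments run at desk scale on one CPU. Distribution
recovery trains the full-width model on 200 simulated random-walk
sequences for 250 optimizer steps. The probe-guidance experiment uses
noiseless fixed-step approaches with 32-frame sequences equal to the
training window — so training clips and evaluation rollouts see the same
input distribution and every clip contains coarse-stage frames — and a
width-reduced configuration (32 embedding/hidden channels, 64 projection,
64 feature channels; the full-width architecture is exercised by the
structural checks) on 500 sequences for about 1,000 steps with gradient
clipping and a 0.3-factor annealing schedule. The seed-sensitivity
harness trains three smaller models (30 sequences each) under different
initialization seeds on fixed data and reports the across-seed standard
deviations of direction accuracy and gaze error. These sizes were chosen
so the full suite runs in minutes while each experiment still has the
statistical room its check needs (e.g., recovery tolerances are several
times the standard error at those sample sizes).

## Known limitations

* The frame encoder contract (640×7×9 → 1,920 pooled channels) is
  satisfied by a lightweight randomly initialized test backbone; no
  pretrained classifier weights ship with the package, and the image
  pathway therefore carries less structure than a pretrained encoder
  would.
* Densities are Gaussian or Gaussian mixtures by construction; heavier
  tailed gaze behavior (blinks, off-screen excursions) is handled only by
  boundary clamping.
* The bidirectional pathway weights are global per channel, not
  input-conditioned.
* Batch-norm evaluation statistics are estimated from training batches;
  models evaluated without any training carry warm-start placeholders and
  should not be interpreted quantitatively.
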