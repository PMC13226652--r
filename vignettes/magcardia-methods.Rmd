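---
title: "Methods: self-supervised representation learning for multichannel magnetocardiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised representation learning for multichannel magnetocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Magnetocardiography (MCG) records the magnetic field generated by myocardial
currents with a planar array of magnetometers above the chest — here 64
channels measuring the normal field component (Bz) at 500 Hz. The signal is
high-dimensional and the clinically interesting structure (regional
repolarisation heterogeneity, global ventricular function, latent atrial
substrate) is distributed across channels and cardiac phases, while labels
are scarce. `magcardia` implements a complete pipeline for this setting:

1. a current-dipole **field simulator** that generates labelled 64-channel
   cohorts with controllable class effects and noise,
2. **preprocessing** (10-s segmentation, zero-phase 0.5 Hz Butterworth
   high-pass, 50 Hz notch),
3. **quality control** by a beat-aligned SVD signal-to-noise metric with the
   "mean SNR < 5 dB is excluded" rule,
4. SimCLR-style **contrastive pretraining** (NT-Xent, temperature 0.1) of a
   temporal convolutional encoder under strong stochastic augmentations,
5. **probing**: shallow task heads with a frozen-encoder warm-up, joint
   fine-tuning, patient-stratified cross-validation and patient-level
   metrics, plus a supervised end-to-end baseline, and
6. **Grad-CAM attribution** in time (beat-aligned) and space (sensor array).

Real clinical MCG cohorts are not publicly available, so everything here is
exercised on the bundled simulator; the tests are property-based (oracle
agreement, invariances, controlled-recovery experiments), not reproductions
of clinical effect sizes.

# The field simulator

## Forward model

The elementary generator is a free-space current dipole: a moment
$\mathbf p$ (A·m) at $\mathbf r_0$ produces
$\mathbf B(\mathbf r)=\frac{\mu_0}{4\pi}\,
\frac{\mathbf p\times(\mathbf r-\mathbf r_0)}{|\mathbf r-\mathbf r_0|^3}$,
of which each sensor reads the z-component. Volume currents are omitted: for
a horizontally layered conductor the normal field component is dominated by
the primary currents, which is precisely the regime that motivates measuring
Bz. A consequence worth knowing is that the z-component of the moment is
invisible in Bz, so the simulated moment rotates in the sensor plane.

The sensor array is four concentric rings of 16 magnetometers at radii
3.5/7/10.5/14 cm (alternate rings rotated half a step), standoff 1 cm —
a plausible anterior-thorax coverage for a fixed circular grid; the layout is
fully configurable. The main source sits 6 cm below the array centre.

## Cardiac dynamics

One beat is a sum of Gaussian bumps in beat phase
$\theta\in[-\pi,\pi)$ (P, Q, R, S, T), each with its own amplitude, phase
centre, width, and in-plane moment direction — the classic dynamical-ECG
construction carried over to a rotating magnetic dipole. The R peak (at
$\theta=0$) is scaled to 20 µA·m, which yields fields of roughly 100–200 pT
at 1 cm standoff, the typical MCG range; the package otherwise treats
amplitude as arbitrary-but-consistent units (pT) because the learning
pipeline normalises per segment anyway. RR intervals are Gaussian
(default mean 0.85 s, SD 0.05 s) truncated at ±3 SD so beats stay ordered.
Ground-truth R-peak sample indices are stored for validation.

## Class effects

Each effect is parameterised by a non-negative `effect_size`; at 0 the
generator is bit-identical to the control path on the same seed (all classes
consume identical random draws), which makes matched-seed contrasts exact:

* **Coronary territory (cad_lad / cad_lcx / cad_rca)** — a secondary dipole
  displaced 3.5–4.5 cm towards the anterior-septal (+y), lateral (+x) or
  inferior (−y) sector, active in the ST–T phase (Gaussian bump centred at
  $\theta=1.05$ rad, width 0.35 rad, i.e. roughly 80–280 ms after the
  R peak at 70 bpm). At `effect_size = 1` its amplitude is 0.6 µA·m, ~30% of
  the T-wave moment; the "strong" benchmark setting of 3 makes it comparable
  to the T wave itself.
* **Reduced ejection fraction (low_ef)** — QRS amplitudes scaled by
  $\max(1-0.15e,\,0.2)$ and QRS widths by $1+0.15e$.
* **AF substrate (af_substrate)** — P-wave prolongation ($\times(1+0.2e)$),
  a duplicated late atrial bump, and per-beat log-normal jitter of P
  amplitude and width.

Noise comprises per-channel white Gaussian noise (default 0.5 pT), slow
sinusoidal baseline drift at 0.12/0.31 Hz (default 5 pT), 50 Hz line
interference (default 2 pT), and channel dropout (default probability 0.03)
— dropped channels are zeroed and flagged, never removed, so array geometry
is preserved.

## Inter-subject variability

Real cohorts differ strongly between subjects, and that variability is not
cosmetic: instance-discriminative pretraining aligns with cardiac morphology
only when patients actually differ in morphology. The generator therefore
draws, per subject (before any class effect, on a stream shared by all
classes): log-normal per-wave amplitude (15%) and width (10%) multipliers,
±10° moment-direction jitter, a 20% overall dipole-strength factor, an 8%
heart-rate factor, and ~1 cm heart-position jitter. `subject_variability`
scales all of these; 0 gives the deterministic reference morphology used by
the forward-model oracle tests. Without it, simulated patients are clones
and the only patient-identifying information is nuisance (dead-channel
patterns, noise idiosyncrasies) — a degenerate regime for any
self-supervised objective.

## What the simulator does not emulate

No torso conduction or anatomically realistic source geometry; no
respiration or movement artefacts; no sensor cross-talk or calibration
drift; no active arrhythmia (the AF class is a sinus-rhythm substrate
proxy); class effects are low-dimensional and much cleaner than clinical
disease. Passing the recovery experiments therefore shows the pipeline can
learn and localise the kind of spatio-temporal structure these conditions
imprint — it says nothing about clinical effect sizes.

# Preprocessing

Recordings are segmented first (non-overlapping 10-s windows, trailing
remainder discarded), then filtered per segment, keeping segments
independent. The chain is a 5th-order Butterworth high-pass at 0.5 Hz
followed by a second-order notch at 50 Hz (quality factor 30), both
zero-phase.

**Numerical choice — exact zero-phase application.** The designed filters'
squared magnitude response $|H(\omega)|^2$ is applied in the frequency
domain on reflect-padded windows (1000 samples of point-symmetric padding,
outer half tapered to the series mean so the DFT sees a continuous circular
boundary). This is the ideal forward–backward response: recursive
application of the 0.5 Hz high-pass is numerically fragile because its poles
sit at radius ≈ 0.997 and the start-up transient spans seconds. The
frequency-domain form gives exact DC rejection, exact linearity and exact
zero phase; the price is an edge-leakage band of roughly one second at each
window end where amplitudes can deviate by a few percent (the tests measure
signal-level properties in the window interior; the designed-response checks
carry the 1% passband and ≥40 dB notch contracts).

All-zero (missing) channels pass through untouched and are excluded from
per-channel statistics downstream.

# Quality control

R peaks are detected on the RMS trace across valid channels after a 5–30 Hz
zero-phase band-pass (robust to the per-channel polarity of magnetic field
maps), thresholded at 0.5× the rolling 2-s maximum, with a 200 ms refractory
period, then snapped to the nearby wide-band RMS maximum (±50 ms) for sample
accuracy. Segments with fewer than two detectable beats fail QC outright.

Beats are stacked in fixed windows (150 ms before to 450 ms after the
R peak; 300 samples). Per channel, the beat matrix is reconstructed from its
top-k singular triplets (k = 3 by default — dominant beat morphology plus
slow modulation; clamped to `n_beats − 1`); the noise is the residual, and

$$\mathrm{SNR} = 10\log_{10}\frac{\overline{\text{recon}^2}}
{\overline{(\text{residual})^2}}\ \text{dB},$$

capped at +80 dB when the residual underflows. "Signal" is the low-rank
reconstruction itself, the complement of the residual-defined noise. The
segment score is the mean over valid channels with complete beats, and the
exclusion rule is *mean SNR < 5 dB* (a segment at exactly 5 is kept). The
threshold's unit (dB, base-10, factor 10) is explicit in the configuration.

# Augmentations

Three stochastic views, applied in order with independent draws per view:

1. **Additive Gaussian noise** with per-channel SD `α · sd(channel)`
   (default α = 1 — deliberately strong, so matching views requires robust
   morphology rather than pixel identity).
2. **Channel dropout**: `round(0.10 · n_valid)` valid channels (ties-to-even,
   minimum 1) replaced entirely by noise from their own distribution —
   Gaussian with the channel's empirical mean and SD by default, a bootstrap
   resample behind a flag.
3. **Simulated sensor dropout**: 5% of valid channels zeroed per view.
   Recordings carry per-session dead-channel patterns; left stable across
   views, that pattern is a perfectly augmentation-invariant fingerprint of
   the recording, and the contrastive task will happily use it instead of
   morphology. Randomising the zero pattern between views enforces the
   missing-sensor invariance the augmentation suite is meant to provide.
4. **Per-channel temporal masking**: a contiguous run of length
   `L ~ Uniform{0..⌊0.75·T⌋}` starting at `s ~ Uniform{0..T−L}` replaced by
   the channel's pre-mask mean (maximum-entropy reading of "up to 75%").

Invalid channels are never selected for dropout and receive no noise; the
same channel may be hit by dropout and masking (independent draws). Every
transform is individually toggleable and the whole pair generation is
deterministic given a seed.

# Encoder and contrastive objective

## Architecture

Four residual blocks of 1-D convolutions over time; all input channels
enter every convolution as feature maps, so inter-channel field structure is
mixed at every layer, while convolution happens only along time. Each block
is `conv(k) + 1×1 projection skip → batch norm → ReLU → stride-2 average
pooling`; global average pooling over time, another normalisation and a
linear map produce the embedding. The full-scale configuration uses widths
32/64/128/128, kernel 15 and a 128-dimensional embedding; the first-class
desk variant (`encoder_config_desk()`) uses widths 8/16/32/64, kernels
5/9/9/9, a stride-2 first convolution and a 64-dimensional embedding. The
last block is kept comparatively wide because the globally pooled features
are the representation bottleneck: how reliably class structure survives
(random or learned) features scales strongly with the pooled-layer width.
The stride-2 entry halves the temporal resolution at the input — ample for
cardiac morphology at 500 Hz — and roughly halves the arithmetic cost;
convolutions in the desk variant run in single precision (~1e-6 relative
rounding; the small analytically-checked configurations stay in double
precision).

**Normalisation.** Affine-free batch normalisation follows every block
(per feature map, over time × batch) and the global pooling (per feature,
over the batch). It serves two measured purposes: per-block normalisation
keeps activations well-scaled over the short optimisation schedules this
package runs, and pooled-feature centring removes the dominant common
component of GAP'd ReLU features that otherwise starts all pairwise cosine
similarities near 1 and parks NT-Xent on its symmetric plateau — this is
what batch normalisation contributes inside standard SimCLR encoders. Batch
statistics drive contrastive pretraining; afterwards all statistics are
recalibrated exactly over the training segments (running statistics lag the
drifting feature distribution over short schedules) and frozen for
supervised phases and inference, so embeddings are deterministic per
segment. Re-estimating statistics from small fine-tuning batches measurably
destroys even training-set accuracy, hence the freeze.

**Batch composition.** Pretraining batches contain at most one segment per
patient. In-batch negatives then always come from other patients, as they
almost surely would in a large cohort; with few patients and several
segments each, uniform batches would force the representation to separate a
patient's own segments from each other, penalising exactly the stable
morphology the objective is meant to promote.

Inputs are normalised per segment by the global standard deviation, so the
encoder cannot rely on absolute field amplitude.

## NT-Xent pretraining

Two augmented views of each segment pass through the shared encoder and a
2-layer projection head (D→D→proj, SimCLR convention; embeddings are taken
*before* the head, and a no-head mode exists). With L2-normalised
projections $z$, temperature $\tau = 0.1$, partner $j(i)$ and batch size
$B$ (so $2B$ anchors):

$$\mathcal L = \frac1{2B}\sum_i -\log
\frac{\exp(\cos(z_i,z_{j(i)})/\tau)}
{\sum_{k\ne i}\exp(\cos(z_i,z_k)/\tau)}.$$

Optimisation is AdamW (initial learning rate 1e-3, decoupled weight decay
1e-4) with cosine decay to 1% of the initial rate over the schedule;
reference defaults are 100 epochs at batch size 32, single process. One
master seed derives independent streams for weight initialisation, data
order and augmentation, making runs bit-reproducible.

# Probing protocol

Task heads are `dropout(0.2) → 64-unit dense layer with swish activation →
sigmoid`, attached to the shared encoder; heads per task are trained
independently. Each patient-stratified fold (every patient in exactly one
fold; per-fold positive counts within one patient of the global proportion)
runs:

1. **Warm-up** (5 epochs): head only, encoder frozen — asserted by a
   parameter checksum; training embeddings are computed once. A frozen
   per-dimension standardiser of the embeddings (training-split statistics)
   conditions the head's optimisation and is absorbed into the head's first
   layer afterwards, so saved heads operate on raw embeddings.
2. **Joint fine-tuning** (30 epochs at full scale; the synthetic benchmark
   uses 15): encoder and head under Adam. The fine-tuning learning rate is
   not part of the reference recipe; the defaults are 1e-3 for the joint
   phase (a smaller rate leaves the encoder effectively frozen over the few
   dozen steps of a desk-scale schedule) and 1e-2 for the head-only warm-up
   (a freshly initialised shallow head on frozen features tolerates and
   needs the larger rate).

The loss is class-frequency-weighted binary cross-entropy
(`Σ wᵢℓᵢ / Σ wᵢ`, weights inverse to class frequency, normalised to mean 1).
Validation segments are scored in inference mode, aggregated per patient by
the arithmetic mean (median behind an option), and metrics are computed at a
fixed 0.5 operating point — deliberately not tuned on validation data. AUC
is the rank statistic with half credit for ties. Tables report the fold mean
with a 95% t-interval across folds; patient-bootstrap ROC bands are
available via `roc_points()` on resampled scores.

The supervised baseline trains the identical encoder–head architecture from
random initialisation with the supervised objective only, no frozen warm-up,
matching the total epoch budget.

**What self-supervision does and does not buy at desk scale.** The bundled
benchmark exposes both sides honestly. In the low-label regime (few labelled
patients, more unlabelled ones) the SSL-then-probe path reaches a higher
patient-level AUC than the supervised baseline — the directional claim the
test suite checks. With *all* patients labelled, however, short pretraining
schedules (tens of optimisation steps over a couple of hundred segments) are
a liability: the instance-discrimination task is already solvable from a few
strong subject-identity dimensions (overall amplitude, heart rate, axis), so
the convolutional features compress onto those and the class-carrying ST–T
direction — redundant for telling patients apart — is partly dropped; the
short fine-tuning phase cannot rebuild convolutional features from that
starting point, while the same architecture trained supervised end-to-end
learns the task directly. This mirrors the known scale-dependence of
instance-discriminative objectives: their feature richness comes from large
instance counts, and no hyperparameter of the small regime substitutes for
scale. Clinical AUC magnitudes are out of scope by construction.

# Attribution

Grad-CAM runs at the deepest convolutional block (configurable): feature
maps are weighted by their time-averaged gradients of the head logit,
summed, rectified, and linearly upsampled to the 5000-sample segment.
Temporal profiles are aligned to R peaks (same −150/+450 ms window as QC)
and averaged over validation segments, then max-normalised.

Grad-CAM's map lives after channel mixing, so it cannot be resolved per
sensor. Per-channel scores instead use time-summed |gradient × input| at the
input tensor — the minimal input-resolution attribution consistent with the
model, zero for invalid channels by construction; a saliency-only variant
would drop the `× input` factor. Channel scores are projected onto the
sensor coordinates; the importance-weighted centroid summarises the spatial
focus, and a territory "hit" means the centroid lies within ±60° of the
territory's displacement direction at a non-degenerate radius.

# Containers, configuration, CLI

A cohort is one hierarchical container file (RDS-serialised) with
per-patient groups (signal, validity mask, R peaks, labels), the geometry
table, acquisition attributes and provenance (seed, config hash, package
version); reads validate the schema and name missing fields. A
reporting-checklist validator maps thirteen minimum-reporting items for MCG
studies (sensor system, field components, array layout, standoff,
positioning, shielding, noise conditions, recording protocol,
synchronisation, preprocessing, signal format, labels, validation design) to
presence/validity checks on the container metadata. The `magcardia`
executable (a thin Rscript over `cli_dispatch()`, installed under
`inst/cli/`) exposes `simulate | preprocess | qc | pretrain | probe |
attribute | validate`, takes YAML configs (unknown keys are errors naming
the key), and writes a JSON manifest next to every output.

# Problem sizes and reproducibility

The bundled benchmark uses 60 patients (30/30) at 30 s per patient (three
10-s segments each), the desk encoder, 10 pretraining epochs, and 5 warm-up
+ 15 joint probing epochs per fold — sizes chosen so the complete recovery,
permutation-control, low-label-comparison and attribution experiments run
comfortably on a single CPU while still exercising every moving part at
realistic signal dimensions (64 × 5000). At this cohort size patient-level
AUC estimates are coarse (six validation patients per fold) and outcomes
vary substantially across cohort and training seeds; single-run numbers
should be read with that granularity in mind. Unit tests use an 8-channel,
200-sample encoder configuration for mechanics (finite-difference gradient
checks, determinism, checkpoint round-trips) where signal realism is
irrelevant.

Every stochastic component is seed-controlled: the simulator derives
per-patient seeds from the cohort seed, pretraining derives independent
streams from its master seed, and fold assignment, head initialisation and
batch order derive from the probe seed. Two runs from the same seeds are
bit-identical end to end.

# Known limitations

* The simulator's class effects are deliberately low-dimensional; none of
  the acceptance results transfer to clinical data.
* The frequency-domain zero-phase filters have a ~1 s edge band per window
  with percent-level amplitude error; beats at window edges also carry this.
* Batch-normalisation statistics frozen during fine-tuning mean the encoder
  cannot adapt its feature scaling to a new label distribution — acceptable
  for probing, but a deliberate trade-off.
* The supervised baseline shares the SSL path's schedule and learning rate
  rather than being tuned separately; the comparison mirrors the reference
  protocol, not a best-possible supervised model.
* Single process, single device; no mixed precision beyond the optional
  single-precision convolutions.
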