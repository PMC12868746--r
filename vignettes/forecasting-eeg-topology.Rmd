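---
title: "Forecasting the topology of EEG rhythms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting the topology of EEG rhythms: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

topoforecast turns multi-channel EEG into sequences of *high-order
persistence images* — fixed-size summaries of the loops (H1) and voids (H2)
in the delay-embedded signal — and learns to forecast the next window's
image with an adversarially trained generator built from graph-attention
layers, an LSTM, and a sigmoid head. This vignette is the package's own
account of the models involved, the parameters that matter, and the design
choices made where the problem was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## From signal to image

Each recording is band-passed into the five classical bands (Delta 1–3,
Theta 4–7, Alpha 8–12, Beta 13–30, Gamma 31–49 Hz) with a zero-phase
order-4 Butterworth filter (forward–backward, so the effective roll-off is
doubled and band-edge attenuation one octave out comfortably exceeds
20 dB). Channels are averaged into one analysis series — filtering and
averaging commute, so the package averages first for speed; a single
channel can be selected instead. The series is cut into consecutive
non-overlapping 4-s windows.

Each window is converted to a point cloud by Takens delay embedding
(defaults: dimension 3, delay 4 samples; a mutual-information-based delay
selector is available). At the default 250 Hz a 4-s window has 1000
samples, giving 992 points, which are subsampled (seeded, uniform) before
the Vietoris–Rips filtration because the reduction cost grows steeply with
cloud size. Persistence is computed over Z/2 by standard boundary-matrix
reduction (compiled code), with the *enclosing radius* as the default
filtration cutoff — beyond it no new finite feature above dimension 0 can
appear. An independent pure-R implementation (`brute_force_persistence`,
capped at 12 points) exists solely to validate the fast path
feature-for-feature in the tests.

Diagrams are vectorized as persistence images: finite features of the
configured homology dimensions (default H1 + H2, the "high-order" image)
are mapped to (birth, persistence) coordinates, smoothed with a Gaussian
kernel (sd defaults to 5% of the persistence-axis range, standard
persistence-image practice), weighted linearly in persistence, and
accumulated on an R × R grid (R = 100 by default). Two choices matter for
forecasting:

* **Axis ranges are pooled per band** over the input set rather than fit
  per image, so images are comparable across windows and subjects — a
  per-image range would silently renormalize away the very drift the
  forecaster should learn.
* **Each image is min–max normalized to [0, 1]**, matching the range of
  the generator's sigmoid output.

## The forecaster

The generator consumes a persistence image as a pixel graph: one node per
pixel in row-major order, 8-neighbourhood grid adjacency (4-neighbourhood
optional) plus self-loops, with pixel intensity as the single input
feature. The graph is structure-only; nothing about it depends on pixel
values. Self-loops guarantee every softmax neighbourhood is non-empty.

Two graph-attention layers follow. For head $k$, edge $(i, j)$ receives a
raw score $e_{ij} = a(W^k h_i, W^k h_j)$ (a learned linear form on the
transformed pair), scores pass through a LeakyReLU (slope 0.2) and are
softmax-normalized over each node's neighbourhood, and node outputs are
the **average over the K heads** of the attention-weighted sums
$\sigma\!\big(\tfrac1K \sum_k \sum_{j \in N_i} a^k_{ij} W^k h_j\big)$.
The first layer uses K = 8 heads (per-head width 8), the second a single
head back to one feature per node, so a 100 × 100 image is still a
100 × 100 grid after attention. Head *averaging* (rather than the more
common concatenation) is deliberate: it is the aggregation the model's
defining equation prescribes. The inter-layer nonlinearity is ELU
(configurable); output range control is delegated to the final sigmoid.
During training, dropout (default 0.6; the source material gives both 0.6
and 0.5, and the architecture description wins) is applied to the first
layer's input features and attention coefficients.

The attended grid is flattened row-major into an $R^2 \times 1$ sequence
and fed to an LSTM *with scalar inputs and hidden size 5* — i.e. the LSTM
steps over the 10,000 pixels, not over time windows. This is the only
reading consistent with the stated "10,000 × 1 into the LSTM" data flow; a
temporal variant (sequence over past windows) would be a different model.
The last hidden state (5 numbers) passes through an affine map to $R^2$
logits and a sigmoid, and is reshaped to R × R. The tiny bottleneck is a
strong regularizer: the generator must summarize where the image mass is
and re-render it.

The discriminator is two fully connected sigmoid layers
($Y = \mathrm{Sigmoid}(W V + b)$ per layer, 16 hidden units) on the
flattened image, emitting the probability that an image is real.

## Training

Both players use RMSprop (ρ = 0.9) with binary cross-entropy losses, batch
size 32. Pretraining minimizes pixelwise BCE between predicted and true
next-window images at learning rate 0.01. Joint training at 0.001
alternates: the discriminator sees real targets (label 1) versus generated
images (label 0); the generator minimizes adversarial BCE toward label 1
*plus* the pixelwise reconstruction BCE (weight 1 by default) — a pure
adversarial loss cannot anchor next-window *content*. Because a
fully-connected discriminator separates real from generated images far
faster than this generator can catch up, joint training includes a balance
gate: discriminator updates are skipped while its loss is below a floor
(default 0.35). This is the package's concrete form of the "gradient
balance monitoring" the training procedure calls for; without it the
discriminator wins immediately and the generator's loss diverges upward
instead of declining.

Splits are at the subject level (80/20, with 10% of train as validation),
never at the pair level, so no subject's windows straddle train and test.
Divergence (non-finite loss) aborts with a diagnostic rather than
continuing silently.

## Evaluation protocols

The pixelwise protocol binarizes each target image at the classification
threshold 0.4; predicted intensities act as scores. AUC uses the
Mann–Whitney formulation, AP is the step-interpolated area under the
precision–recall curve, MAP the mean AP over images, MAE the pixelwise
mean absolute error. Targets whose binarization is all-zero or all-one are
excluded from AUC/AP (they are ill-defined there) but still count toward
MAE. The choice of *what* AUC/MAP range over was genuinely open; the
pixelwise reading is primary because it uses the stated threshold and
needs nothing beyond the image pairs themselves.

The subject-level readout trains the generator on training-split patients
only and scores every held-out subject by the generator's reconstruction
BCE *divided by the identity baseline's BCE* (predicting the current image
for the next window). The normalization matters: raw reconstruction error
confounds class membership with how intrinsically variable a subject's
sequence is, and its sign flips between regimes; the ratio measures how
much of the subject's dynamics the trained model explains, and is
consistently lower for subjects from the trained class. AUC is reported
patient-positive over held-out subjects.

Ablation variants share the training harness: GAT-only keeps the attention
stack and replaces the LSTM tail with a shared per-node affine + sigmoid
(it can re-render but not re-locate mass); LSTM-only feeds the raw
flattened image to the LSTM (it can track but not denoise). Both have
fewer parameters than the full model. A caveat the tests make explicit:
removing the LSTM is catastrophic for forecasting, but removing the GAT
is nearly free at desk scale — the 5-unit LSTM bottleneck dominates, and
on bump-drift data the full model and the LSTM-only variant sit within a
fraction of a percent of each other in MAE, with the sign of the
difference at the mercy of training seeds. The package reports both
comparisons honestly rather than engineering data to manufacture a gap.

## Image-quality coefficients

The clinical module implements the score-supervised reading of "image
quality coefficients": a small CNN (two 3 × 3 conv + 2 × 2 max-pool
blocks, 16/32 channels, one hidden dense layer) is trained with Adam for a
fixed budget (500 rounds by default) to regress a clinical score from a
subject's persistence image; the trained model's per-sample outputs *are*
the coefficients, which are then correlated (Pearson, two-sided t
transform) with each clinical variable. This definition is knowingly
circular — the coefficients are fitted values — so their correlation with
the supervising score is biased upward; the package implements it as
specified and the tests treat it as a recovery property (a planted
relation is found), not as an unbiased inference. No multiple-testing
correction is applied by default, matching a raw per-cell report; a
Benjamini–Hochberg adjustment is one `p.adjust()` call away.

## The synthetic cohort

Real resting-state clinical EEG of the kind this pipeline targets is not
redistributable, so the package ships a seeded simulator. Each recording
sums, per band, a sinusoid at band-centre frequency with slow random
amplitude modulation (0.05–0.3 Hz, depth 0.5) plus band-passed Gaussian
noise, projected to all channels as one coherent source with small
per-channel gain and phase perturbations, plus independent white sensor
noise. Coherent projection is essential, not cosmetic: independent
per-channel phases would let channel averaging cancel the oscillation
(Rayleigh fading) and silently destroy any planted class effect.
Per-subject lognormal amplitude jitter (sd 0.2) makes subject summaries
vary, which the clinical module needs. Patients differ from controls by
additive per-band amplitude shifts; a PANSS-like total score is planted as
50 + slope × (subject's realized Theta amplitude) + noise, with positive
and negative subscores as fixed fractions (0.28, 0.23 — the approximate
subscore-to-total ratios of published cohort summaries).

What the simulator does *not* emulate: dipole geometry and volume
conduction beyond a gain/phase perturbation, artifacts (blinks, EMG),
non-stationary spectra, and any actual neuropathology — the class contrast
is a band-amplitude stand-in, not a claim about schizophrenia. Passing
tests therefore demonstrate that the pipeline recovers structure it is
able to represent, not that it diagnoses patients.

## Desk-scale study conditions

The test suite and acceptance script run everything end-to-end on one CPU,
at sizes chosen once as the package's scaled-down study conditions:
cohorts of 10 subjects per class, 40-s recordings at 250 Hz (10 windows of
4 s), Theta-band images at R = 20 from H1 with clouds subsampled to 40
points; 30 pretraining epochs and 100 joint epochs; ablations on simulated
image sequences (drifting bump, 30% pixel occlusion, 5 seeds); the
classification null over 20 seeded cohorts (a short training budget
suffices there — under class exchangeability the AUC is at chance for any
budget) and a planted Theta shift of +15 amplitude units for the power
run; 50 clinical-recovery replicates and 200 null replicates for the
correlation test's level. The full-resolution (R = 100, H1+H2,
200-point-cloud) configuration remains the default for real use.

## Numerical choices and degenerate inputs

* Attention scores are clamped to ±25 before exponentiation; softmax
  denominators are grouped sums over each node's edges, which self-loops
  keep non-empty. Sigmoids saturate safely; BCE probabilities are clamped
  to [1e-7, 1 − 1e-7].
* Zero-persistence pairs are discarded from diagrams; essential classes
  carry infinite death and never enter images. An empty eligible feature
  set yields the all-zero image, which min–max normalization leaves at
  zero.
* Rips tie-breaks (equal diameters) order simplices by dimension then
  vertex order; the resulting diagram multiset is tie-break-invariant,
  which is what the oracle-equivalence tests compare.
* The LSTM forget-gate bias starts at 1 (gates open), a standard
  initialization that avoids early memory washout; all other weights are
  Glorot-uniform from seeded streams. All randomness flows from one run
  seed through named substreams, so any stage is reproducible in
  isolation.
* `cohort_config()` rejects non-positive rates and durations not divisible
  by the window length; band definitions are validated against Nyquist.

## Known limitations

The Rips backend is exact but dense-filtration-based: it is comfortable at
the package's defaults (≤ 200 points, H1–H2 with the enclosing-radius
cutoff) but is not a substitute for state-of-the-art reduced-basis
implementations at thousands of points. The scalar-input LSTM reading of
the generator makes image forecasting tractable but means spatial context
enters only through the attention layers. The adversarial game is kept
stable by the balance gate rather than by tuned schedules; on very
different data the floor (0.35) may need revisiting. Finally, all
end-to-end claims are demonstrated on simulated cohorts; the package makes
no claim about real clinical recordings.
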