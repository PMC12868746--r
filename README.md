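# topoforecast

Adversarial forecasting of the topology of EEG rhythms.

`topoforecast` is for researchers who study resting-state EEG through the
lens of topological data analysis and want to model how that topology
*evolves*: it converts band-decomposed EEG windows into high-order
persistence images, trains a graph-attention + LSTM generator against a
fully connected discriminator to predict the next window's image, scores
the forecasts (pixelwise AUC / MAP / MAE), derives subject-level
classification readouts, and correlates CNN-based image-quality
coefficients with clinical severity scores. Because clinical EEG of this
kind is not redistributable, the package includes a seeded synthetic-EEG
cohort simulator with plantable class effects and clinical-score
relations, so the entire pipeline is testable end to end.

## The method

For each subject, band *b* ∈ {Delta 1–3, Theta 4–7, Alpha 8–12, Beta
13–30, Gamma 31–49 Hz} and 4-s window:

1. **Topology extraction.** The band-passed, channel-averaged window
   x₁…x_T is delay-embedded, point *i* = (x_i, x_{i+τ}, …,
   x_{i+(m−1)τ}) (defaults m = 3, τ = 4 samples); the Euclidean
   Vietoris–Rips filtration of the (subsampled) cloud yields a persistence
   diagram {(bᵢ, dᵢ, qᵢ)}; finite features with homology dimension q ≥ 1
   (loops and voids — the "high-order" part) are smoothed into an R × R
   persistence image in (birth, persistence) coordinates with a Gaussian
   kernel and linear persistence weighting, then min–max normalized to
   [0, 1].
2. **Forecasting.** The generator treats the image as a pixel graph
   (8-neighbourhood + self-loops) and applies two graph-attention layers —
   attention a_ij = softmax_j LeakyReLU(a(W h_i, W h_j)) with 8-head
   averaging, h′_i = σ((1/K) Σ_k Σ_{j∈N_i} a^k_ij W^k h_j) — then scans
   the flattened R² pixels with an LSTM (scalar inputs, hidden size 5) and
   renders the predicted next-window image from the last hidden state
   through an affine map and sigmoid. The discriminator,
   Y = Sigmoid(W·V + b) stacked twice, scores images as real or generated.
3. **Training.** RMSprop, binary cross-entropy; pretraining of the
   generator at learning rate 0.01, joint adversarial training at 0.001
   (generator loss = adversarial BCE + pixelwise reconstruction BCE),
   batch 32, subject-level 80/20 split.
4. **Evaluation.** Pixelwise protocol: target pixels binarized at 0.4,
   predicted intensities as scores; AUC (Mann–Whitney), MAP (mean area
   under the precision–recall curve), MAE. Subject-level readout: the
   generator's reconstruction error normalized by the identity baseline,
   AUC over held-out subjects. Clinical module: a small CNN regressor's
   per-sample outputs ("image quality coefficients") are Pearson-correlated
   with PANSS-like scores per band.

See `vignettes/forecasting-eeg-topology.Rmd` for assumptions, parameter
rationale, and known limitations.

## Worked example

A desk-scale run (4 subjects per class, 40 s at 250 Hz, Theta band,
20 × 20 images from H1):

```r
library(topoforecast)

cohort <- generate_cohort(cohort_config(n_subjects_per_class = 4,
                                        duration_s = 40, fs = 250,
                                        n_channels = 2, seed = 42))
seqs <- extract_pi_sequences(
  cohort, bands = "Theta",
  tda = tda_config(max_points = 40, max_hom_dim = 1, hom_dims = 1,
                   resolution = 20),
  seed = 1)
labels <- vapply(seqs, function(e) e$label, character(1))
pairs <- make_pairs(seqs[labels == "patient"])    # 9 pairs per subject
tconf <- training_config(seed = 7)

pre <- pretrain_generator(generator_state(20, seed = 3, dropout = 0.6),
                          pairs, tconf, epochs = 20)
adv <- adversarial_train(pre$gen, discriminator_state(20, seed = 4),
                         pairs, tconf, epochs = 30)
evaluate_prediction(adv$gen, pairs, tconf)
```

which prints

```
<eeg_cohort> 8 recordings (4 patient / 4 control), 40 s @ 250 Hz
<pi_pairs> 36 pairs, R = 20, 4 subjects
pretraining BCE, epoch 1 -> 0.679 ; epoch 20 -> 0.129
<evaluation_report> band Theta: AUC 0.782, MAP 0.049, MAE 0.0726 (36/36 pairs scored)
```

The pretraining loss falls by ~80% over 20 epochs; on this tiny training
set the forecasts rank true-bright pixels well above background
(AUC 0.78) with a mean absolute pixel error of about 0.07. MAP is low
here because each binarized 400-pixel target contains only a handful of
positives, so precision at the early ranks is noisy. `cohort$clinical`
holds the planted PANSS-like scores used by the clinical module:

```
  subject_id panss_total panss_positive panss_negative property
1 P01               63.8           18.0           15.1    13.0
2 P02               58.6           16.6           12.3     7.92
```

A command-line wrapper over the same functions is installed at
`inst/cli/topoforecast` (commands: `simulate`, `extract-pi`, `train`,
`evaluate`, `ablate`, `clinical-corr`, `full-run`), each reading a JSON
run configuration (`run_config()` / `save_run_config()`).

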