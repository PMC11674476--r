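---
title: "Dual-attention convolutional Bi-LSTM networks for EEG emotion decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DACB: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dacb)
```

## The model

DACB classifies emotional state from raw multichannel EEG. Its unit of
classification is a single timepoint: one length-$C$ vector of electrode
voltages ($C = 62$ electrodes in SEED-IV-style recordings, $C = 14$ in
DREAMER-style recordings). The network treats this channel vector as a
length-$C$ sequence of scalar features and extracts two complementary
representations in parallel:

* **Spatial branch** — a 1D convolution (64 filters, kernel 3, stride 1,
  same padding, ReLU) over the channel axis, non-overlapping max pooling
  (window 2), and squeeze-and-excitation (SE) channel attention. SE first
  *squeezes* each of the 64 feature maps to its global average
  $z_c = \frac{1}{W}\sum_{i=1}^{W} u_c(i)$, then *excites* through a
  two-layer bottleneck $s = \sigma(W_2\,\delta(W_1 z))$ with ELU
  ($\delta$) and sigmoid ($\sigma$) activations and reduction ratio
  $r = 8$, and finally rescales each map by its weight, $u_c \mapsto
  s_c u_c$. The result is flattened.
* **Temporal branch** — a bidirectional LSTM with 32 units per direction
  run across the channel sequence. Each direction applies the standard
  gated recurrence: forget, input and output gates through the logistic
  sigmoid, a tanh candidate, $C_t = f_t C_{t-1} + i_t \tilde C_t$ and
  $h_t = o_t \tanh C_t$. The default merge concatenates per-step forward
  and backward states, $[\overrightarrow{h}_t, \overleftarrow{h}_t]$,
  and flattens the sequence; a gated merge
  $\sigma(W_h[\overrightarrow{h}_t,\overleftarrow{h}_t]+b_h)$ is
  available as an option.

Both flattened branch vectors are linearly projected to a common width
(64) and stacked as a two-row value matrix $V$. A tanh-keyed dot-product
attention layer fuses them: keys $K = \tanh(V W^a)$, weights
$d = \mathrm{softmax}(q K^\top)$ with a learned query $q$, and output
$a = d V$. The attention weights are non-negative and sum to one, so the
fused vector is a convex combination of the two branch representations —
the network learns how much spatial versus sequential evidence to use.
The head is Dense(64, ReLU) → Dense(32, ReLU) → softmax over the classes.

Training minimizes categorical cross-entropy with Adam (learning rate
0.001, batch size 1024, seed 42 by default — DACB's reference training
protocol) with
seeded shuffling per epoch. All forward and backward passes are
implemented in this package; the bidirectional recurrence and the heavy
convolution/pooling stages run in compiled (RcppArmadillo) kernels, and
every layer has an independent plain-R reference implementation
(`conv1d_forward()`, `maxpool1d()`, `se_squeeze()`/`se_excite()`/
`se_scale()`, `lstm_step()`, `bilstm_forward()`, `dot_attention()`)
against which the batched path is tested.

## Sample construction and evaluation protocols

From each trial (channel × time matrix) a centred segment is extracted
(`extract_middle_segment()`, floor-centred start, 1000 timepoints by
default) and every timepoint becomes one training sample inheriting the
trial's label and subject (`slice_timepoint_samples()`); a 15-subject ×
24-clip corpus with 1000-point segments therefore yields 360,000 samples.
Channels are z-scored with statistics computed on the training side only
(`normalize_batches()`), guarding standard deviations by $10^{-8}$.

Two evaluation designs are provided:

* `run_single_split()` — subject-wise hold-out (12/3 subjects for the
  SEED-IV shape, 18/5 for DREAMER): no subject contributes samples to
  both sides.
* `run_kfold()` — 10-fold cross-validation with a seeded shuffle. The
  default `sample_shuffled` mode assigns individual timepoint samples to
  folds, matching protocols that shuffle all samples before folding; because
  adjacent timepoints of one trial are highly correlated, this lets
  near-duplicates of training samples appear in test folds.
  `trial_grouped` mode keeps whole trials together and is provided so
  users can quantify that leakage. Each fold re-initializes the model
  from a fold-derived seed and refits normalization statistics on its own
  training side.

`run_ablation()` trains the spatial-only (`block1_spatial_only`),
temporal-only (`block2_temporal_only`) and full variants on identical
fold assignments. In a single-branch variant the attention layer receives
a one-row value matrix and degenerates to the identity, and the absent
branch's parameters are simply not allocated.

`channel_contributions()` exports two attributions from a trained model:
the batch-averaged SE excitation both before the sigmoid (logits
$W_2\,\mathrm{ELU}(W_1 z)$, which may be negative) and after it (weights
in $(0,1)$), and a per-electrode occlusion score — the drop in accuracy
when an input channel is zeroed.

## The synthetic generator

Real SEED-IV and DREAMER recordings are permission-gated, so the package
ships a generator (`synth_spec()`, `generate_trialset()`) that emulates
their *sample structure*: subjects × clips, channel counts (62 or 14),
one 4-class label per trial or three independent 5-class ratings
(valence/arousal/dominance), balanced up to rounding. Each class $c$
carries a signature: a unit-norm channel-gain vector $g_c$ (pairwise
cosine similarity between classes below 0.9, enforced by redraw) and an
oscillation set. A trial is

$$X = g_c\, w_c(t)^\top + \varepsilon, \qquad
  w_c(t) = a_0 + \sum_{k=1}^{3} a_k \sin(2\pi f_k t + \phi_k),$$

with normalized frequencies $f_k \in [0.01, 0.15]$ cycles per timepoint
(1–19 Hz at a 128 Hz sampling rate — the classical EEG band range),
amplitudes $a_k \in [0.5, 1.5]$ scaled per oscillation group, and
i.i.d. Gaussian noise with variance set from the requested
signal-to-noise ratio, $\sigma^2 = \overline{\text{signal}^2}/\text{snr}$.
The baseline term $a_0 = 1.25\sum_k a_k$ keeps $w_c(t)$ bounded away from
zero: with per-timepoint sampling, a zero crossing of a pure sinusoid
mixture would yield samples containing no class information at all,
capping attainable accuracy regardless of model quality. The baseline
makes the instantaneous spatial pattern informative at every timepoint,
which is the regime the per-timepoint protocol presupposes.

For ablation studies the spec accepts `gain_groups` and `osc_groups`
assignments so that classes can *share* spatial or oscillatory
signatures: with gains shared in pairs and oscillations shared in the
transposed pairs, the class identity is the conjunction of a spatial and
an oscillatory property and neither alone determines the label.

What the generator deliberately does **not** emulate: 1/f spectra,
artifacts, volume conduction, inter-subject variability, rater
disagreement, or trial-specific idiosyncrasies. Two consequences matter
for interpreting results. First, synthetic benchmarks reaching ~100%
accuracy show that the implementation learns the structure it was given,
not that real EEG is this separable. Second, because trials of one class
differ only by noise, `sample_shuffled` and `trial_grouped`
cross-validation score alike here, whereas on real data the former is
expected to score higher through adjacent-timepoint leakage.

## Numerical and design choices

Several architecture details are underdetermined by DACB's layer listing
(layer types and widths only); this package's choices are:

* kernel 3, stride 1, same padding; pool 2 — the smallest standard
  receptive field, keeping the channel axis meaningful at $C = 14$;
* SE reduction $r = 8$ (64/8 = 8 bottleneck units);
* attention over the two *branch vectors* (a two-row value matrix) as the
  default reading of "importance of spatial and temporal features"; an
  alternative `position` mode treats every flattened feature as one
  attention position and applies the resulting weights as an elementwise
  reweighting (dimension-preserving, scaled by the position count);
* Bi-LSTM returns the full per-step sequence (concat merge) before
  flattening; the printed gated-merge equation is available via
  `bilstm_merge = "gated"`;
* ReLU after the convolution and both dense layers; the output layer is a
  dense softmax over the classes;
* Glorot-uniform initialization, zero biases except the LSTM forget-gate
  bias, initialized at 1 so early training does not flush the cell state;
* argmax ties break toward the lowest class index (determinism);
* macro averaging for multiclass precision/recall, F1 as the harmonic
  mean of the macro aggregates, and multiclass MCC as the macro average
  of per-class one-vs-rest binary MCC (the matrix-correlation
  generalization is available via `mcc_score(method = "multiclass")`);
  zero denominators contribute 0, never NaN;
* per-channel z-scoring with train-only statistics (population standard
  deviation, $\varepsilon = 10^{-8}$ guard).

The compiled gate kernels evaluate the logistic and tanh through a
branch-free, Padé-based exponential accurate to about one unit in the
last place, so they agree with the R reference implementations to
floating-point precision while vectorizing cleanly.

Everything is deterministic given the seeds: generation is a pure
function of the spec (the caller's RNG state is saved and restored),
training shuffles with per-epoch seeds derived from the training seed,
and each cross-validation fold derives its model seed from the master
seed, so any run is reproducible from its manifest.

## Benchmark scales

The test-suite and acceptance benchmarks use reduced problem sizes chosen
once as the package's desk-scale study conditions: the 62-channel
cross-validation benchmark uses 15 subjects × 24 clips with 28-point
segments (10,080 samples) at snr 25 and 4 training epochs; the ablation
study uses 5 subjects × 24 clips × 14 channels with 25-point segments
(3,000 samples) at snr 15, batch size 256 and 9 epochs, averaged over
three seeds. The smaller batch size in the ablation study gives all three
variants enough optimization steps on the small corpus to approach their
ceilings, which is where capacity differences — rather than optimization
noise — drive the comparison.

## Limitations

* Real-data readers for the MAT-file distributions of SEED-IV and DREAMER
  are not bundled (no MAT parser is available to this package);
  `read_trials()` documents the portable `synthetic_dir` layout to
  convert into.
* DACB's reported headline accuracies on the real datasets are not
  reproducible here: the data are permission-gated, and the per-timepoint
  sampling and shuffling protocol leaves room for adjacent-timepoint
  leakage that the package exposes (`trial_grouped` mode) rather than
  resolves.
* Under per-timepoint sampling both branches receive the identical input
  vector, so each single-branch variant is itself close to a universal
  approximator of the task; the full model's advantage in the synthetic
  ablation study is therefore a capacity- and ensemble-sized effect
  (about one accuracy point on seed-averaged means), not the large
  structural gap seen on real recordings, and individual seeds can order
  the variants either way.
* Training is CPU-bound and single-threaded by design; the reference
  150-epoch configuration on full-size corpora is feasible but slow, and
  the defaults here are meant for desk-scale experiments.
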