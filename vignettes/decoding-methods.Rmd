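---
title: "Decoding motor imagery with multi-scale fusion networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with multi-scale fusion networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates the
power of band-limited EEG rhythms (mu, ~8–13 Hz, and beta, ~14–30 Hz) over
sensorimotor cortex. A brain–computer interface decodes which movement was
imagined from a few seconds of multichannel EEG. The signals are noisy,
non-stationary and highly subject-specific, which is why modern decoders
combine several inductive biases rather than relying on one.

`mifuse` implements such a hybrid decoder end to end in R. An epoch
$X \in \mathbb{R}^{C \times T}$ ($C$ electrodes, $T$ samples) passes
through five stages:

1. **Spatiotemporal convolution (SC).** A temporal convolution with $F_1$
   kernels of width 16 (bias-free, 'same' padding) learns frequency-selective
   filters; a depthwise spatial convolution with kernel $(C, 1)$ and depth
   multiplier $D$ collapses the electrode axis into $F_2 = D F_1$ learned
   spatial patterns. Batch normalization, an ELU, average pooling of width 8
   and dropout follow, leaving a $(F_2, 1, T/8)$ map.
2. **Multi-branch separable convolution (MSC).** Three parallel
   depthwise-separable branches with kernels of 8, 16 and 32 samples
   (i.e. 0.25 s, 0.5 s and 1 s at the post-pooling rate) and filter counts
   $F_2/4$, $F_2/4$, $F_2/2$ capture short-, medium- and long-range temporal
   structure; their outputs are concatenated on the depth axis, normalized,
   pooled by 8 again and dropped out: $(F_2, 1, T/64)$.
3. **Multi-head self-attention (MSA).** The pooled sequence (length
   $T/64$, embedding $F_2$) is layer-normalized; each of $m = 8$ heads
   computes $Q = Y W^Q$, $K = Y W^K$, $V = Y W^V$ and
   $\mathrm{softmax}(QK^\top/\sqrt{d_h})V$ with attention dropout 0.3; heads
   are concatenated, projected by $W^o$ and passed through an ELU. Shapes
   are unchanged.
4. **Temporal convolutional network (TCN).** The MSC and MSA sequences are
   concatenated depth-wise (feature fusion, depth $2F_2$). Three overlapping
   sliding windows of the fused sequence pass through one shared TCN of
   $L = 2$ residual blocks, each holding two dilated causal convolutions
   (kernel $K_t = 4$, dilation $2^{i-1}$ in block $i$, bias-free) with batch
   norm, ELU and dropout 0.5. The receptive field,
   $\mathrm{RFS} = 1 + 2(K_t - 1)(2^L - 1) = 19$, exceeds the window length
   (13 for $T = 1000$), so the last time step sees the whole window. The
   three last-step vectors concatenate to a $6 F_2$ feature.
5. **Decision fusion.** One linear classifier reads the flattened MSC map,
   another reads the TCN vector; their logits are summed and softmaxed.
   Training minimizes the cross-entropy of the fused logits.

Everything — convolutions, normalizations, attention, the TCN, Adam,
backpropagation — is implemented in this package on top of BLAS matrix
products, with a few elementwise loops in C++. The analytic gradients of
every block are verified against central finite differences in the test
suite, for the full graph and for each ablated variant.

## Training protocol

Adam with learning rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.99$ and weight
decay 0.001; mini-batches of 64 by default. After every step the max-norm
constraints are re-projected: each fully-connected unit's incoming weight
vector is clipped to norm 0.25, each TCN filter to 0.5, and each attention
projection column to 0.25. Validation loss is evaluated once per epoch;
training stops after `patience` evaluations without an improvement greater
than `min_delta` ($10^{-4}$), and the weights from the best validation epoch
are returned. With a fixed seed a run is bit-reproducible on one worker.

Two evaluation protocols are provided. *Within-subject*: stratified k-fold
(default 5) per subject, a stratified 20% of each fold's training part held
out for early stopping, per-subject accuracy averaged over folds.
*Cross-subject* (LOSO): one model per held-out subject, trained on the
pooled remaining subjects. Normalization statistics (per-channel mean and
variance over trials and time) are always fitted on the training part alone
and applied unchanged to validation and test data. Reports carry per-subject
accuracies, their mean and standard deviation, and Cohen's kappa
$(p_a - p_e)/(1 - p_e)$ both pooled over the combined confusion matrix and
averaged per subject (the pooled figure is the headline one).

## The synthetic generator, and what it does (not) show

No public EEG download is required anywhere: the package ships a generator
of labelled synthetic epochs that emulates the *physics of the class signal*
used by MI decoders — event-related modulation of band-limited power:

* every trial carries baseline oscillations for *all* class signatures
  (random frequency within the band, random phase, Hann envelope) on their
  designated channels;
* in a trial of class $k$, the class-$k$ oscillation amplitude is scaled by
  $1 + d_k$, where $d_k \in [0, 1]$ is the modulation depth — an
  event-related synchronization analogue. At $d = 0$ all classes are
  distributionally identical by construction;
* a symmetric nearest-neighbour leakage matrix mixes signals into adjacent
  electrodes; background noise is an equal-power mix of $1/f$-shaped and
  white Gaussian noise scaled by `noise_sd`; each subject applies its own
  log-normal channel gains;
* every (subject, trial) pair derives an independent RNG stream from the
  master seed by counter-style mixing, so regeneration is bit-identical and
  order-independent.

A band-power nearest-centroid classifier (`separability_oracle`) certifies
that a generated set is learnable *before* the network is blamed: it
extracts, per class signature, the mean log periodogram power over the
signature band and channels, and reports 5-fold cross-validated accuracy.

What passing tests on these data do show: the architecture can extract
class-dependent band-power structure through its full pipeline, the
protocols are leak-free, and optimization behaves. What they do not show:
performance on real EEG, which adds artifacts, non-stationarity,
inter-session drift and much smaller effect sizes. The published benchmark
accuracies on the BCI Competition IV datasets require those downloads and
GPU-scale training and are out of scope here.

## Desk-scale study conditions

The learning and ablation studies in the test suite run on a reduced
geometry chosen so that a full study (21 trainings for the ablation grid)
completes on one CPU core: 4 channels at 64 Hz, 4-second epochs
($T = 256$), 4 classes with 10/20/12/22 Hz signatures on one channel each,
24 trials per class per subject, modulation depth 0.8 with noise sd 0.3
("high SNR": the band-power oracle scores 1.0), and the reduced model
$F_1 = 8$, $D = 2$ ($F_2 = 16$, ~20k parameters). Each run trains at most
150 epochs with mini-batches of 16. Under these conditions the full model
and every single-block-ablated variant reach test accuracy 1.0, so the
ablation comparison asserts the non-strict ordering (full $\geq$ ablated) —
the direction, not the magnitude, of the published ablation table.

```{r, eval = FALSE}
library(mifuse)
spec <- synthetic_spec("mi4", n_channels = 4, fs = 64, epoch_duration = 4,
                       trials_per_class = 24, modulation_depth = 0.8,
                       noise_sd = 0.3, seed = 5)
ep <- generate_epochs(spec, subject_index = 1)
separability_oracle(ep, spec)   # ~1.0 under these conditions
fit <- mifuse(ep, config = model_config(4, 256, 4, F1 = 8),
              control = train_config(max_epochs = 150, batch_size = 16))
summary(fit)
```

## Numerical and design choices

Points where the underlying architecture description was ambiguous or
silent, and what this package does:

* **Normalization denominator.** The preprocessing formula is named
  Z-score normalization but is sometimes typeset with the *variance* in the
  denominator. Dividing by variance is unit-inconsistent, so the default
  divides by the standard deviation; `zscore_apply(..., denominator =
  "variance")` preserves the literal reading. Statistics are per channel
  over trials and time — the standard EEG convention.
* **Temporal kernel width.** The layer table lists 16 samples while the
  running text mentions 32; the table is the complete, internally consistent
  listing, so 16 is the default (`temporal_kernel` is configurable).
* **Pooling arithmetic.** Two width-8 poolings of $T = 1000$ give
  $\lfloor 1000/8 \rfloor = 125$ and $\lfloor 125/8 \rfloor = 15$ steps
  (floor division); derived quantities (flattened width 960, window length
  13) follow from the floored values.
* **The $6F_2$ TCN output.** A single TCN emits a $2F_2$ last-step vector;
  the $6F_2$ fused feature is obtained by running three overlapping sliding
  windows of the fused sequence through one shared-weight TCN and
  concatenating their last-step vectors. `n_windows` is configurable and
  does not change the parameter count (shared weights).
* **Decision fusion.** The layer table writes a concatenation of the two
  classifier outputs yet lists the output extent as $N_c$, not $2N_c$;
  element-wise logit summation before the softmax is the only operation
  matching that extent and is the default. A literal concatenation followed
  by a learned linear map is available via `fusion = "concat"`.
* **Spatial convolution extent.** The spatial depthwise convolution is
  applied with valid padding on the channel axis, collapsing $C$ to 1 —
  the only reading consistent with every later stage's printed extent.
* **Attention residual.** No residual connection is drawn around the
  attention block, so none is added by default; `msa_residual = TRUE`
  enables the transformer-conventional variant. The max-norm annotation on
  the attention row is read as a 0.25 constraint on the projection columns.
* **Early-stopping granularity.** "No improvement for 300 steps" is
  interpreted as 300 *validation evaluations*, evaluated once per epoch
  (`patience`, configurable), with improvement meaning a loss decrease
  greater than `min_delta`.
* **Ablation of the MSC block** replaces the three branches with the
  identity but keeps the subsequent normalization, pooling and dropout, so
  every downstream extent (and hence the rest of the graph) is unchanged.
* **Batch norm** uses batch statistics in training and running estimates
  (momentum 0.1, eps $10^{-5}$) in evaluation; initialization is
  Glorot-uniform with a recorded seed; both follow common framework
  defaults, which the source architecture leaves unstated.
* **Degenerate inputs.** Constant channels make Z-scoring impossible and
  raise an error naming the channel; sequences at least as long as the
  receptive field are rejected by the TCN; empty attention sequences and
  out-of-range labels raise immediately.

## Known limitations

* Pure-R/BLAS training is orders of magnitude slower than a GPU framework;
  the package is sized for desk-scale studies and method scrutiny, not for
  benchmark-scale sweeps.
* The generator makes no attempt at forward head modelling, ocular/muscle
  artifacts, or non-stationarity; transfer of results to real EEG must be
  established on real EEG.
* GDF ingestion shells out to Python MNE when available; it is an optional
  convenience, not a tested guarantee (no GDF writer exists to build
  round-trip fixtures from).
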