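# mifuse

Multi-scale fusion networks for motor-imagery EEG decoding, implemented
entirely in R.

## What this is

Brain–computer interfaces decode imagined movements from a few seconds of
multichannel EEG. The discriminative signal is event-related modulation of
band-limited power (mu/beta rhythms) over sensorimotor cortex — weak,
noisy, and spread across time scales. `mifuse` implements a hybrid neural
decoder that attacks this with five cooperating blocks:

* **SC** — temporal convolution (F1 kernels, width 16) followed by a
  depthwise spatial convolution across all C electrodes (depth multiplier
  D, giving F2 = D·F1 maps), batch norm, ELU, average pooling (width 8),
  dropout;
* **MSC** — three parallel depthwise-separable branches with kernels of
  8/16/32 samples and filter counts F2/4, F2/4, F2/2, concatenated on the
  depth axis, then pooled by 8 again;
* **MSA** — m = 8 heads of scaled dot-product self-attention over the
  pooled sequence: Q = YW^Q, K = YW^K, V = YW^V,
  softmax(QKᵀ/√d_h)V, heads concatenated and projected by W^o;
* **TCN** — feature fusion (depth concat of MSC and MSA sequences, depth
  2F2), then three overlapping windows through one shared temporal
  convolutional network of L = 2 dilated-causal residual blocks (kernel
  Kt = 4), receptive field RFS = 1 + 2(Kt−1)(2^L−1) = 19 > 13 (window
  length at T = 1000); the last-step vectors concatenate to 6F2 features;
* **MFF** — decision fusion: the MSC-branch classifier logits and the
  TCN-branch classifier logits are summed and softmaxed.

Training is Adam (lr 0.001, β₁ = 0.9, β₂ = 0.99, weight decay 0.001) on the
cross-entropy of the fused logits, with per-epoch early stopping and
max-norm re-projection (0.25 on dense units, 0.5 on TCN filters). Accuracy
and Cohen's kappa, stratified 5-fold within-subject and leave-one-subject-out
(LOSO) cross-subject protocols, Wilcoxon signed-rank comparisons, ablation
switches for every block, and interpretability exports (penultimate
embeddings, branch kernel spectra) are included.

There is no deep-learning framework underneath: every layer, the
backpropagation of each, and the optimizer are written in this package on
top of BLAS matrix products (plus a few small C++ loops). All analytic
gradients are tested against finite differences.

A synthetic ERD/ERS generator produces labelled epochs whose classes differ
only in narrow-band oscillation amplitude on chosen channels, with 1/f
background noise, inter-electrode leakage and per-subject gains — so the
whole pipeline is testable offline. A band-power nearest-centroid oracle
certifies each dataset's separability before any network is trained.

## Worked example

```r
library(mifuse)

# 4 synthetic classes: 10/20/12/22 Hz oscillations on distinct channels
spec <- synthetic_spec("mi4", n_channels = 4, fs = 64, epoch_duration = 4,
                       trials_per_class = 24, modulation_depth = 0.8,
                       noise_sd = 0.3, seed = 5)
ep <- generate_epochs(spec, subject_index = 1)
print(ep)
#> <eeg_epochs> subject SYN01: 96 trials x 4 channels x 256 samples @ 64 Hz
#>   labels: 0:24 1:24 2:24 3:24

separability_oracle(ep, spec)
#> [1] 1

fit <- mifuse(ep, config = model_config(C = 4, T = 256, Nc = 4, F1 = 8),
              control = train_config(max_epochs = 150, batch_size = 16,
                                     seed = 1))
print(fit)
#> Multi-scale fusion EEG decoder
#>   4 channels x 256 samples -> 4 classes; 19800 parameters
#>   trained 150 epoch(s) on 80 trials (best epoch 147, val acc 1.000)

mean(predict(fit, ep) == ep$labels)  # resubstitution accuracy
#> [1] 1
```

The oracle value (1.0) says the band-power structure alone separates the
classes, i.e. the data are learnable; the fit summary shows the 19,800-
parameter reduced network reaching validation accuracy 1.0 under those
conditions. On zero-signal data (`modulation_depth = 0`) the same pipeline
stays at chance — see the test suite.

Architecture inspection against the published layer contract (22 channels,
1000 samples):

```r
shape_trace(model_config(C = 22, T = 1000, Nc = 4))
#> stage extents: temporal_conv 32,22,1000 ... pool2 64,1,15 ...
#>                feature_fusion 128,15 ... tcn_windows 384 ... softmax 4
#> attr(, "rfs") 19; attr(, "tcn_input_len") 15
```

A command-line interface wraps the same functions
(`simulate`, `train`, `evaluate`, `ablate`, `inspect`, `export-embeddings`,
`kernel-spectra`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mifuse", package = "mifuse"))')
Rscript "$CLI" simulate --out fixtures --subjects 2 --seed 1
Rscript "$CLI" inspect --C 22 --T 1000
Rscript "$CLI" train --protocol within --k 2 fixtures/subject*.rds
```

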