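---
title: "Decoding visual categories from an area-ordered space sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual categories from an area-ordered space sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

When a person views a natural image, fMRI yields one deconvolved response
amplitude per voxel in each retinotopically defined visual area — V1, V2,
V3, V4 and the lateral occipital cortex (LO), ordered from primary to
high-level. Category information is carried twice over in these data: each
area's own pattern contains a *marginal* category signal that strengthens
along the hierarchy, and the *relationship between* areas — shaped by
bottom-up and top-down information flows — carries category structure of
its own. `visseq` implements a two-stage method that exploits both.

**Stage 1 — voxel-wise encoding and selection.** For each voxel $y$ and each
candidate stimulus-feature layer $X \in \mathbb{R}^{m \times n}$ we fit the
sparse linear encoding model

$$y = Xw, \qquad \min_w \|w\|_0 \ \text{s.t.}\ Xw = y ,$$

with regularized orthogonal matching pursuit (ROMP). Fits are scored by the
Pearson correlation between predicted and observed responses on held-out
samples. Per area, the layer whose top-200 voxels have the best mean
correlation is chosen, and the top-100 voxels on that layer are kept: five
areas times 100 voxels.

**Stage 2 — recurrent decoding of the space sequence.** The five selected
voxel vectors are treated as the five ordered nodes of a (fake-temporal)
sequence, V1 first. An LSTM consumes the nodes; its cell follows the
standard gate equations

$$f_t = \sigma(W_f [h_{t-1}, x_t] + b_f), \quad
  i_t = \sigma(W_i [h_{t-1}, x_t] + b_i), \quad
  o_t = \sigma(W_o [h_{t-1}, x_t] + b_o),$$
$$c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_c [h_{t-1}, x_t] + b_c),
  \qquad h_t = o_t \odot \tanh(c_t).$$

The bidirectional model runs one LSTM forward (V1 → LO, the bottom-up
direction) and one backward (LO → V1, top-down) and concatenates the two
final hidden states — 16 dimensions per direction, 32 combined — into the
input of a fully connected softmax head over 5, 10 or 23 categories (the
three nested label levels). Training minimizes the multiclass focal loss

$$\mathrm{FL}(p_y) = -(1 - p_y)^{\gamma} \log p_y, \qquad \gamma = 5,$$

with Adam (learning rate 0.001, decoupled L2 weight decay 0.001, batch size
64, about 200 epochs), and dropout of 0.5 on the combined feature during
training.

## A worked run

```{r, eval = FALSE}
library(visseq)
cfg <- sim_config(n_train = 400, n_val = 120, voxels_per_area = 20,
                  beta_marginal = rep(2, 5), seed = 1)
sim <- simulate_area_sequences(cfg, make_label_hierarchy(1))
model <- brnn(sim$train, sim$val, level = "coarse", epochs = 150, seed = 1)
model
predict(model, sim$val)[1:10]
```

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `hidden_dim` | 16 | per-direction LSTM feature width; the combined feature is 2×16 = 32 |
| `dropout` | 0.5 | rate on the combined feature, training only |
| `gamma` | 5 | focal-loss focusing; down-weights easy samples, 0 = cross-entropy |
| `batch_size`, `learning_rate`, `weight_decay` | 64, 0.001, 0.001 | Adam recipe |
| `epochs` | 200 | fixed budget, no early stopping |
| `max_nonzeros` | min(m/4, 100) | ROMP sparsity budget per voxel |
| `residual_tol` | 1e-4 | ROMP relative-residual stop |
| `top_n` | 200 | voxels averaged for per-area layer choice |
| `k` | 100 | voxels kept per area |

All are dimensionless except the learning rate (per-step size on the loss
scale) and `epochs` (full passes over the training split).

## The synthetic generator

Real recordings of this kind cannot be redistributed, so the package ships
a generator whose defaults are the study conditions the tests target: a
1750/120 train/validation split, five areas, 100 voxels per area, nested
5/10/23 balanced labels, and two separable kinds of category signal plus
unit Gaussian noise:

* **marginal signal** — area $a$ of a sample with fine label $\ell$ receives
  $\beta_{\mathrm{marg}}[a]\,\mu(\ell, a)$, with the per-area strengths
  nondecreasing from V1 to LO (default 0.2 … 1.0), emulating the
  hierarchical gradient of decodability;
* **relational signal** — each coarse label owns one orthogonal mixing
  operator per area; a per-sample latent vector $z$ enters area $a$ as
  $\beta_{\mathrm{rel}} Q_a^{(\kappa)} z$. Because every $Q$ is orthogonal,
  each area's marginal distribution is standard normal whatever the label:
  the label is carried *only* by the cross-area coupling. Mixing operators
  are keyed by the coarse label (per-fine operators at the default 100
  voxels per area would cost ~100 MB and add nothing the relational
  analyses use).

For the encoding stage a separate generator draws voxels as exactly
`sparsity_k`-sparse linear functions of an assigned feature layer, noise
variance set from the configured signal-to-noise ratio, standardized per
voxel on the training split — so true supports, weights and layers are
known and recoverable. `simulate_dataset()` composes both signals into one
dataset for the end-to-end pipeline. One global seed fans out to
per-component child seeds by fixed offsets ([child_seed()]), so every stage
is independently reproducible and bitwise identical across calls.

What the generator does **not** emulate: hemodynamics or any time series
(amplitudes are post-deconvolution scalars by construction), spatial voxel
correlation within an area, retinotopy, non-Gaussian noise, class
imbalance, and the actual image-feature statistics of a pretrained network
(feature matrices are white noise). Tests passing on this generator
therefore demonstrate correctness of the estimators and the claimed
ordering of models under the stated signal structure — not absolute
accuracy levels on real recordings.

## Numerical and design choices

* **ROMP details.** Candidate sets are the `max_nonzeros` largest residual
  correlations; the regularization step scans the magnitude-sorted
  candidates for the maximal-energy window whose entries are within a
  factor 2 of each other. Least-squares refits use QR. Iteration stops on
  the relative-residual tolerance, a full support, or a non-decreasing
  residual; the residual path is stored and is non-increasing by
  construction. In the best-subset benchmarks the budget is set to twice
  the true sparsity, mirroring the solver's own halting convention.
* **Feature standardization.** Columns of every feature layer are z-scored
  with training-split statistics before fitting, so residual-correlation
  magnitudes are comparable across columns.
* **Tie-breaks.** Layer selection ties break toward the lower layer index;
  voxel selection ties break by ascending voxel id; undefined (constant-
  prediction) correlations rank last. All orderings are deterministic.
* **Reading "combined the output features from two directions".** The
  16-D-per-direction and 32-D-combined arithmetic forces concatenation of
  the two final hidden states; per-node pooling is rejected.
* **Dropout placement** is on the combined 32-D feature only, training
  mode only; the unidirectional ablations use the identical recipe on
  their 16-D feature for comparability.
* **Weight regularization** is implemented as decoupled L2 decay in the
  Adam update, applied to weight matrices but not biases.
* **Initialization.** Uniform ±1/√H for recurrent and head weights, zero
  biases except the forget-gate block at +1. Seeded; training is
  single-threaded and reproducible per seed.
* **Focal loss** uses no per-class α weighting; the true-class probability
  is clamped at 1e-12 (with a message) before the logarithm.
* **Backward direction** is implemented as a forward pass over the
  reversed node order, which makes the ablation identity "forward on
  reversed sequences ≡ backward on originals" exact, including the random
  stream.
* **Significance testing.** The repeat protocol (5 seeds, mean ± sample
  standard deviation in percent) is compared across methods with a
  two-sided Welch t-test; when one method is deterministic (the SVMs and
  AdaBoost repeat to identical accuracies) a one-sample test against that
  constant is used; results should be read with that choice in mind.
* **Shuffled-label nulls.** With strongly clustered class signal, a model
  trained on permuted labels memorizes a random label per cluster, so the
  null validation accuracy varies at the granularity of the 23 fine
  clusters, not of individual validation samples. Null checks therefore
  average several independent shuffles before comparing against the
  binomial band around chance.
* **Storage.** Datasets, fit tables, selections, reports and model
  checkpoints are delimited text and JSON (see `?write_dataset`,
  `?save_decoder`): human-readable, diff-able and lossless for the
  purposes of the pipeline's determinism guarantees.

## Problem sizes used by the test suite

The packaged checks run the generator at reduced sizes chosen to keep the
statistical claims meaningful: encoding-recovery at 300 training samples,
64 features and 40 voxels per area; end-to-end decoding at 400–600 training
samples, 16–20 voxels per node, 120–150 epochs, 5 repeat seeds; the
best-subset benchmark at 200 seeded 20×8 problems. The defaults of
`sim_config()` remain the full study conditions (1750/120, 100 voxels per
area).

## Known limitations

* The sequence length is the five-area list; other area sets work but the
  method is designed around the V1→LO ordering.
* The relational signal is learnable only through the recurrent models'
  multiplicative gating; linear per-area read-outs are blind to it by
  construction, and at small sample sizes all models recover it only
  partially.
* No GPU path and no attention/GRU variants; the decoder is deliberately
  the minimal bidirectional LSTM the method requires.
* Real MATLAB-container releases must be converted to the text layout
  before `load_vim1()` can read them; the package never downloads data.
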