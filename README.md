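# visseq

Two-stage decoding of visual stimulus categories from fMRI response
amplitudes in human visual cortex, for researchers doing multivariate
pattern analysis who want to exploit not only each visual area's own
category signal but also the *relationship between* areas induced by
bottom-up and top-down information flows.

## The method

**Stage 1 — voxel-wise encoding and voxel selection.** Each voxel's
response vector *y* (one amplitude per stimulus, time removed by
deconvolution upstream) is modelled as a sparse linear function of a
stimulus feature layer *X*:

    y = Xw ,   min ||w||_0  subject to  Xw = y ,

solved by regularized orthogonal matching pursuit (ROMP): greedy selection
of comparable-magnitude batches of features with orthogonal least-squares
refits. Fits are scored by held-out Pearson correlation; per visual area
(V1, V2, V3, V4, LO) the feature layer with the best mean correlation over
its top-200 voxels is chosen, and the 100 best-predicted voxels are kept.

**Stage 2 — bidirectional recurrent decoding.** The five areas' selected
voxel vectors form an ordered "space sequence" (V1 → V2 → V3 → V4 → LO).
Two LSTMs traverse it in opposite directions — bottom-up and top-down —
and the concatenation of their final hidden states (16-D each, 32-D
combined) feeds a fully connected softmax head over 5, 10 or 23 nested
categories. Training is end-to-end under the multiclass focal loss
`-(1-p)^γ log p` with γ = 5, Adam (learning rate 0.001, weight decay
0.001, batch size 64, ≈200 epochs) and dropout 0.5 on the combined
feature. Classical baselines (decision tree, random forest, AdaBoost,
linear/RBF SVM), a fully connected network (500-64-32), and unidirectional
ablations are included, along with the evaluation protocol: 5-repeat
mean ± std accuracies, Welch significance tests and row-normalized
confusion matrices.

A synthetic generator produces labeled datasets with the two signal kinds
the method targets — a per-area marginal category signal strengthening
from V1 to LO, and a purely cross-area relational signal realised as
label-dependent orthogonal coupling — so everything is testable without
any data download.

## Worked example

```r
library(visseq)
cfg <- sim_config(n_train = 400, n_val = 120, voxels_per_area = 20,
                  beta_marginal = seq(0.2, 1, length.out = 5), seed = 1)
sim <- simulate_area_sequences(cfg, make_label_hierarchy(1))
model <- brnn(sim$train, sim$val, level = "coarse", epochs = 150, seed = 1)
model
#> Recurrent space-sequence decoder (bidirectional LSTM)
#>   sequence: V1 -> V2 -> V3 -> V4 -> LO  (K = 20, H = 16)
#>   classes: 5 (coarse level), 4901 trainable parameters
#>   final validation accuracy: 0.7000
```

70% of the 120 held-out samples are assigned the correct one of five
coarse categories (chance is 20%), under the generator's default
hierarchy-gradient signal. The repeat protocol and the confusion matrix:

```r
repeated_runs(function(s) brnn(sim$train, sim$val, level = "coarse",
                               epochs = 150, seed = s), seeds = 1:5)
#> Accuracy over 5 repeat(s): 70.00 ± 3.82 %

cm <- normalized_confusion_matrix(predict(model, sim$val),
                                  sim$val$labels$coarse, 5)
round(matrix(cm, 5, 5, dimnames = dimnames(cm)), 2)
#>     predicted
#> true    0    1    2    3    4
#>    0 0.76 0.04 0.08 0.04 0.08
#>    1 0.05 0.81 0.05 0.05 0.05
#>    2 0.04 0.07 0.67 0.00 0.22
#>    3 0.29 0.10 0.00 0.52 0.10
#>    4 0.08 0.12 0.08 0.00 0.73
```

Each row is a true category and sums to 1; entry (i, j) is the fraction of
class-i validation samples predicted as class j.

The full pipeline — simulate, encode, select, assemble, decode, report —
runs from one configuration via `run_pipeline(pipeline_config(...), dir)`
or the thin CLI (`exec/visseq run --out DIR`). See the vignette
(`vignettes/space-sequence-decoding.Rmd`) for the model details, the
generator's design and every numerical choice.

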