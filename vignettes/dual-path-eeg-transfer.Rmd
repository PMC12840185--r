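---
title: "Dual-path spatio-temporal EEG encoding and parameter-efficient cross-task transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-path spatio-temporal EEG encoding and parameter-efficient cross-task transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package fits a regression encoder to epoched multichannel EEG
`x ∈ R^{B×C×T}` with one continuous label per epoch. The encoder has four
stages, composed as

```
F     = FrontEnd(x)                        (B × T' × D)
H_t   = TemporalPath(F)                    (B × T' × D_t)
H_s   = SpatialPath(F_nodes, A)            (B × T' × D_s)
H_f   = G ⊙ H_t' + (1 − G) ⊙ H_s'          (B × T' × D_f)
H_out = γ_t ⊙ H_f + β_t  → bottleneck      (B × T' × D_f)
ŷ     = MLP(mean over frames of H_out)     (B)
```

**Multi-scale front-end.** Three parallel dilated temporal convolutions with
kernel/dilation pairs (7, 1), (5, 2) and (3, 4) cover receptive fields of 7,
9 and 9 frames at three dilation rates, matching slow oscillations,
intermediate rhythms and fast transients at the 100 frames/s working rate.
Branch outputs are concatenated, pooled by a stride-2 frame average
(`T' = T/2`), projected to the common width `D`, batch-normalized and passed
through GELU.

The published pipeline feeds both encoder paths from a single front-end
tensor of shape `B × T' × D`, which has no channel axis; a channel-node graph
path cannot consume it directly. We resolve this with a *two-view front-end*:
the channel-mixing view above for the temporal path, and a channel-preserving
view — per-channel (depthwise) convolutions with the same kernels and a small
channel multiplier — for the graph path, giving node features of dimension
`n_branches × multiplier` per electrode. This keeps the "channels as graph
nodes" semantics while honouring the published front-end shape. It is one
reading of an under-specified design, and we flag it as such.

**Temporal path.** Pre-norm transformer encoder layers: multi-head
self-attention over frames, a depthwise temporal convolution (kernel 7), and
a feed-forward sublayer, each wrapped in a residual connection, with one
fixed sinusoidal positional encoding added before the first layer and a final
layer norm. Pre-norm and GELU follow small-scale conformer convention; the
published description fixes the sublayer types but not these details.

**Spatial path.** The electrode montage becomes a graph: symmetrized
k-nearest-neighbour adjacency on 3-D electrode positions (k = 8 at 128
channels, k = 4 at desk scale), self-loops, symmetric degree normalization.
Graph-convolution layers (`H ← gelu(Â H W)`) run per frame; mean pooling over
nodes and a linear projection give `H_s`.

**Gated fusion.** Both streams are projected to `D_f` and a two-layer MLP on
their concatenation emits a sigmoid gate `G` of the same shape (per frame,
per feature — the elementwise product in the fusion rule implies elementwise
weights). `H_f` is the elementwise convex combination of the streams, so it
always lies inside their envelope; this invariant is property-tested.

**Task-adaptive residual block.** A task id selects an embedding `e_t`;
linear maps give feature-wise modulation `γ_t, β_t`; the modulated features
pass through a bottleneck residual block (down-project to `r`, GELU,
up-project, add). The bottleneck output layer and both modulation weight
matrices start at zero with `γ = 1, β = 0`, so a fresh adapter is the exact
identity — standard adapter practice that protects the backbone's function at
the start of transfer.

## The reference calibration

The published configuration pins `C = 128`, `T = 200`, `D = 256`, 8 heads, 2
temporal and 2 graph layers, dropout 0.1, and the component parameter budgets:
593,792 backbone parameters, 10,436 adapter-plus-head parameters, 604,228 in
total (1.7% trainable under transfer). It does not print the internal widths.
We treat the budgets as the normative constraint and fixed the free
dimensions by integer search until both budgets are met exactly:

| dimension | value |
|---|---|
| branch channels | 96 per branch |
| depthwise multiplier | 4 (node dim 12) |
| D_t / ffn | 128 / 264 |
| graph dims / D_s | 32, 32 / 48 |
| D_f / gate hidden | 64 / 32 |
| D_e / bottleneck r / head hidden | 16 / 29 / 67 |

Three exact solutions existed in the searched grid; we chose the one with
conventional proportions (ffn ≈ 2·D_t; concatenated front-end width 288
projected to 256). The calibration ships in
`inst/extdata/reference_config.toml` and is asserted by tests. `T' = T/2`
comes from one stride-2 pooling — the published frame count after the
front-end is never stated, and halving keeps attention cost quadratic in 100
rather than 200 frames.

## Training protocol

Both stages share one loop: Adam (weight decay 1e-4 added to gradients),
MSE loss on z-scored targets (training-split statistics; predictions are
rescaled before metrics are computed), per-epoch cosine annealing from the
stage base rate to a floor of 1e-5, batch size 16, early stopping on
validation loss with strict improvement. Pre-training uses base rate 1e-3
and trains everything (task id 0); transfer uses 1e-4 and trains only the
adapter and head (task id 1) with the backbone frozen. Augmentation —
circular temporal jitter up to 10 frames and whole-epoch amplitude scaling
in [0.9, 1.1] — applies to training batches only. The jitter and scaling
magnitudes are package choices; the published protocol names the
augmentations without parameters.

Two transfer-stage conventions are worth stating. First, the frozen backbone
runs in inference mode (no dropout, running batch-norm statistics), so its
weights *and* buffers are bitwise invariant over any number of optimizer
steps. Second, when the backbone is frozen and augmentation is disabled, the
fused features are input-fixed; the loop then computes them once and trains
the adapter on the cache. This is exactly equivalent to the full forward pass
(asserted in tests to machine precision) and makes adapter fine-tuning cheap.
The desk-scale adapter stage therefore runs augmentation-free; the
from-scratch comparator uses the identical configuration so the comparison
budget stays symmetric.

## The synthetic cohort

Real cohorts of this kind (hundred-channel child/adolescent EEG with
trial-level reaction times and questionnaire-derived psychopathology scores)
cannot ship with a package, so every end-to-end claim is exercised on a
synthetic cohort with a known hierarchical structure:

* per subject *i*: latent efficiency `z_i ~ N(0,1)`; psychopathology
  `p_i = −a_p z_i + ε_p`, with `a_p = 0.8`, `sd(ε_p) = 0.45`;
* per trial *j*: efficiency `e_ij = z_i + ε_e` (`sd = 0.5`); reaction time
  `RT_ij = 600 − 150 e_ij + ε_rt` ms (`sd = 100` ms), floored at 150 ms;
* per epoch: a 10 Hz alpha carrier whose amplitude falls monotonically with
  trial efficiency (`1.5·(1 − 0.5·tanh e)`, a stylized alpha-suppression
  mechanism), spread by a smooth posterior topography; an evoked Gaussian
  bump (amplitude 2, width 50 ms) centred at the frame corresponding to the
  trial's reaction time inside the 0.5–2.5 s post-stimulus window, with a
  centro-parietal topography; and per-channel 1/f noise (sd 1).

The slopes and noise levels were chosen once to give a learnable but
non-trivial task: behaviourally plausible RT spread, a subject-level
RT-mean/psychopathology correlation near 0.85 (the generator test checks the
sample value against the closed-form implied by the slopes), and a positive
but modest alpha-power linear-probe floor. Epochs are shared between the RT
and psychopathology views; splits are subject-grouped (0.6/0.2/0.2).

What the generator does **not** emulate: real electrode montages, ocular and
muscle artifacts, inter-subject anatomical variability, non-stationary
rhythms, or any quantitative RT↔psychopathology effect size from a real
population (none is published for the motivating cohort). Passing the
package's acceptance runs therefore demonstrates that the architecture,
optimization and transfer machinery work as specified on data with the
intended latent structure — not that the published real-data performance
numbers are reproduced. Those numbers depend on an external dataset and are
explicitly out of scope.

## Desk-study problem sizes

Simulation studies run a small instance of the same architecture
(`dstage_config_desk()`: 16 channels, 24-dimensional features, one
transformer and one graph layer, ~12k parameters) on the reference cohort of
60 subjects × 50 epochs. Pre-training runs up to 10 epochs (patience 5);
the adapter-transfer/from-scratch comparison runs up to 10 epochs
(patience 4) per arm at the transfer learning rate, identically for both
arms, over five seeds. These sizes are the package's choice of simulation
scale: large enough that the pre-trained encoder clearly beats the linear
alpha-power probe floor and the transfer contrast is measurable, small
enough to run on a single CPU core in minutes. The full 128-channel
reference calibration is exercised structurally (construction, forward pass,
exact parameter accounting) rather than trained in the test suite.

## Numerical choices and degenerate inputs

* Float comparisons in tests use 1e-6 relative tolerance unless the
  contract is bitwise (determinism, freeze invariance).
* Layer/batch norm use eps 1e-5; Adam uses (0.9, 0.999, 1e-8).
* GELU uses the tanh approximation throughout (forward and backward are a
  matched pair, verified against finite differences).
* Attention rows are max-shifted before the softmax; rows sum to 1 within
  1e-6.
* Zero-variance channels make per-epoch z-scoring undefined and raise an
  error naming the channel and epoch; constant targets make NMSE undefined
  and raise an error; duplicate electrode positions are rejected when the
  adjacency is built.
* Non-finite training loss aborts with a diagnostic rather than continuing.
* Ties in early stopping resolve to the earliest epoch (strict improvement).

## Known limitations

* The gradient engine is purpose-built for this architecture; it is not a
  general autodiff system, and adding new layer types means writing their
  backward passes.
* Adjacency is fixed after construction (a learned-adjacency variant is out
  of scope); electrode positions default to a synthetic spherical-cap layout
  when no montage is supplied.
* EDF ingest expects one sampling rate across signals and takes events from
  a user-supplied onset table rather than embedded annotations.
* Training is single-threaded CPU; the desk scale is sized for that budget.
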