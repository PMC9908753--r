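---
title: "Methods: FC network construction, DGCNN classification and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FC network construction, DGCNN classification and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braindgcnn)
```

## The model

The pipeline treats each subject's brain as an undirected graph over a fixed
ROI atlas and classifies subjects (MDD vs. NC) from graph structure plus
continuous node features.

**Functional connectivity.** For ROI signals $x_i(t)$, $t = 1..T$, the FC
matrix entry is the Pearson correlation
$\gamma_{ij} = \frac{\sum_t (x_i - \bar x_i)(x_j - \bar x_j)}
{\sqrt{\sum_t (x_i-\bar x_i)^2}\sqrt{\sum_t (x_j-\bar x_j)^2}}$.
This assumes stationarity over the scan (only static FC is modelled) and
requires every ROI signal to have nonzero variance; constant signals are
rejected with the offending ROI index rather than mapped to 0, because they
almost always indicate an extraction fault upstream.

**Binarization.** An edge joins $i \ne j$ when $\gamma_{ij} \ge \tau$. Three
conventions here were genuinely open and are fixed as follows:

* *Signed, not absolute*: negative correlations never create edges. Cohort
  edge counts at permissive thresholds (roughly a third of all pairs at
  $\tau = 0.2$) are consistent with a one-sided rule, and nothing in the
  source procedure mentions magnitudes. `absolute = TRUE` switches to
  $|\gamma_{ij}| \ge \tau$ for sensitivity analyses.
* *Inclusive boundary* ($\ge$): ties at exactly $\tau$ are kept, so behaviour
  at ties is deterministic and documented rather than accidental.
* *No self-loops stored*: the diagonal is always zero; the classifier adds
  the self-loop itself inside its propagation rule.

**Node features** are the rows of the *continuous* FC matrix (each node's
whole-brain correlation profile), not the binary rows — "nodal functional
connectivity" is most informative as strengths; `features = "binary"` is
available for ablation.

**Connectivity audit.** The Warshall recursion
$R_k[i,j] = R_{k-1}[i,j] \lor (R_{k-1}[i,k] \land R_{k-1}[k,j])$ computes
the transitive closure (vectorized per pivot as an outer product — the same
recursion evaluated in one sweep). The diagonal is initialized true, so
"connected" means every ordered pair of distinct nodes is mutually
reachable. The cohort *connectivity ratio* is #connected / #unconnected; at
permissive thresholds every network can be connected, and the ratio is then
reported as `Inf` rather than erroring, so threshold sweeps always complete.
Both overall and per-group (MDD/NC) ratios are tabulated, since group-wise
curves are the natural reading of connectivity-vs-threshold plots.

## The classifier

Input: binary adjacency $A$ (zero diagonal) and features $X \in
\mathbb{R}^{n \times d}$ (default $d = n$).

1. Four graph convolutions $Z_{t+1} = \tanh(\tilde D^{-1} \tilde A Z_t W_t)$
   with $\tilde A = A + I$ and $\tilde D$ its degree matrix; channel widths
   32, 32, 32, 1 (the standard DGCNN stack). The source names the
   architecture but prints no propagation formula; the cited defaults are
   adopted wholesale.
2. Layer outputs are concatenated ($C = 97$ channels) and passed through
   **SortPooling**: rows sorted descending by the last channel, ties broken
   by preceding channels right-to-left, then by node index; the top $k$ rows
   are kept, zero-padded if $n < k$. Because every brain graph shares one
   atlas, all graphs have $n$ nodes and $k$ defaults to $n$ (no truncation);
   a percentile rule for variable-size graphs is unnecessary here. The fully
   specified tie-break is what guarantees permutation invariance: the model
   output is invariant (to 1e−6 and in practice to machine precision) under
   any relabelling of the input nodes, because sorting restores a canonical
   order. Note the invariance is over node *order* (adjacency rows/columns
   and feature rows); feature columns are semantic channels and are not
   permuted.
3. Head: 1-D convolution with 16 filters whose width and stride equal $C$
   (it reads one node's channel vector per step), ReLU; max-pool width 2
   stride 2; 1-D convolution, 32 filters, width 5, stride 1, ReLU; dense
   128, ReLU; dropout 0.5; dense 2; softmax. ReLU (not tanh) is used in the
   head, following the explicit statement that convolutional and dense
   layers use rectified-linear activations.
4. Loss: batch-mean binary cross-entropy on the MDD probability,
   $-\frac1B\sum_i y_i\log\hat y_i + (1-y_i)\log(1-\hat y_i)$, with
   probabilities clipped to $[10^{-7}, 1-10^{-7}]$ to keep logs finite.
   Optimizer: Adam with the standard $\beta_1 = 0.9$, $\beta_2 = 0.999$,
   $\epsilon = 10^{-8}$ (the source tunes only the learning rate).

Forward and backward passes are hand-written dense linear algebra; the
block-diagonal propagation over a mini-batch is a per-graph loop over small
dense blocks, which profiled ~20× faster than a sparse block-diagonal
matrix at 20–160-node scale.

### Tunable parameters

| parameter | default | meaning / guidance |
|---|---|---|
| `tau` | 0.3 | binarization threshold (correlation units). 0.2–0.4 is the studied range; 0.3 was the best-accuracy working point at lr 0.001. |
| `learning_rate` | 0.001 | Adam step size; the one hyperparameter worth sweeping (0.0001–0.01). |
| `epochs`, `batch_size` | 100, 50 | training regime of the source study. Small synthetic cohorts separate in far fewer epochs. |
| `k` | `NULL` (= n) | SortPooling size; only change when mixing graph sizes. |
| `dropout` | 0.5 | between the dense layers; inverted convention (scaled at train time), so eval uses raw weights — mathematically equivalent in expectation to classic weight scaling. |
| `conv_channels`, `filters1/2`, `width2`, `dense_width` | 32·3+1, 16/32, 5, 128 | cited architecture defaults; shrink all of them together for desk-scale experiments. |

Numerical choices: Glorot-uniform initialization (fan-based limits) seeded
by `config$seed`; all randomness (init, shuffling, dropout) is drawn from
that one stream in a fixed order, so identical seeds give bit-identical
training histories. Head geometry requires $\lfloor k/2 \rfloor \ge$
`width2`; smaller graphs must reduce `width2` (validated with a clear
error). Max-pool ties route gradient to the first element; ReLU uses the
zero subgradient at its kink — with zero-initialized biases some
pre-activations start exactly on the kink, which is why gradient
verification is done at a generic point (small random biases).

## Evaluation

MDD is the positive class (sensitivity = MDD detection rate). ACC, SEN,
SPE, PRE and F1 are percentages; zero-denominator ratios are `NaN`, never
silent zeros. AUC is the trapezoidal area over all unique score thresholds
of the MDD probability, which equals the Mann–Whitney pair statistic with
ties counted ½.

* **Holdout**: stratified 90/10 with largest-remainder rounding, so the
  train size is exactly `round(0.9 n)` while class shares stay within one
  subject of proportional.
* **k-fold CV**: stratified folds; one model trained from scratch per fold
  (seed offset by fold index); the aggregate is the *unweighted mean* of
  fold metrics — the pooled-confusion alternative is also reported, since
  the choice is a convention, not a theorem.
* **Leave-one-site-out**: each site is held out entirely once and the model
  trained on all other sites — the reading of "leave-one-site-out
  cross-validation" that measures cross-site generalization. (The
  alternative reading, k-fold within each site, answers a different
  question and is not what a site-effect analysis needs.)
* Trainers are pluggable (`trainer`/`predictor` arguments), so the harness
  can also evaluate cheap baselines such as the bundled nearest-centroid
  classifier; the DGCNN is the default.

## The synthetic generator

The generator stands in for access-restricted consortium data. It emulates:
two diagnostic groups whose difference is a planted within-community
correlation increase $\Delta$ (disease expressed as altered FC, not altered
signal mean); block-structured FC (functional communities), with
`base_within_r = 0.4` and `base_between_r = 0.1` chosen as typical
within/between-community resting-state correlation levels; and a multi-site
structure in which each site adds a global correlation offset (evenly
spaced over `site_shift`, default 0.1, centred so the cohort mean is
unchanged) — a crude but effective stand-in for scanner/protocol effects.
Target matrices are repaired to the nearest positive-semidefinite
correlation matrix (eigenvalue clipping, then renormalization to unit
diagonal) because naive block matrices with large $\Delta$ can be
indefinite; signals are i.i.d.-in-time multivariate normal draws.

The default geometry is desk-scale — 20 ROIs, T = 200, 100 subjects per
group, 4 sites, $\Delta = 0.3$ — which exercises every code path in well
under a minute; `n_rois = 160` restores atlas scale.

It does **not** emulate: haemodynamic/BOLD dynamics or temporal
autocorrelation, negative-tail FC structure, subject-level covariates (age,
sex, medication), missing data, or site differences in noise level rather
than correlation offset. A green planted-effect test therefore establishes
that the pipeline recovers a correlation-structure group difference under
clean conditions — not that it attains any particular accuracy on real
consortium data, whose headline numbers are out of reach without access.

## Reproducibility and I/O

Single-threaded deterministic execution is the default; every output file
(metrics, history, ROC, checkpoint, run manifest) is bit-reproducible from
config + seeds, and the run manifest deliberately contains no timestamps
(those live in the log). Node indices are 0-based in all on-disk edge lists
— atlas tables are conventionally 1-based, so exports shift by one.
Configs, manifests and checkpoints are JSON (the pre-installed, declared
dependency set includes `jsonlite` but no YAML parser); cohort I/O is a
manifest CSV plus one TSV per subject, and no HDF5 reader is bundled for
the same reason.

## Limitations

Pure-R training is practical at desk scale and adequate at 160-ROI scale
for hundreds of subjects, but is not a GPU deep-learning stack. Only static
FC is modelled. Learned features are not interpretable (no saliency
machinery). The generator's i.i.d. normal signals make FC estimation easier
than real autocorrelated BOLD; planted-effect margins should be read as
upper bounds on desk-scale behaviour.
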