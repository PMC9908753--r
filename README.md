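# braindgcnn

Classification of brain functional-connectivity networks with a deep graph
convolutional neural network (DGCNN), in pure R.

## The problem

Resting-state fMRI studies of major depressive disorder (MDD) describe the
brain as a network: nodes are atlas-defined regions of interest (ROIs, e.g.
the 160-region Dosenbach atlas) and edges reflect functional connectivity
(FC) — the Pearson correlation γ_ij between the ROI-averaged time courses
x_i(t), x_j(t). Given per-subject FC networks, the task is to classify
subjects as patients (MDD) or normal controls (NC), ideally on large
multi-site cohorts where single-site variability averages out. This package
implements that pipeline end to end for analysts working with ROI time
series (or precomputed FC matrices) and case/control labels:

1. **Network construction** — per-subject Pearson FC matrix; sparsification
   into a 0–1 adjacency by thresholding γ_ij ≥ τ (signed, inclusive;
   absolute-value mode optional); node features are the rows of the
   continuous FC matrix.
2. **Connectivity audit** — Warshall transitive closure
   (R_k[i,j] = R_{k−1}[i,j] ∨ R_{k−1}[i,k] ∧ R_{k−1}[k,j]) decides whether
   each network is connected; the cohort-level *connectivity ratio*
   (#connected / #unconnected) is tabulated per threshold.
3. **Classification** — a DGCNN: four graph-convolution layers
   Z_{t+1} = tanh(D̃⁻¹ Ã Z_t W_t) with Ã = A + I, their concatenated outputs
   passed through **SortPooling** (canonical node ordering, fixed output
   size k), then a 1-D convolutional head (16 filters spanning one node's
   channels → max-pool 2/2 → 32 filters of width 5, ReLU), a 128-unit dense
   layer, dropout 0.5, and a 2-way softmax. Trained with binary
   cross-entropy and Adam (defaults: lr 0.001, batch 50, 100 epochs).
4. **Evaluation** — ACC/SEN/SPE/PRE/F1 (percent) from the confusion matrix,
   trapezoidal ROC-AUC (= Mann–Whitney statistic), stratified 90/10 holdout,
   stratified k-fold CV, and leave-one-site-out evaluation for cross-site
   generalization.
5. **Synthetic cohorts** — consortium rs-fMRI repositories are typically
   access-restricted, so a generator produces multi-site two-group cohorts
   whose group difference is a planted perturbation Δ of within-community
   correlations, making every stage testable end to end.

## Worked example

```r
library(braindgcnn)

spec   <- synthetic_cohort_spec(n_per_group = 30, n_rois = 20, T_len = 200,
                                effect_delta = 0.3, seed = 42)
cohort <- generate_cohort(spec)
cohort[[1]]
#> <roi_ts> subject case_001  label MDD  site S1  20 ROIs x 200 time points

fcs <- lapply(cohort, pearson_fc)
connectivity_table(fcs, c(0.2, 0.3, 0.4))
#>   threshold n_connected n_unconnected ratio ratio_MDD ratio_NC mean_edges_MDD mean_edges_NC
#> 1       0.2          37            23  1.61      1.31        2           55.9          57.4
#> 2       0.3           0            60  0.00      0.00        0           40.4          36.5
#> 3       0.4           0            60  0.00      0.00        0           40.0          19.4

graphs <- cohort_to_graphs(cohort, tau = 0.3)
cfg    <- dgcnn_config(epochs = 20, learning_rate = 0.005, seed = 42)
kfold_cv(graphs, k = 5, cfg, seed = 42)
#> <cv_result> 5 folds/sites
#>     unit   ACC    SEN    SPE    PRE    F1    AUC
#> 1  fold1 75.00 100.00  50.00  66.67 80.00 0.9722
#> ...
#> 6   mean 78.33  86.67  70.00  77.50 80.10 0.9000
#> 7 pooled 78.33  86.67  70.00  74.29 80.00 0.8844
```

Reading the output: raising τ prunes edges, so the number of connected
networks (and the connectivity ratio) falls monotonically — at τ = 0.3 no
20-ROI network in this small cohort remains fully connected, yet the DGCNN
still separates the groups (mean CV accuracy 78.3%, AUC 0.90) because the
planted Δ = 0.3 within-block correlation difference survives in the node
features and edge topology. `mean` is the unweighted average of per-fold
metrics; `pooled` recomputes them from the summed confusion matrix.

An end-to-end run (simulate → FC → connectivity → train → evaluate, with
all artifacts on disk) is one call:

```r
res <- run_pipeline(pipeline_config(output_dir = "results",
                                    protocol = "holdout",
                                    synthetic_spec = spec))
```

or from the shell via the CLI driver (subcommands `simulate`,
`build-networks`, `connectivity`, `train`, `evaluate`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "braindgcnn.R", package = "braindgcnn"))')" \
    run --out results --threshold 0.3 --epochs 20 --seed 42
```

Outputs are reproducible bit-for-bit given the same config and seeds
(single-threaded execution; all RNG flows from the configured seeds).

## Scope

Raw fMRI preprocessing (slice timing, realignment, normalization,
filtering), atlas registration and vendor imaging formats (NIfTI/DICOM) are
upstream of this package: inputs are ROI-by-time matrices (TSV + manifest
CSV) or precomputed FC matrices. See `vignettes/methods.Rmd` for the model,
its assumptions, parameter guidance and known limitations.
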