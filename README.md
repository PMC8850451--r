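# loomnet

Brain-wide network analysis of visual habituation in larval zebrafish, as a
tested, reusable R pipeline over synthetic cohorts.

Repeated looming stimuli (an expanding dark disc simulating an approaching
predator) trigger escape responses that habituate — a basic form of
non-associative learning. Habituation speed and post-rest recovery depend on
the stimulus train (fast/slow expansion, 20-s or 60-s inter-stimulus
intervals: the f20/f60/s20/s60 paradigms) and on genotype (*fmr1* mutants,
a Fragile X model, habituate more slowly). `loomnet` is aimed at systems
neuroscientists who want the full quantitative chain from behavior and
calcium imaging to network statistics without the original imaging data:
a synthetic-cohort generator reproduces the statistical structure the
analysis assumes, and every downstream stage is ordinary, documented R.

The pipeline implements:

- **Behavior** — escape detection (>30 mm/s bins inside the loom window),
  per-loom response probabilities, constrained one-phase decay fits
  `y = plateau + (Y0 − plateau)·exp(−K·(x − 1))` with `K > 0`, and exact
  one-sided binomial tests of mutant vs WT response proportions with
  Bonferroni cutoffs.
- **Functional clustering** — per-data-set z-scoring, regression of every ROI
  on template regressors (three strongly habituating subtypes, moderate,
  weak, inhibited, auditory, and per-fish motor regressors; strict r² > 0.3
  and > 0.2 thresholds), cityblock k-means for cluster discovery, outlier-fish
  flagging, normalized per-loom response maxima, anatomical proportion
  tables, behavior–neural Pearson correlations, and the motor-association
  threshold (Spearman mean + 1 SD).
- **Graphs** — spatial–functional nodes from the 200/500/1000/3000 ROI-count
  rule (configurable for desk-scale cohorts), per-fish per-loom node
  correlation matrices, group averages with leave-one-out, |r| ≥ 0.75
  thresholding, density, participation coefficients
  `P_i = 1 − Σ_k (S_iCk / S_i)²`, recovery matrix matching, relative graphs,
  and edge recovery deltas.
- **Null models** — amplitude-adjusted Fourier transform (AAFT) surrogates
  (whole-trace and windowed) and layer-permutation temporal nulls.
- **Dynamic communities** — multilayer modularity
  `Q = (1/2μ) Σ_ijlr [(A_ijl − γ_l P_ijl) δ_lr + δ_ij ω_jlr] δ(C_il, C_jr)`
  optimized by generalized Louvain on the supra-modularity matrix, γ/ω sweeps
  with temporal-null-referenced scores and bounding rules, iterative consensus
  partitions, and per-node flexibility `ξ_i = g_i/(L−1)`, cohesion
  `Ω_i = Σ_j M_ij` and promiscuity `Ψ_i = g_i^dif/(K−1)`, compared across
  genotypes by Friedman tests at the 13-test Bonferroni cutoff.
- **Topology** — persistent homology (dimensions 0–2, GF(2)) of the
  correlation-filtered clique complex, barcodes and lifetime sums.

## Worked example

```r
library(loomnet)

# behavior: 36 larvae under the fast-loom, 20-s-ISI train
train <- build_stimulus_train("f20", seed = 1)
tracks <- simulate_behavior_cohort(36, train, seed = 1)
prob <- response_probability(escape_matrix(tracks))
round(prob[1:11], 2)
#> 1.00 0.36 0.14 0.19 0.06 0.08 0.14 0.08 0.06 0.08 0.58
fit_one_phase_decay(prob[1:10])
#> One-phase decay fit: Y0 = 0.9995, K = 1.2160, plateau = 0.0902 (SSE 0.01289)
```

All 36 fish escape the first loom, the probability collapses within a few
looms (rate constant K ≈ 1.2 per loom toward a ≈ 0.09 floor), and it rebounds
to 0.58 at the 11th loom, right after the 5-minute rest — habituation with
partial spontaneous recovery.

```r
# imaging: simulate, classify, and build the loom-resolved graph
cohort <- simulate_cohort(
  cohort_config("f20", n_fish = 5, roi_counts = default_roi_counts(0.6)),
  seed = 11
)
zs <- zscore_traces(cohort$traces)
regs <- archetype_regressors(cohort$train)
motor <- lapply(cohort$motor_events, motor_regressor, n_timepoints = ncol(zs))
labels <- classify_rois(zs, regs, fish_id = cohort$rois$fish_id,
                        motor_regressors = motor)
mean(labels$label == cohort$rois$true_archetype)
#> 0.949

labels$region <- cohort$rois$region
gs <- graph_stage(cohort, labels, run_config(n_fish = 5, roi_scale = 0.6, seed = 3))
gs$metrics[gs$metrics$window %in% c("pre", "loom1", "loom3", "loom10", "loom11"), ]
#>  window edges_gt_cutoff    density mean_participation
#>     pre               5 0.03676471          0.0000000
#>   loom1             120 0.92647059          0.6224459
#>   loom3              52 0.38235294          0.3068384
#>  loom10              28 0.20588235          0.2140091
#>  loom11              98 0.72058824          0.5518975
```

Classification recovers 94.9% of the generator's archetype labels, and the
graph shows the study's signature trajectory: near-complete connectivity at
the first loom, progressive sparsification as habituation proceeds, and
substantial recovery after the rest.

```r
bc <- persistent_homology(gs$avg[, , "loom10"], max_dim = 1)
sum(bc$dimension == 1)        # 2 persistent loops in the habituated graph
lifetime_sum(bc, 1)           # 0.0107
```

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on synthetic
cohorts and write their tables under `results/`:

1. `01_simulate_cohorts.R` — imaging and behavior cohorts for f20, f60 and
   the WT/fmr1 pair on the two-block s20 train.
2. `02_behavior.R` — response probabilities, decay fits, genotype binomial
   tests.
3. `03_classify.R` — ROI classification, proportion tables, behavior
   correlations, motor-association selection.
4. `04_graphs.R` — nodes, correlation tensors, density/participation/edge
   metrics, leave-one-out, recovery matching, edge recovery deltas.
5. `05_communities.R` — γ/ω sweep, consensus partitions,
   flexibility/cohesion/promiscuity, Friedman genotype comparison.
6. `06_topology.R` — barcodes and lifetime sums per loom and genotype.

`run_pipeline()` wraps the same stages as one call with a manifest of output
hashes.

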