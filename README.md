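# olfnet

Graph-theoretic analysis of the resting-state human olfactory functional
network.

The olfactory system is unusually distributed: primary cortices receiving
direct olfactory-bulb input (piriform cortex, amygdala, entorhinal cortex,
olfactory tubercle, olfactory OFC) sit alongside limbic, insular, thalamic
and orbitofrontal regions serving emotion, homeostasis and high-level
integration. `olfnet` implements, as tested reusable R functions, the full
analysis chain that maps this system as a functional network from
resting-state fMRI:

1. **Cleaning** of ROI-averaged BOLD timeseries: per-run standardization,
   zero-phase 0.01-0.08 Hz Butterworth bandpass, regression of the
   24 motion nuisance parameters, and scrubbing of scans whose framewise
   displacement FD = |Δd_x| + |Δd_y| + |Δd_z| + |Δα| + |Δβ| + |Δγ| exceeds
   0.5 mm, plus voxel-level COV masking and participant-level QC.
2. **Network construction**: Fisher-z connectivity (z = atanh r), one-sample
   t-tests of each pair against its global whole-brain baseline, per-node
   proportional thresholding (top k = ⌊density·(N−1)⌋ connections per node,
   31 of 625 at the default 5%), and seeded admission — key olfactory
   regions are always retained, other ROIs join iff they hold at least one
   suprathreshold edge to a key region. A cross-modality control counts
   edges to a disjoint (e.g. visual) set at 5/10/15% density.
3. **Graph characterization**: Newman-Girvan modularity
   Q = (1/2m) Σ_ij (A_ij − k_i k_j / 2m) δ(c_i, c_j) via Louvain restarts
   and Girvan-Newman, permutation z-scores against degree-preserving
   rewired nulls, small-world index σ = (C/C_rand)/(L/L_rand), centralities
   with composite hub scores, participation coefficients
   P_i = 1 − Σ_s (k_is/k_i)², and node-deletion resilience.
4. **Behavioral linkage**: subject weighted networks (|r| masked by the
   group template), weighted clustering/efficiency, 2AFC odor-discrimination
   d′ = Φ⁻¹(hit) − Φ⁻¹(false alarm), and permutation-tested Spearman
   correlations, including group-matrix concordance and subject-to-group
   partition similarity (standardized Rand z-scores).

A synthetic-data module generates every input the real study measured —
multi-run ROI timeseries with a planted three-module covariance and
bridging hubs, motion traces with injected displacement spikes, 2AFC trial
records at a planted d′, and cohorts of subject matrices with a planted
clustering-behavior coupling — so the whole pipeline is exercisable and
testable with no scanner data. See the methods vignette
(`vignettes/olfactory-network-methods.Rmd`) for the model, parameter and
design details.

## Worked example

Run the full pipeline on the planted study scenario (three modules over
22 connected ROIs plus six decoupled candidates and 128 whole-brain filler
regions; sizes reduced from the 10,000-permutation defaults for a quick
run):

```r
library(olfnet)
cfg <- pipeline_config(
  seed = 1,
  simulate = list(n_subjects = 3),
  graphmetrics = list(n_restarts = 200, n_perm = 200, n_rand = 200),
  behavior = list(n_subjects = 64, trials_per_mixture = 100, n_perm = 2000))
res <- run_pipeline(cfg)
print(res)
#> Olfactory network pipeline result
#> Binary network: 22 nodes, 87 edges (density 37.7%)
#>   roles: key=6, rejected=6, secondary=16
#> Partition (louvain): 3 modules, Q = 0.4280
#>   modularity Z = 18.72 (cutoffs: Q > 0.3, Z > 3)
#> Small-world: C = 0.838 (rand 0.430), G = 0.680 (rand 0.687), L = 1.675 (rand 1.629), sigma = 1.894
#>   clustering~d' Spearman rho = 0.507 (p = 0.0004998)
```

Reading the output: the seeded admission recovered exactly the 16 planted
secondary regions (the six decoupled candidates were rejected), Louvain
found the three planted modules with modularity Q = 0.43, far above its
degree-preserving null (Z = 18.7 ≫ 3); clustering C exceeds its null while
efficiency G matches it, the small-world signature (σ = 1.89 > 1); and
across the 64 synthetic subjects, weighted clustering correlates with
odor-discrimination d′ (Spearman ρ = 0.51, permutation p ≈ 5·10⁻⁴ —
the planted coupling was 0.4).

Per-node metrics identify the planted connector hubs:

```r
head(res$node_metrics[order(res$node_metrics$composite_rank),
                      c("node", "degree", "composite_z", "composite_rank",
                        "participation", "deletion_impact")], 4)
#>    node degree composite_z composite_rank participation deletion_impact
#> 3   AMY     19   4.0384205       1.000000     0.6537396      13.6464968
#> 18 INSa     12   0.9714507       2.000000     0.5694444       1.4437367
#> 14 NAcc      9   0.2787265       3.333333     0.3703704       1.3853503
#> 17 Oapc      9   0.1914084       3.666667     0.1975309       0.5095541
```

The amygdala and anterior insula — the two generated bridging hubs — top
the composite centrality ranking, carry the highest participation
coefficients (connector hubs), and their removal costs the most global
efficiency.

A thin command-line wrapper (`exec/olfnet`) exposes the same stages as
subcommands (`simulate`, `preprocess`, `build-network`, `graph`,
`behavior`, `sweep`, `run-all`) over TSV/CSV/JSON files, configured by a
YAML file such as `inst/extdata/config_example.yaml`.

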