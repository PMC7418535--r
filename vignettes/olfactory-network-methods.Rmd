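---
title: "Methods: constructing and characterizing the olfactory functional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and characterizing the olfactory functional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`olfnet` implements a complete resting-state functional-connectome analysis
of the human olfactory system: it cleans ROI-averaged BOLD timeseries,
builds a group binary network seeded on the primary olfactory cortices,
characterizes the network's meso-scale organization (modularity,
small-world-ness, hubness, resilience), and links individual network
segregation to odor-discrimination sensitivity. This vignette explains the
models and procedures, the parameters that matter, the synthetic ground
truth the tests rest on, and the numerical choices made where the design
was genuinely open.

## The analysis model

### Timeseries cleaning

Raw input is a scans-by-ROI matrix per run with a known repetition time
(TR), plus a six-parameter rigid-body motion trace per scan. The chain is:

1. **Per-run standardization.** Each ROI's series is mean-centred and
   variance-normalized within each run before runs are pooled, so no run
   dominates the pooled correlation.
2. **Temporal bandpass, 0.01-0.08 Hz.** Resting-state coupling lives in
   slow spontaneous fluctuations; the band removes scanner drift (below
   0.01 Hz) and respiratory/cardiac aliasing (above 0.08 Hz). The filter
   realization is a zero-phase forward-backward Butterworth of order 4 —
   standard resting-state practice, chosen because the forward-backward
   pass leaves no phase distortion. Each run is filtered separately and
   demeaned first (DC sits below the passband anyway; removing it first
   suppresses forward-backward edge transients).
3. **24-parameter motion regression.** Least squares against the six
   motion parameters, the same six at the previous scan, and the squares
   of those twelve (plus an intercept). Residuals are orthogonal to the
   regressor span by construction; a rank-deficient design (e.g. motion
   recorded as zeros) falls back to the pivoted-QR pseudoinverse with a
   warning.
4. **Motion scrubbing.** Framewise displacement at scan *i* is
   FD(i) = |Δd~x~| + |Δd~y~| + |Δd~z~| + |Δα| + |Δβ| + |Δγ|, with
   rotations supplied already converted to millimetre equivalents (the
   common 50 mm sphere convention) so the 0.5 mm spike threshold is
   meaningful. Scans with FD > 0.5 mm are dropped, not interpolated.

The order bandpass-then-regression follows the listed cleaning sequence;
because the evidence on ordering is genuinely mixed in the field, the
reverse order is available via `bandpass_first = FALSE` and the scrubbing
mask is unaffected by the choice.

Two quality-control operations accompany the chain. Voxel-level COV
masking excludes a voxel when its coefficient of variation exceeds the
Gaussian-weighted (σ = 5 mm) neighborhood mean by more than 0.5
neighborhood SDs — a local rule, so regionally different but internally
homogeneous ROIs lose nothing. Participant-level QC excludes a
participant when any ROI has fewer than 50 voxels, is missing more than
60% of its anatomic voxels, or has temporal SNR (mean/SD over time) more
than 3 SDs below the sample mean for that ROI; the olfactory tubercle, a
very small structure, is exempt from all three rules. Note the 3-SD rule
cannot fire in cohorts smaller than ~11, since the largest attainable
|z| in a sample of n is (n−1)/√n.

### Network construction

Pairwise Pearson correlations over retained scans are Fisher
z-transformed (`atanh`); correlations at |r| ≈ 1 are capped just below 1
rather than mapped to infinity, and zero-variance ROIs are flagged as
`NA` rather than silently zeroed. The group matrix is the mean of
subject z-matrices.

Thresholding is proportional and per node: within the whole-brain
context matrix each node keeps its k = ⌊density · (N−1)⌋ strongest
connections (31 of 625 at the default 5%); an ROI pair is suprathreshold
when it is kept from **at least one** endpoint. This union rule is the
symmetrization we adopt because it converts the per-node rule into a
symmetric adjacency without discarding any marked connection; the
stricter both-endpoint rule is available (`rule = "and"`). Rank ties are
broken by partner-name lexicographic order so results are deterministic.
Note that with the floor rule k ≤ N−2 for any density strictly below 1,
so the thresholded graph is never complete.

Each pair also carries a one-sample t-test across subjects of its Fisher
z against the pair's *global baseline* — the mean of the two nodes' mean
connectivity to all other whole-brain regions. The operative edge
criterion defaults to the top-5% rule alone, with the t-test reported
alongside; a conjunction mode (top-5% **and** baseline-exceeding at
α = 0.05) is available and is what makes admission exact on planted data,
because proportional thresholding always marks k connections per node
even for a node with no real coupling, whereas such noise edges cannot
beat the node's own baseline systematically.

The network itself is seeded: the six key olfactory regions (anterior
and posterior piriform cortex, amygdala, entorhinal cortex, olfactory
tubercle, olfactory OFC) are always retained, and each of the remaining
candidate ROIs is admitted iff it has at least one suprathreshold edge
to a key region. The result is the induced subgraph over retained nodes,
with node roles recorded. A cross-modality control counts suprathreshold
edges between the network and a disjoint control set (e.g. visual
parcels) at 5/10/15% density; decoupled sets should show none at 5%.

### Graph characterization

All quantities are computed from explicit closed forms (igraph supplies
shortest paths, betweenness, Louvain/Girvan-Newman moves and
degree-preserving rewiring underneath):

* **Modularity** Q = (1/2m) Σ~ij~ (A~ij~ − k~i~k~j~/2m) δ(c~i~,c~j~).
  Louvain is run with seeded randomized restarts (default 10,000; the
  best-Q partition is kept, ties to the first found); Girvan-Newman
  removes highest-edge-betweenness edges and returns the dendrogram level
  maximizing Q. A partition is considered strong when Q exceeds 0.3 and
  its permutation z-score exceeds 3.
* **Permutation null.** "Random reassignment of connections" is read as
  degree-preserving (Maslov-Sneppen) rewiring, with an Erdős-Rényi
  alternative (`null = "erdos_renyi"`) since the looser reading is also
  defensible; each null graph is re-partitioned with the same algorithm.
  Null partitioning uses a reduced restart count (default 10) — the null
  needs the typical attainable Q, not an exhaustive search, and the
  observed partition's budget would be wasted there.
* **Small-world-ness.** C (mean triangle fraction), G (mean inverse
  shortest-path length; disconnected pairs contribute 0) and L (mean
  finite path length) on the network, against null means over rewired
  graphs. The summary index is σ = (C/C~rand~)/(L/L~rand~), the
  path-length-based criterion with σ > 1 marking the small-world regime;
  G and G~rand~ are reported alongside because efficiency is the
  integration measure the analysis interprets.
* **Hubness.** Degree, betweenness (Brandes fractional counting,
  endpoints excluded, normalized) and closeness (reciprocal mean
  distance; per reachable set, with a warning, when disconnected) are
  z-scored across nodes and averaged into a composite z, and their
  descending ranks averaged into a composite rank. Zero-variance metrics
  contribute 0 with a warning.
* **Participation coefficient** P~i~ = 1 − Σ~s~ (k~is~/k~i~)²: 0 for
  provincial nodes, toward 1 for connector hubs.
* **Resilience.** Each node is deleted in turn and the percentage drop in
  G recorded; deletion may disconnect the graph, which G tolerates.
* **Partition similarity** uses the standardized pair-counting Rand
  score: z = (w − E[w])/SD[w], with the permutation-null moments in
  closed form. The implementation was checked against exhaustive
  enumeration of all label permutations on six-node instances.

Weighted variants (used at the subject level) take edge length 1/weight
for paths and the Onnela geometric-mean triangle form for clustering,
normalized by the maximum weight and using binary-support degrees — the
conventions of the standard brain-connectivity toolboxes; both reduce
exactly to the binary forms on 0/1 weights.

### Behavioral linkage

Subject weighted networks are |r| masked by the group binary template
(absolute correlations index coupling strength regardless of sign).
Odor-discrimination sensitivity comes from a 2AFC task over five binary
mixtures; d′ = Φ⁻¹(hit) − Φ⁻¹(false alarm) uses only the two extreme
mixtures (80/20 and 20/80), with perfect rates replaced by 0.5/n and
(n−0.5)/n so 15-trial blocks stay finite. The correction convention was
chosen to apply only at the boundary, leaving interior rates untouched.
Associations use Spearman rank correlation with a permutation test
(default 10,000 permutations, one-tailed at the 95th percentile, the +1
continuity correction applied; two-tailed available). Group-matrix
concordance correlates the unique off-diagonal entries of two matrices
over a designated edge set (default: the template's edges; Pearson R is
reported alongside because both conventions appear in practice).

## The synthetic ground truth

The generator plants a known correlation structure and produces
everything a real study would have measured:

* **Modular timeseries.** Zero-mean unit-variance Gaussian signals with
  within-module correlation 0.5, between-module 0.1 (defaults), mixed by
  the Cholesky factor of the implied matrix, which is checked for
  positive definiteness and **rejected** — never silently repaired —
  when infeasible, because a repaired matrix would invalidate
  ground-truth recovery tests. An optional AR(1) coefficient (default
  0.3 in the pipeline scenario) gives the signals band-limited content
  for the bandpass stage to act on without touching cross-node
  correlations. Signals are white by default in the standalone
  generator: the simplest model satisfying the pipeline's assumptions.
* **Hubs.** Designated hub nodes get cross-module correlation at the
  midpoint of the intra and inter values (0.3 by default): enough to
  dominate every centrality at generation scale while keeping the
  planted hierarchy (intra > hub > inter) and positive definiteness.
* **The study scenario** mirrors the published network composition: 28
  ROIs named after the real parcels, three modules (sensory, limbic,
  frontal) covering 22 of them with the six key regions distributed
  among the modules, amygdala and anterior insula as hubs, and six
  decoupled candidates the admission rule must reject. Whole-brain
  context is emulated by 128 filler regions (about five times the ROI
  count; the real context is a 627-parcel atlas) that carry the
  between-module correlation level with all connected nodes — real
  whole-brain parcels couple diffusely at roughly that level, and
  silent (zero-correlation) fillers would let every weak between-module
  ROI edge outrank them at high densities, which no real ranking context
  does.
* **Motion** is a heavily smoothed low-amplitude random walk per
  parameter with step-displacement spikes injected at chosen scans,
  aligned with the local baseline delta so the framewise displacement at
  a spike is guaranteed to reach the spike size.
* **2AFC responses** come from an equal-variance Gaussian observer with
  the planted d′ at the extreme mixtures and sensitivity scaled linearly
  in the dominant-component proportion for the middle mixtures (a
  generator convention — the middle mixtures never enter d′).
* **Cohorts** centre each subject's correlation matrix on a group matrix
  (supplied, or drawn per edge) plus Gaussian noise, and set each
  subject's true d′ through a Gaussian copula on the rank of their
  weighted clustering, with the latent Pearson correlation chosen as
  2·sin(πρ/6) so the *population Spearman* correlation equals the
  requested coupling exactly. No empirically established generative
  model links network metrics to behavior; this construct exists purely
  for power and recovery testing.

What the generator does **not** emulate: voxel-level volumetric
structure, physiological (cardiac/respiratory) noise, scanner-specific
artifacts, spatial autocorrelation between parcels, and non-Gaussian
BOLD marginals. Passing recovery tests therefore demonstrates that the
pipeline's inference chain is correct under its own statistical
assumptions, not that those assumptions hold in any given scanner
dataset.

## Reproducibility and problem sizes

Every random stage draws its seed from the single top-level seed through
named substreams (`substream_seed`), so stages are reproducible in
isolation and a change in one stage's consumption cannot silently shift
another's draws. Identical configurations give bit-identical artifacts;
the run manifest records per-stage wall-clock and MD5 checksums.

The test-suite and acceptance-script scenarios run at deliberately
reduced sizes, chosen as the package's own trade-off between statistical
resolution and turnaround: group samples of 3-6 subjects (the planted
margins are wide enough that the baseline t-test resolves them at n = 3),
null ensembles of 50-500 draws where the defaults are 10,000, Louvain
restart counts of 100-200 where the default is 10,000, and cohorts of
64-500 subjects. The planted effects are large by design, so these sizes
keep all recovery probabilities near 1 while every default remains at
its full-scale value in `pipeline_config()`.

## Known limitations

* Closeness on disconnected graphs is a per-reachable-set convention;
  comparisons across graphs with different component structure need
  care.
* The σ index inherits the usual sensitivity of small-world indices to
  density; the density sweep (4-10%) is the package's guard against
  reading σ at a single arbitrary threshold.
* The permutation z-score for modularity depends on the null family;
  degree-preserving rewiring is the default and the Erdős-Rényi variant
  typically yields larger Z on the same graph.
* Proportional thresholding guarantees k marked connections per node
  even for decoupled nodes; exact recovery of a planted admission set
  therefore requires the conjunction mode, and the default
  top-density-only mode should be read as topology-permissive.
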