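---
title: "Methods: synthetic CCD connectomes and their network analysis"
author: "ccdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic CCD connectomes and their network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdnet)
```

## Scope and model

`ccdnet` analyses weighted structural connectomes of the mouse brain under
four callosal conditions: a normal corpus callosum (CC), complete corpus
callosum dysgenesis (CCD), partial CCD, and a *virtual callosotomy* — an
in-silico control in which callosal edges are deleted from normal networks
without any compensatory rewiring, so that differences between CCD and this
control can be attributed to reorganization rather than mere absence of the
callosum.

A connectome here is a symmetric 76 × 76 matrix over a bilateral
parcellation of 38 regions per hemisphere, with zero diagonal and edge
weights in (0, 1) interpreted as mean fractional anisotropy (FA) along the
reconstructed tract. Absent edges are stored as exact zeros; any weight
strictly greater than zero denotes presence.

## The synthetic cohort generator

Because the analysis pipeline is exercised without access to diffusion MRI
data, the package ships a generator whose defaults *are* the study
conditions: ten subjects per condition, FA-like weights, and
condition-specific rewiring. Each condition has a deterministic **template**:
an edge list with mean weight, tract tag (`intra`, `cc`, `ac`, `pc`, `hc`,
`probst`, `sigmoid`), presence probability and weight-noise SD. Subjects are
sampled independently: each edge is kept with probability
`presence_prob × edge_consistency[tract_tag]`, and kept edges receive a
truncated-normal weight about the template mean (SD 0.05, truncated to
(0, 1)). Sampling is a pure function of `(rng_seed, subject_index)`, with
per-subject streams derived from the master seed, so cohorts are exactly
reproducible and the virtual-callosotomy cohort shares every non-callosal
draw with its paired normal cohort bit for bit.

Topology choices, made once on anatomical grounds and exposed in
`cohort_config()`:

* **Intrahemispheric wiring.** A deterministic pseudo-random subset of node
  pairs, mirrored across hemispheres and identical in every condition: 80%
  of within-lobe pairs (mean weight 0.50) and 30% of between-lobe pairs
  (mean weight 0.22). Subcortical grey-matter groups are wired at half the
  within-lobe density and slightly lower weight — cortical lobes are the
  tightly clustered units. Cortical association hubs (frontal association
  cortex, claustrum, secondary motor cortex) receive denser between-lobe
  wiring (45% of pairs), giving the normal brain high-degree nodes whose
  edges span modules.
* **Commissures.** Homotopic callosal (`cc`) edges connect the neocortical
  pairs (weight 0.50); olfactory/amygdalar pairs route through the anterior
  commissure, hippocampal/subicular/entorhinal pairs through the hippocampal
  commissure, and midbrain pairs through the posterior commissure (weights
  0.45/0.40). These non-callosal commissures are identical in every
  condition, matching the observation that their projections do not differ
  between callosal phenotypes.
* **Complete CCD.** All `cc` edges are absent. Probst-bundle edges connect
  the frontal association cortex to six ipsilateral posterior areas (visual,
  auditory, parietal association) in both hemispheres at elevated weight
  (0.55) and full presence — the bundle projects consistently. Between-lobe
  wiring presence drops to 80% of the control value, reflecting the greater
  subject-to-subject variability of rerouted long-range connectivity, and
  weight noise is scaled by 1.3.
* **Partial CCD.** An anteriorly biased callosal remnant (30% of `cc` edges,
  ranked by an ordinal anteroposterior score, ties broken by node index)
  with low consistency (0.6); reduced Probst edges (presence 0.5,
  consistency 0.85); and the asymmetric sigmoid bundle: left frontal
  association → right hippocampus with presence probability equal to the
  penetrance parameter (default 0.5, i.e. five of ten mice), plus a weaker
  left frontal association → right parietal association edge (presence 0.2).
  Carriers are recorded in the cohort metadata.
* **Weight heterogeneity.** Template means carry a deterministic per-edge
  perturbation (±0.08) computed as a pure hash of the node pair, so edge
  weights are heterogeneous yet identical for edges shared between condition
  templates; between-condition edge-wise tests therefore see differences
  only where conditions genuinely differ.

What the generator does **not** emulate: voxel-level tractography and its
distance/curvature biases, spatially correlated noise between neighbouring
edges, anatomical coordinates beyond the ordinal lobe layout, and
weight–degree coupling found in real FA networks. Tests that pass on these
cohorts validate the pipeline's statistical machinery and its directional
behaviour under known rewiring; they are not evidence about any particular
real dataset.

## Connectome construction from seed maps

For workflows that start from per-seed voxel connectivity maps,
`build_connectome()` applies a two-step rule: a candidate pair is proposed
when the ratio of summed connectivity over the target's voxels to the
target's voxel count is greater than zero in either direction, and confirmed
only when both directions pass the same test on maps masked to the pair
(`retain_connection()`). Confirmed edges are weighted by the mean FA over
voxels whose pair-map connectivity exceeds 0.001 (`edge_weight_fa()`). In
this synthetic path, step 2 reuses the step-1 maps masked to the pair rather
than re-simulating streamlines — a documented simplification; toy label
volumes are generated pre-eroded, so perimeter erosion and midline exclusion
ROIs belong to the (out-of-scope) imaging path.

Group **consensus connectomes** (`build_consensus()`) keep edges present in
at least half the subjects — "present in half" is read inclusively as
⌈n/2⌉ — and weight kept edges by the mean over carriers only. Averaging
zeros in would conflate prevalence with strength and break the FA semantics
of the weight; the fraction is configurable.

## Graph measures over proportional thresholds

Networks are proportionally thresholded at sparsities 0.05–0.13 (step 0.01):
at sparsity *s* the top `round(s·n(n−1)/2)` edges by weight are kept
(round-half-even; ties at the cutoff broken by stable node order), so all
conditions are compared at identical density. Each measure is computed at
every threshold and summarized by the trapezoidal area under the curve —
on this uniform grid a rectangle rule would differ only at the endpoints.

Definitions, with edge length taken as the reciprocal of weight
(configurable to −log w; the reciprocal is the standard choice for
FA-weighted connectomes):

* **Strength**: sum of incident edge weights.
* **Betweenness**: percentage of shortest paths between other node pairs
  passing through the node.
* **Clustering**: Onnela's weighted form, geometric-mean triangle intensity
  over max-normalized weights; zero below degree 2.
* **Global efficiency**: harmonic form, the mean reciprocal shortest-path
  distance with 1/∞ = 0 — finite on disconnected graphs, where a plain
  "inverse mean path length" is ill-defined (CCD networks disconnect at
  strict thresholds).
* **Local efficiency**: global efficiency of each node's neighbour-induced
  subgraph.

Group comparisons of per-subject AUCs use unpaired two-tailed tests gated on
a D'Agostino–Pearson omnibus normality check (implemented from the K²
formulas; sample sizes below 8 fall back to Shapiro–Wilk): Student's t when
both samples pass, in the Welch form when an F test finds unequal variances,
otherwise Mann–Whitney U. The Welch gate is applied to every measure alike.
Families of measures are corrected by Holm–Šidák step-down, implemented
directly since base R offers Holm–Bonferroni only.

## Community structure, participation, hubs

`louvain()` maximizes weighted modularity with resolution γ:

$$Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \gamma\frac{k_ik_j}{2m}\right]\delta(c_i,c_j)$$

using 20 seed-shuffled restarts and keeping the best-Q partition (ties
broken by the shuffle, deterministic given the seed). The default γ = 1.2
was optimized for modularity on normal-CC consensus networks and is applied
unchanged to every condition; `gamma_sweep()` reproduces that optimization
step. Modules are detected on the per-condition consensus connectome.
`consensus_partition()` stabilizes repeated runs through the co-assignment
matrix. Participation follows Guimerà–Amaral,
$P_v = 1 - \sum_m (s_{vm}/s_v)^2$; hubs are nodes at or above the 0.8
strength quantile, split into connector (P ≥ 0.5) versus provincial hubs —
the cutoffs are conventions, both configurable, since no standard exists.

Under the default generator, the designed hub architecture is recovered:
normal-CC consensus networks show a positive correlation between nodal
strength and participation (association hubs are connectors), while complete
CCD inverts it — with callosal edges gone, the surviving cross-module nodes
are low-degree commissural subcortical regions. This sign pattern is the
least robust of the package's directional checks: it depends on the module
granularity that Louvain resolves at γ = 1.2, and flattens when between-lobe
wiring is made heavier than the defaults.

## Network-based statistic

`nbs_test()` computes edge-wise pooled-variance two-sample t statistics
(one-sided, oriented by the requested contrast; edges with zero variance in
both groups are uninformative and set to 0), extracts connected components
of the suprathreshold graph (t > t*), and compares each component's **edge
count** against the permutation null of the maximal component size under
full subject relabeling. P-values use the +1 correction,
p = (1 + #{null ≥ size})/(P + 1), so they are never zero and never below
1/(P+1). Component size as extent (not intensity) matches how the flagged
subnetworks are reported; duplicate permutations are allowed, as in standard
Monte-Carlo NBS. The test runs on raw weighted matrices (not
sparsity-thresholded ones), the NBS convention. `threshold_sweep()` repeats
the test over primary thresholds 2–5 and counts, per edge, the thresholds at
which it fell in a significant component (0–4). The permutation engine is
vectorized across permutations (matrix products over an edges × subjects
stack), which keeps the 200-replicate null calibration
(`nbs_fwer_null()`) at roughly a minute.

## Variability and novel connections

Edge variability is the coefficient of variation across subjects
(`edge_normalized_sd()`). Network similarity (`pairwise_similarity()`) is
the Pearson correlation (Spearman optional) between two subjects'
edge-weight vectors over the union of edges present in at least one of the
two, computed for the whole network and for inter-/intrahemispheric edges
separately; each subject is summarized by the mean of its n−1 pairwise
correlations, and the cohort by the mean ± SEM of those values. Restricting
to the per-pair union (rather than including all structural zeros, which
inflates r, or the consensus mask, which discards subject-specific edges) is
a documented choice; with interhemispheric edges removed the whole-network
value equals the intrahemispheric value exactly, mirroring how the
whole-network similarity is a presence-weighted blend of the two classes.
Note that the union restriction makes independent *sparse* networks
anti-correlate (present-vs-absent mismatches dominate); the unbiasedness
null holds for dense networks.

Novel connections (`discover_novel_edges()`) are edges present in at least
two case subjects (20% penetrance at n = 10) and absent from every control
subject, evaluated on unthresholded individual connectomes since the rule
precedes thresholding in the workflow; preserved connections are edges in
both cohorts' consensus networks. On default partial-CCD cohorts the rule
recovers the planted sigmoid bundle with its generator-recorded carrier
count.

## Numerical and reproducibility choices

* Matrices are validated on read: square, labeled, non-negative, symmetric
  within 1e−9 (then symmetrized exactly), zero diagonal.
* All stochastic stages (sampling, Louvain restarts, permutations) consume
  explicit integer seeds; `run_pipeline()` derives every stage seed from one
  master seed and writes a manifest with config snapshot and MD5 hashes, so
  a rerun reproduces artifacts bit for bit.
* Degenerate inputs: empty graphs have zero efficiency and density;
  isolated nodes have zero betweenness, clustering and participation;
  a sparsity request beyond the available edges keeps all edges with a
  warning; a single-threshold grid is an error for AUCs.
* Test problem sizes: metric oracles run on graphs of ≤ 8 nodes against
  exhaustive path/triangle enumeration (100 seeds); the NBS null calibration
  uses 200 replicate cohort pairs with 1000 permutations at t* = 3; planted
  Louvain benchmarks use the 4 × 19-node design at p_in = 0.6 / p_out = 0.05
  over 20 seeds. These sizes make the full suite run in a couple of minutes
  while keeping every check at its stated power.

## Known limitations

* The generator's presence/weight factorization cannot produce correlations
  between edge presence and subject-level global effects (e.g. whole-brain
  FA shifts).
* The degree–participation sign recovery depends on module granularity, as
  noted above.
* `build_connectome()`'s step 2 masks step-1 maps instead of re-running
  pair-constrained tractography; with real voxel data the two differ.
* Whether both regions of a pair must pass the retention ratio (the choice
  here) or either suffices is ambiguous in the source procedure; the
  conjunction is stricter and configurable in spirit — passing pre-filtered
  candidate pairs reproduces the disjunctive reading.
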