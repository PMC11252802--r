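---
title: "Discovering GRN cell states: models, parameters, and design choices"
author: "grnstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering GRN cell states: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`grnstates` implements a pipeline for defining tumor cell states from
single-cell RNA-seq by the activity of *regulons* — transcription factors
with their target-gene sets — rather than by raw expression clusters. The
motivating application is treatment-resistant prostate cancer, where
AR-driven adenocarcinoma, inflammatory, WNT, embryonic/EMT and
neuroendocrine (ASCL1/NEUROD1) programs coexist across and within
patients, and where cell-surface antigen expression (PSMA, STEAP1/2,
TROP2, CEACAM5, DLL3) tracks those programs. Regulon *inference* (motif
pruning, co-expression networks) is deliberately out of scope: regulons
enter as curated gene sets in GMT format, and the package takes over from
there.

The pipeline stages are:

1. **Ingest and normalize.** Counts (10x-style MTX triplet or CSV) are
   log-normalized per cell: `log(1 + s·c/total)`, natural log, pseudocount
   1. The scale factor `s` (default `1e4`) is a convention, not a
   statement about the data; it is exposed in `analysisConfig()` because
   it only moves profiles by a cell-wise monotone map, which the
   rank-based scoring downstream ignores entirely.
2. **Regulon activity.** AUCell-style recovery-curve AUC per cell and
   regulon, normalized by the maximal attainable curve so activities live
   in [0, 1].
3. **GRN discovery.** Ward clustering of cells on z-scaled activities;
   the number of states is picked by a resampling-stability adjusted Rand
   index (ARI) criterion; regulons are attached to states by the regulon
   specificity score (RSS) with permutation significance.
4. **Heterogeneity.** Graph clustering of cells plus cluster-balanced,
   resampled Shannon entropy of patient frequencies.
5. **Marker statistics.** Lin's concordance correlation, exact Wilcoxon
   tests, hurdle differential expression, Fisher overlap tests, and
   diffusion imputation for antigen summaries.

# The activity score and its assumptions

For a cell with `n` genes and a regulon with `m` genes present, genes are
ranked by descending log-normalized expression and the score integrates
the recovery curve over the top `T = ⌈f·n⌉` ranks:

```
AUC_raw = Σ_{r=1..T} hits(r),    activity = AUC_raw / Σ_{r=1..T} min(r, m).
```

The top fraction `f` defaults to 0.05, the convention of the SCENIC
family; it is the single most influential parameter of the stage and is
therefore a first-class configuration value. The score assumes only that
a regulon's activity manifests as its targets crowding the top of a
cell's ranking — it needs no distributional model and is invariant to any
monotone transform of the cell's values (a property the test suite checks
explicitly).

Sparse counts make ties abundant, so tie-breaking is explicit: the
default breaks ties by a seeded random permutation shared by all cells of
one scoring call; `tieMethod = "stable"` (deterministic order by gene
position) is available for exact reproducibility against the brute-force
oracle. A regulon with *no* genes present cannot be scored and is
reported `NA` with a warning — never 0, which would fake evidence of
absence.

The heatmap view is z-scored per regulon across cells and clipped to
±2 (`zclip`); clipping bounds the influence of extreme cells on the
Euclidean geometry used for clustering. Constant regulons map to 0.
Z-scaling is performed within the analyzed cohort (not jointly across
cohorts), and the choice is recorded in the run log.

# Choosing the number of GRNs

The dendrogram (Ward linkage on Euclidean distances; neither metric nor
linkage is canonical, but Ward on standardized features is the common
default and keeps clusters compact) is cut by a stability criterion:

* for each candidate `k` in `kRange` (default 2–15): take the full-data
  partition `P_k`; recluster `nResamples` (default 20) random 80% subsets
  and compute the ARI between the subset reclustering and `P_k`
  restricted to the subset;
* choose the `k` with maximal mean ARI, ties toward smaller `k`; record
  the whole profile (`ariProfile()`) so the decision is auditable; set
  the cut height to the midpoint of the height interval realizing `k`.

The rationale: if the data contain `k*` well-separated states, partitions
with `k < k*` are unstable because which states get merged depends on the
subsample, and `k > k*` is unstable because splitting within a state is
arbitrary; `k = k*` reclusters reproducibly. On the package's planted
five-state cohorts the profile is near-flat at 1.0 exactly at the true
`k` and visibly lower elsewhere. Degenerate inputs (all cells identical)
return a single GRN with an empty profile and a warning rather than an
error, since a pipeline should survive a pathological subset.

ARI itself is computed from the contingency-table closed form and is
tested against brute-force pair counting; the degenerate case where the
maximal index equals its expectation (e.g. both partitions all
singletons) is defined as 1 for identical partitions and 0 otherwise.

# Regulon specificity and significance

RSS compares a regulon's activity, normalized to a probability
distribution over cells, with the uniform indicator distribution of a
GRN, via the Jensen–Shannon divergence with **base-2 logarithms**, so JSD
∈ [0, 1] and `RSS = 1 − √JSD` ∈ [0, 1]: exactly 1 when activity is the
uniform indicator of the GRN, exactly 0 when activity is supported
entirely outside it. Raw (non-negative) activities are required — the JSD
construction does not admit the signed z-scaled view. RSS is invariant to
positive rescaling of a regulon's activity vector.

Ranking "by significance" is implemented as a label-permutation test
(default 1000 permutations; fewer than 100 triggers a resolution
warning), with Benjamini–Hochberg adjustment across regulons within each
GRN, and regulons ordered by RSS within GRN. Empirical p-values use the
add-one convention `(1 + #{perm ≥ obs})/(nPerm + 1)`, so they are never
exactly 0.

Robustness of a partition is probed by leave-one-unit-out reclustering
(units are typically patients): cells of one unit are dropped, the rest
reclustered at the same `k`, and the ARI against the original partition
restricted to retained cells is reported. A state private to a removed
patient disappears by construction; its cells are absent from the
restricted comparison, which is the intended reading.

# Patient-diversity entropy

Cells are clustered by a PhenoGraph-style pipeline: PCA (30 components),
kNN graph (`k = 30`), shared-neighbour Jaccard weights
(`scran::buildSNNGraph`), Louvain modularity (resolution 1.0, seeded).
Per cluster, `nPerCluster = 100` cells are drawn **with replacement**
`nReps = 100` times and the Shannon entropy (natural log; the base only
rescales and every downstream comparison is rank-based) of the patient
frequencies of each draw is kept. Resampling with replacement means
clusters smaller than 100 cells are handled uniformly rather than
excluded. The resampled mean converges to the plug-in entropy of the true
cluster composition as the draw size grows — the suite checks 100 versus
10,000.

Group comparisons use a two-sided Wilcoxon test on per-cluster mean
entropies. The cluster sets of two disease categories are unpaired, so
the rank-sum form is the default; the signed-rank form exists for
genuinely paired designs. Small samples (rank-sum `n_x + n_y ≤ 12`,
signed-rank `n ≤ 15`) use exact enumeration of the permutation
distribution, which stays exact under ties (base R's exact path does
not); larger samples use the tie-corrected normal approximation.
Significance tiers follow the conventional `*` < 0.05, `**` < 0.01,
`***` < 0.001, `****` < 1e-4 mapping.

# Marker statistics

**Lin's CCC** uses population (1/n) moments,
`CCC = 2s_xy/(s_x² + s_y² + (x̄−ȳ)²)`, with the 95% CI from Lin's
Fisher-z asymptotic variance. `|CCC| ≤ |r|` always, with equality when
means and variances agree — both facts are exercised in tests. Zero
variance in both inputs is an error, not a silent NA.

**Hurdle differential expression** is a deliberately reduced two-part
model: a detection component (2×2 binomial likelihood-ratio test of
detected/undetected against group) plus a continuous component (Gaussian
LRT on log-normalized expression among detected cells), combined by
summing chi-squares and degrees of freedom, dropping a component when it
is inestimable (detection constant; detected cells in one group only).
It intentionally omits a full MAST-style framework — no cellular
detection rate covariate, no shrinkage — because the downstream use is
gene-level log2FC plus an adjusted p. The fold change is
`log2((mean_A + 1)/(mean_B + 1))` on de-logged normalized means; the
pseudocount keeps detection-only genes finite and differs from MAST's
model-based fold change (a documented divergence). The adjustment for
"adjusted p" is Benjamini–Hochberg — the multiple-testing companion MAST
users conventionally apply — and is exposed rather than hard-wired.
Under a null split of one simulated population the type-I error is
checked to sit within two binomial standard errors of nominal at 0.01
and 0.05 over 2,000 genes.

**Overlap testing** is the one-sided hypergeometric tail
`P(X ≥ |A∩B|)` with the sample odds ratio from the 2×2 table; it is
validated against exhaustive enumeration for universes up to 12.
Cross-cohort comparison thresholds each cohort at `log2FC > 0.4` and
`p_adj < 0.05` (both configurable), intersects, and tests the overlap on
the common gene universe.

**Diffusion imputation** builds the cell kNN graph (Euclidean over 20
principal components; dimensionality precedes the graph because raw
log-space distances are noise-dominated), applies an adaptive Gaussian
kernel with bandwidth the distance to the `⌈k/3⌉`-th neighbour and
self-affinity 1, symmetrizes by the mean, and row-normalizes to a Markov
matrix; `t` steps mix each cell's profile with its neighbourhood
(`t = 0` is the identity). Row-stochastic averaging keeps every imputed
value inside the gene's observed range. Coincident neighbourhoods
(bandwidth 0) fall back to uniform weights over the zero-distance cells,
which makes a dataset of identical cells an exact fixed point. With
`k = 1` and two distinct cells the kernel gives self weight 1 and
neighbour weight `e^{-1}`, i.e. Markov rows `(1, e^{-1})/(1 + e^{-1})` —
the two-cell case in the tests is frozen to this hand-derived matrix.

# The synthetic cohort: what it does and does not emulate

The generator is the package's ground truth and its defaults are the
study conditions used by the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `nStates` | 5 | planted regulon-defined states |
| `cellsPerState` | 120 | 600 cells total |
| `genesPerRegulon` | 30 | targets per planted regulon |
| `nBackgroundGenes` | 440 | 590 genes total |
| `regulonEffect` | 8 | fold-up of targets in the owning state |
| `baselineMean` | 0.5 | NB mean, sparse scRNA-like counts |
| `dispersion` | 10 | NB size |
| `patientAlpha` | 5 | Dirichlet concentration (per state) |
| `nPatients` | 8 | cohort size |

Counts are negative binomial; dropout arises naturally at low means, so
no zero-inflation component is added — sufficient for rank-based scores,
and one fewer parameter to justify. Patient structure is Dirichlet:
α = 0.05 concentrates a state in one patient (the patient-specific, low
entropy regime), α = 50 spreads it evenly (shared, high entropy). Antigen
coupling is multiplicative on the mean in the owning state, mirroring the
qualitative couplings of surface antigens to regulatory states (a
PSMA-like gene up in the AR-like state; a DLL3-like gene up in an
ASCL1-like state and lower in a NEUROD1-like one). The entropy-contrast
fixture uses 12 states × 50 cells with six states per α regime so that
the exact rank-sum comparison (6 vs 6 clusters) can reach p < 0.01.

The TMA generator draws each marker pair from a shared latent plus
independent noise; the latent variance is solved in closed form from the
target concordance (`σ_L² = ρσ_e²/(1−ρ)`), which forces equal means and
variances within a pair so the population CCC equals the planted ρ.
Pairs chained through an already-generated marker are extended
conditionally at the same population correlation. All H-score markers
share one scale (mean 100; total sd from the strongest pair's
calibration) because CCC is only calibrated under equal moments;
Ki-67-type markers sit at half scale on [0, 100], which preserves Pearson
targets but not cross-scale CCC. Clipping to the score range can shrink
the realized CCC slightly; the tests therefore allow ±0.05 at n = 500
cores. The default panel plants the package's three design points:
INSM1~ASCL1 at CCC 0.86, SYP~ASCL1 at 0.52, EZH2~Ki-67 at Pearson 0.73.

What the generator does **not** emulate: gene-length/GC bias, doublets,
batch or site effects, ambient RNA, zero-inflation beyond NB sparsity,
spatial or histology-linked marker structure (histology mean shifts
exist but are off by default). Passing tests therefore demonstrate the
*correctness of the machinery* under a faithful null and planted-effect
model, not robustness to every artefact of real cohorts; on real data
the ARI profile may be flatter and the chosen `k` should always be read
together with its exported profile.

# Reproducibility and problem sizes

A single master seed fans out to per-stage seeds by a stable string hash
of the stage name (`stageSeed()`), so adding a stage never perturbs the
randomness of existing ones and every pipeline run is byte-identical
given (config, inputs, seed). The test suite and `scripts/acceptance.R`
use 600-cell/590-gene cohorts for discovery (swept over 20 seeds),
2,000-gene nulls for DE calibration, and 500-core panels for the
concordance checks — sizes chosen so the full suite completes in a few
minutes on one CPU while keeping every check's sampling error well below
its decision threshold.

# Known limitations

* Regulon inference is out of scope by design; results are conditional on
  the supplied gene sets.
* The stability criterion selects a *reproducible* `k`, which on weakly
  separated data can be smaller than the biological truth; inspect
  `ariProfile()` rather than trusting the argmax blindly.
* The hurdle model omits covariates (e.g. cellular detection rate); a
  covariate hook in the interface is the natural extension point.
* Lin's Fisher-z CI is asymptotic; for very small panels a bootstrap is
  preferable.
* XLSX H-score sheets are not read directly; export to CSV/TSV first.
* Diffusion imputation recomputes a dense cell-cell distance matrix and
  is intended for cohort-scale (thousands of cells), not atlas-scale,
  inputs.
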