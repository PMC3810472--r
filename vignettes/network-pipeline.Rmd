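---
title: "Methods: graph-theoretical analysis of resting-state connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretical analysis of resting-state connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`restnet` implements a whole-brain resting-state functional-connectivity
analysis on binary graphs, comparing a patient group against controls at
three scales: voxel-level degree centrality, an intermediate scale of
network modules, and global small-world topology. This vignette is the
package's account of the methods: the models and formulas, the tunable
parameters and their defaults, the numerical choices, what the synthetic
cohort generator does and does not emulate, and the known limitations.

## Pipeline overview

For each subject the pipeline consumes a 4D BOLD volume (already
spatially preprocessed and aligned), a six-parameter rigid-body motion
trace, and an integer label atlas shared across subjects. Stages:

1. **Motion QC** — framewise displacement and four motion summaries;
   subjects violating the exclusion rule are dropped.
2. **Time-series preparation** — per-voxel nuisance regression, then
   temporal bandpass filtering (in that order).
3. **Voxel degree maps** — every in-mask voxel correlated with every
   other, supra-threshold connections counted, maps z-transformed.
4. **Atlas refinement** — each anatomical region subdivided into
   functionally homogeneous sub-regions by community detection on the
   control group's mean voxel correlation matrix. Sub-regions are the
   nodes of all ROI-level analyses.
5. **Graphs and metrics** — node-by-node Fisher-z connectivity,
   proportional thresholding across a sparsity grid, degree, clustering,
   characteristic path length, normalized small-world indices, community
   structure, participation.
6. **Group statistics** — permutation tests on global and module
   metrics, node-level tests with FDR control, edge-level t-tests, and
   voxelwise cluster-extent inference.
7. **Motion confound audit** — motion summaries correlated with the
   connectivity of the group-discriminating edges.

All randomness flows from one root seed, forked deterministically per
stage and subject, so a config plus seed reproduces every output byte
for byte.

## Motion quality control

With $d_j(i)$, $j = 1..6$ the three translations (mm) and three
rotations (degrees) of frame $i$ relative to the first frame, the
framewise displacement is

$$\mathrm{FD}(i) = \sum_{j=1}^{6} \lvert d_j(i) - d_j(i-1) \rvert,$$

where each rotation difference is first converted to the arc length it
evokes on a sphere of radius $R = 50$ mm (the approximate mean distance
of the cortex from the head centre): $\theta \cdot \pi/180 \cdot R$.
A 1° step therefore contributes $\pi/180 \times 50 \approx 0.873$ mm.

A subject is excluded when any translation's min-to-max range exceeds
3.0 mm, any rotation's range exceeds 3.0°, or $\mathrm{FD}_{max}$
exceeds 2.5 mm. The range reading of the translation/rotation cutoffs
follows the "(minimum to maximum)" convention; an instantaneous-norm
alternative exists in the literature but is not what the rule states,
so it is not implemented. Four summaries are reported per subject:
$D_{max}$ (largest radius-converted $\lvert d_j(i)\rvert$), $D_{RMS}$,
$\mathrm{FD}_{max}$ and $\mathrm{FD}_{RMS}$. "RMS motion" admits more
than one pooling; the implemented default is the pooled form

$$D_{RMS} = \sqrt{\tfrac{1}{N}\textstyle\sum_i \sum_j \tilde d_j(i)^2},$$

with $\tilde d$ the radius-converted parameters. The audit only needs a
monotone summary of overall motion, so this choice is inconsequential
downstream; a per-frame-Euclidean variant is selectable.

The confound audit correlates each of the four summaries with the
Fisher-z connectivity of every edge that discriminates the groups
(selected at $\alpha = 0.001$), and compares the count of significant
correlations at $\alpha = 0.01$ with the null expectation
$\alpha \times n_{tests}$. Edge or summary columns with zero variance
are flagged undefined and excluded from the counts.

## Time-series preparation

Nuisance regression is per-voxel ordinary least squares on an intercept
plus the regressor columns (six motion parameters; white-matter and
ventricle means when available), keeping the residuals. A rank-deficient
design is an error naming the collinear columns rather than a silent
pseudo-inverse.

The bandpass filter is a zero-phase forward-backward Butterworth,
passband 0.01–0.08 Hz, order 2 per pass (order configurable). The
filter family is a pipeline choice: zero-phase filtering preserves the
zero-lag Pearson structure all connectivity estimates rely on, and a
low-order Butterworth is the common choice in resting-state work.
Because forward-backward filtering is linear, the whole operation is a
single $T \times T$ matrix, built once per (frame count, TR, band) and
applied to all voxels at once. Series are demeaned before filtering —
DC is outside the passband, and removing the offset first avoids
start-up transients on the mean level; a constant series maps exactly
to zero. Regression runs before filtering; with zero-phase filtering
the two stages nearly commute, but the order is fixed for
reproducibility.

## Voxel degree maps

The degree of voxel $v$ is the number of other in-mask voxels whose
series correlate with it above $r = 0.25$. The threshold is one-sided
on signed $r$ — anti-correlations do not count — and configurable. The
correlation matrix is processed in column blocks so peak memory stays
bounded; the result is provably independent of the block size (asserted
in tests). Degree maps are standardized within mask,
$z_v = (D_v - \bar D)/\sigma_D$, with the population-SD convention;
the convention cancels in group contrasts but is fixed for exact
reproducibility. Group hub maps are voxelwise one-sample t statistics
of the z-degrees against zero, thresholded at a configurable cutoff
(default $t > 6$).

## Atlas refinement

For every anatomical region, the voxel-by-voxel Pearson matrices of the
**control subjects only** are Fisher z-transformed and averaged; the
patient group never influences node definitions, which prevents
circularity in the group comparison. $\mathrm{atanh}(\pm 1)$ is
infinite, so $|r|$ is capped at $1 - 10^{-7}$ before the transform;
the cap only binds on degenerate or synthetic data. The averaged matrix
is thresholded proportionally, keeping the strongest 30% of weights
($S = 0.3$), and Newman's spectral algorithm is run on the resulting
binary graph. The detected communities become sub-regions, named
`"<Region> <k>"`. Averaging across subjects happens before
thresholding: the refinement is a property of the group-mean
correlation structure, not of any single subject.

Three deliberate choices: ties in the proportional threshold are broken
by (row, column) lexicographic order, making node definitions identical
across platforms; spatial contiguity of sub-regions is *not* enforced
(nothing in the procedure requires it), but a post-hoc 6-connectivity
fragmentation count is reported per sub-region so users can see it; a
region in which no split increases modularity legitimately stays whole.

Per-region homogeneity — the mean pairwise voxel Fisher z — is reported
for both the parent and the refined parcellation. On data with genuine
sub-structure the refined parcellation is strictly more homogeneous;
this gain, together with reduced size heterogeneity, is the
justification for the refinement.

## Graph construction and metrics

Node time courses are the mean over each sub-region's in-mask voxels;
edges are zero-lag Pearson correlations of node time courses, Fisher
z-transformed (capped as above), diagonal zero. Binary graphs are
obtained by proportional thresholding: the $\mathrm{round}(S\,n(n-1)/2)$
largest off-diagonal weights become edges, with the lexicographic
tie-break. Edge sets are nested along the sparsity grid. Metrics are
computed across $S = 0.10, 0.15, \ldots, 0.35$: below ~0.1 graphs
disconnect, far above ~0.35 spurious weak correlations dominate and
small-world structure washes out. The 0.05 step is a package default;
both ends and the step are configurable.

All metrics use the binary conventions throughout:

* **Degree** $D_i$ = row sum; z-degree standardized across nodes with
  the population SD. A regular graph has no z-degree (error at the
  operation level; the pipeline records zeros for that subject and
  sparsity instead of aborting).
* **Clustering** $C_i = 2 t_i / (D_i (D_i - 1))$ with $t_i$ the
  triangles through $i$; $C_i \equiv 0$ for $D_i < 2$ and such nodes are
  included in the mean (the Watts–Strogatz binary convention).
* **Characteristic path length** $L$: mean BFS hop count over all
  ordered pairs. Disconnected graphs are an error — no silent
  $\infty$-dropping or harmonic mean — and the pipeline records each
  subject's empirical minimum connected sparsity.
* **Small-world indices**: $\gamma = C / \langle C_{rand}\rangle$,
  $\lambda = L / \langle L_{rand}\rangle$ over degree-preserving
  Maslov–Sneppen rewired references (default 20 references, 10
  successful swaps per edge; both configurable and recorded). Swaps
  creating self-loops or multi-edges are rejected; the degree sequence
  is conserved exactly. Disconnected references are skipped with a
  logged count; all-disconnected is an error.
* **Community structure**: Newman's spectral algorithm — recursive
  bisection by the sign pattern of the leading eigenvector of the
  generalized modularity matrix
  $B^{(g)}_{ij} = B_{ij} - \delta_{ij}\sum_{k \in g} B_{ik}$, with
  $B_{ij} = A_{ij} - k_i k_j / 2m$ — including the Kernighan–Lin-style
  fine-tuning pass after each division (each vertex moved once
  greedily, best intermediate configuration kept, repeated to
  convergence), stopping when no division increases $Q$. A leading
  eigenvalue below $10^{-10}$ or a non-positive $\Delta Q$ declares a
  group indivisible. Pure bisection (no fine-tuning) is available for
  comparison and never beats the refined result.
* **Participation** $P_i = 1 - \sum_m (k_{im}/D_i)^2$; zero for
  isolated nodes.

The group community structure is detected once on the control group's
mean connectivity matrix at $S = 0.2$ and applied unchanged to every
subject, so module summaries (mean z-degree, participation, clustering
per module) are comparable across groups.

## Group statistics

Permutation tests on the difference of group means use the add-one
Monte-Carlo convention $p = (1 + \#\{|T^\pi| \ge |T|\})/(n_{perm}+1)$,
switching automatically to exact enumeration when
$\binom{n_a+n_b}{n_a} \le n_{perm}$. Module-level and global tests are
two-sided at $\alpha = 0.05$; module p-values are reported both raw and
BH-adjusted across modules, since a correction across modules is a
reasonable but not mandated reading. Node-level z-degree tests at
$S = 0.2$ are BH-FDR controlled at $q = 0.05$. Edge-level tests are
pooled-variance two-sample t-tests on Fisher-z values (Welch by flag);
the ten strongest edges are reported with one-tailed p where the
analysis calls for a directed question.

Voxelwise inference uses a two-sample t-map, a cluster-forming
threshold at one-sided $p = 0.005$, and face-connected (6-connectivity;
18/26 configurable) components. Cluster significance comes from a
permutation null of the **maximum** cluster size under group-label
exchange (both directions pooled), with BH-FDR across the observed
clusters' p-values; the smallest surviving size is reported as the
critical cluster size. This permutation null replaces random-field /
topological-FDR machinery entirely: it is distribution-free, matches
the exchangeability the permutation tests already assume, and needs no
smoothness estimate. Its cluster sizes are calibrated to the synthetic
data's spatial structure and are not comparable to thresholds derived
from smoothed real fMRI.

## The synthetic cohort generator

No imaging data ship with the package; the generator produces cohorts
with exactly the statistical structure the analysis assumes, so every
stage is testable offline. Voxel series follow a latent-factor model

$$x_v(t) = \sqrt{w_m}\, M_m(t) + \sqrt{u}\, S_s(t) + g\, G(t) +
\sigma\,\epsilon_v(t),$$

with i.i.d. unit-Gaussian frames for every latent: $M_m$ the network
module factor (module factors correlated across modules by the
between-module coupling $\rho_{mm'}$ via a Cholesky factor), $S_s$ the
planted sub-region factor, $G$ an optional global signal (off by
default — the pipeline performs no global-signal regression) and
$\epsilon_v$ voxel noise. Positive semi-definiteness of the implied
covariance is automatic from the construction. Expected correlations
order as within-sub-region $> $ within-module $>$ between-module, each
gap several standard errors at the default 168 frames.

Defaults: a $16^3$ grid, 64 block regions in
4 network modules (named for the resting-state networks they emulate:
subcortical, default-mode, visual, sensorimotor), 2 planted sub-regions
per region, 168 frames at TR = 2 s (178 acquired minus 10 discarded
equilibration frames), 12 subjects per group, $w = 0.30$, $u = 0.30$,
$\rho = 0.30$, $\sigma^2 = 0.40$. The patient group carries two planted
effects mirroring the disease pattern of interest: within-module
coupling of the sensorimotor analog raised to 0.45 (module degree goes
up) and between-module coupling of the visual analog lowered to 0.10
(module participation goes down). Motion traces are Gaussian random
walks (step SD 0.03 mm/° per frame, giving ranges of roughly a
millimetre over a run, comparable to well-behaved adult cohorts), with
optional injected spikes for testing the exclusion rule.

Deliberately **not** emulated: hemodynamic response shape,
physiological noise spectra, scanner drift, spatial autocorrelation
from smoothing, registration error, and any realistic brain geometry.
Consequently, passing tests demonstrate that the algorithms and
inference behave correctly on data satisfying their assumptions — they
do not certify performance on real fMRI, where motion artefact
structure, smoothness-dependent cluster sizes and hemodynamic
confounds are material. The four-module, 128-node demo is also an
order of magnitude smaller than a real whole-brain parcellation
(seven modules over ~343 nodes); sizes were chosen so the full demo
and its 20-seed replication run comfortably on a single CPU, and the
planted effect sizes are large enough for a 12 + 12 cohort because the
demo's purpose is direction recovery, not power estimation.

The Watts–Strogatz fixture for small-world checks uses a ring lattice
($n = 100$, $k = 6$) with rewiring probability 0.3 — deep in the
small-world regime, where normalized clustering stays well above 1
while normalized path length sits near 1. A pure lattice
(`p_rewire = 0`) is kept for rewiring-null checks, where clustering
collapses toward density under degree-preserving randomization.

## Numerical choices collected

* Fisher z cap $|r| \le 1 - 10^{-7}$; capped values only arise on
  degenerate input.
* Proportional-threshold ties broken lexicographically by (row,
  column); identical across runs and platforms.
* Spectral split: leading eigenvalue $\le 10^{-10}$ or
  $\Delta Q \le 10^{-10}$ means indivisible; eigenvectors from
  `eigen(symmetric = TRUE)`.
* Permutation p-values use the add-one convention; exact enumeration
  below the permutation budget.
* Population SD in all z-standardizations.
* Rewiring attempts are capped at $100 \times$ the swap budget; a graph
  with no valid swap (e.g. a triangle) is returned unchanged with a
  warning.
* Test problem sizes: graph oracles are exhaustive over all labelled
  graphs with up to 5 nodes and sampled densely up to 30; recovery
  rates use 100 seeded replicates; the end-to-end demo is replicated
  over 20 seeds.

## Limitations

The pipeline consumes already-aligned, spatially normalized data;
slice-timing, realignment, segmentation, normalization and smoothing
are out of scope, as is any 3-D rendering. Weighted-graph metric
variants are intentionally absent — the binary versions are used
consistently. The cluster-extent null is permutation-based and should
not be numerically compared with parametric random-field thresholds.
Frame censoring ("scrubbing") is not implemented: the exclusion rule
drops subjects, not frames.
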