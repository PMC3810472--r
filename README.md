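# restnet

Graph-theoretical analysis of whole-brain resting-state functional
connectivity, for researchers comparing a patient cohort against
controls with fMRI. The package implements the full analysis chain as
tested, seeded R code: head-motion quality control, voxel time-series
preparation, voxel-level degree centrality, refinement of an anatomical
atlas into functionally homogeneous sub-regions, binary graph metrics
with small-world normalization, module/participation analysis, and
nonparametric group inference. A synthetic-cohort generator with
planted modular structure makes every stage testable without imaging
data.

## The model

Subjects' brain networks are binary graphs. Nodes are sub-regions
obtained by community detection on within-region voxel correlation
graphs of the control group; edges come from proportional thresholding
of the Fisher-z matrix of node time-course correlations, keeping the
top *S* fraction of weights across a sparsity grid (S = 0.10–0.35).
Per graph the package computes:

- degree D_i and its z-score across nodes,
- clustering C_i = 2·t_i / (D_i (D_i − 1)) and its mean (segregation),
- characteristic path length L, the mean shortest hop count
  (integration),
- γ = C/⟨C_rand⟩ and λ = L/⟨L_rand⟩ against degree-preserving
  Maslov–Sneppen rewired references (γ ≫ 1 with λ ≈ 1: small world),
- modularity Q via Newman's spectral algorithm (leading eigenvector of
  the modularity matrix B = A − k kᵀ/2m, recursive bisection with
  Kernighan–Lin refinement),
- participation P_i = 1 − Σ_m (k_im/D_i)².

At the voxel level, degree maps count supra-threshold correlations
(r > 0.25) of each voxel with all others. Motion QC uses Power's
framewise displacement FD(i) = Σ_j |Δd_j(i)| with rotations converted
to arc length on a 50 mm sphere, and excludes subjects beyond
3.0 mm / 3.0° parameter ranges or FD > 2.5 mm. Group inference is by
permutation tests (exact where enumerable), Benjamini–Hochberg FDR,
per-edge t-tests, and permutation-calibrated cluster-extent statistics
on voxel t-maps. See `vignette("network-pipeline")` for the full
methods account.

## Worked example

The built-in demo generates the default synthetic two-group cohort
(12 + 12 subjects, 16³ voxels, 64 atlas regions in four network
modules, 168 frames at TR = 2 s) with two planted patient-group
effects — sensorimotor-analog within-module coupling up, visual-analog
between-module coupling down — and runs the full pipeline:

```r
library(restnet)
res <- run_demo(seed = 1)
res
#> pipeline result: 12 controls, 12 patients; 128 nodes; 4 network modules (Q = 0.741)
#>   significant nodes (FDR): 0 | significant clusters: 0 | edges at alpha: 155
res$parcellation
#> subparcellation: 128 sub-regions from 64 parent regions (threshold S = 0.3 )
#>   mean homogeneity (Fisher z): parent 0.516, refined 0.712
str(res$recovery[c("degree_up_recovered", "participation_down_recovered",
                   "degree_diff", "participation_diff")])
#> List of 4
#>  $ degree_up_recovered         : logi TRUE
#>  $ participation_down_recovered: logi TRUE
#>  $ degree_diff                 : num 0.39
#>  $ participation_diff          : num -0.0867
```

Reading the output: the control-group parcellation recovered both
planted sub-regions in each of the 64 regions (128 nodes), and its
refined homogeneity (mean within-node voxel Fisher z, 0.71) exceeds
the parent regions' (0.52). Community detection on the control mean
matrix at S = 0.2 found exactly the four planted modules (Q = 0.74).
The module matched to the planted sensorimotor analog shows a higher
mean z-degree in patients (+0.39), and the visual analog a lower mean
participation (−0.087) — both planted directions recovered. 155 edges
separate the groups at α = 0.001 and feed the motion-confound audit.
With 12 subjects per group the node-level FDR and voxel cluster tests
are underpowered by design; the module-level permutation tests carry
the comparison (`res$module_tests`).

Individual stages are plain functions — `framewise_displacement()`,
`apply_exclusion()`, `voxel_degree_map()`, `build_subparcellation()`,
`threshold_proportional()`, `detect_communities()`,
`normalized_global_metrics()`, `permutation_test()`,
`voxel_degree_group_test()`, … — and operate on ordinary matrices,
arrays and small S3 containers; `run_pipeline()` also reads cohorts
from NIfTI volumes plus a TSV manifest (`load_cohort()`,
`save_cohort()`).

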