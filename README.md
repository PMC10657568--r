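# morphodelim

Integrative species delimitation for morphologically cryptic taxa:
two-dimensional geometric morphometrics plus DNA barcode clustering in
one tested R package.

Cryptic species — lineages that are genetically distinct but visually
indistinguishable — are common in insects and routinely missed by
morphology-only taxonomy.  The standard integrative workflow combines
two lines of evidence:

1. **Barcode clustering.** Aligned COI minibarcodes (typically 313 bp)
   are compared by uncorrected p-distance (the proportion of differing
   sites among sites unambiguous in both sequences, pairwise deletion)
   and grouped objectively: clusters are the connected components of the
   graph joining sequences with *d* ≤ *t* for a threshold *t* (a
   single-linkage cut, typically at 2–5%).
2. **Geometric morphometrics.** Landmark configurations digitized on
   standard imaging aspects are superimposed by generalized Procrustes
   analysis (GPA) — translation, unit-centroid-size scaling and
   least-squares rotation onto an iteratively refined consensus, with
   semilandmarks slid along their outline curves so their arbitrary
   spacing does not masquerade as shape variation.  The tangent-space
   shape variables then feed variance decomposition (Procrustes
   ANOVA / Goodall's *F* with permutation), ordination (relative warps,
   between-group PCA with thin-plate-spline deformation grids coloured
   by Jacobian expansion factors), and discrimination (CVA with
   jackknifed classification, pairwise PERMANOVA with Bonferroni
   correction).

morphodelim implements both stacks end to end, together with a
synthetic-data generator that plants known species/site/replicate
structure in shapes and known divergence structure in sequences, so
every stage is testable without any external data.

## Core quantities

* centroid size `CS(X) = sqrt(Σᵢ ‖xᵢ − x̄‖²)`, the size measure removed
  by Procrustes scaling;
* Goodall's `F = (SS_factor/df_factor) / (SS_res/df_res)` on summed
  squared Procrustes distances, with p-values from randomized residual
  permutation (RRPP) of the reduced model;
* thin-plate spline with kernel `U(r) = r² log r²`, bending energy
  `wᵀKw` (zero exactly for affine deformations) and analytic Jacobian
  determinants for deformation grids;
* PERMANOVA pseudo-`F = (SS_b/(g−1)) / (SS_w/(n−g))` from Euclidean
  distances on warp scores, `p = (#{F* ≥ F} + 1)/(n_perm + 1)`;
* uncorrected p-distance and its single-linkage merge profile, whose
  cut at height *t* equals the threshold clustering at *t*.

## Worked example

A small synthetic dataset (two planted species, three specimens each,
two digitization replicates; sequences at 8% planted divergence) ships
with the package:

```r
library(morphodelim)
ex <- function(f) system.file("extdata", "example", f, package = "morphodelim")

shapes  <- attach_labels(read_tps(ex("synthetic_shapes.tps")),
                         ex("synthetic_labels.csv"))
sliders <- read_sliders(ex("synthetic_sliders.txt"), shapes$k)
aligned <- gpa(shapes, sliders = sliders)
tangent_check(aligned)
#> Tangent approximation: slope 0.99669, correlation 1.00000 (n = 12)

procrustes_anova(aligned, c("species", "replicate_id"), n_perm = 999, seed = 1)
#> Procrustes ANOVA (Goodall's F), 999 permutations (RRPP)
#>              Df        SS        MS   Rsq_pct         F     p
#> species       1 2.224e-01 2.224e-01  94.19000 146.50000 0.002
#> replicate_id  1 6.332e-05 6.332e-05   0.02682   0.04171 0.979
#> Residuals     9 1.366e-02 1.518e-03   5.78700        NA    NA
#> Total        11 2.361e-01        NA 100.00000        NA    NA

warps <- relative_warps(aligned)
jackknife_classify(warps, "species")
#> Jackknifed classification: 100.0% correctly assigned

dists <- p_distance_matrix(read_fasta(ex("synthetic_coi.fasta")))
objective_cluster(dists, 0.04)
#> Objective clustering at threshold 0.040: 2 cluster(s)
merge_profile(dists)
#> Single-linkage merge profile: 12 sequences, 11 merges
#>   divergence thresholds (%): 6.7, 1.6, 1.6, 1.3, 1.3 (top 5)
```

The ANOVA says the planted species contrast explains 94% of shape
variation while digitization error is negligible (0.03%, p ≈ 1); the
jackknife assigns every specimen to its own species; the barcodes fall
into the two planted clusters at the 4% threshold, with the deepest
merge at 6.7% separating them.  `run_pipeline()` drives the same
analysis from a single YAML configuration and writes CSV tables, a
Newick dendrogram and a JSON summary.

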