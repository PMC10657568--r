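---
title: "Methods and design notes for morphodelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for morphodelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodelim)
```

morphodelim tests species boundaries in cryptic taxa by combining
quantitative shape analysis of digitized landmark configurations with
threshold clustering of aligned DNA barcodes.  This vignette documents
the models behind each stage, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generator does
and does not emulate, and the package's known limitations.

## Superimposition

A configuration is an ordered set of $k \ge 3$ planar landmarks, where
index $i$ marks the same anatomical locus on every specimen.
Generalized Procrustes analysis removes position, size and orientation:
each configuration is centered, scaled to unit centroid size
$CS = \sqrt{\sum_i \lVert x_i - \bar x\rVert^2}$, and rotated onto the
current consensus by the closed-form two-dimensional orthogonal
Procrustes solution (SVD with a determinant constraint of $+1$ —
reflections are disallowed, because a mirrored specimen is not the same
biological object).  The consensus is the coordinate-wise mean of the
aligned set and the loop repeats until its root-mean-square change
falls below `tol` (default `1e-8`, `max_iter = 100`).  The final
orientation is canonicalized to the principal axes of the consensus
with a deterministic sign rule (the landmark with the largest $|x|$
gets a positive $x$), which makes the output invariant to how any input
happened to be rotated.

Two degenerate cases are rejected explicitly: datasets with fewer than
two configurations, and configurations of coincident points (zero
centroid size), which are reported by id.

**Tangent projection.** Shape space is curved; linear statistics
operate in the tangent space at the consensus.  Aligned shapes are
orthogonally projected onto the tangent plane by default
(`project_to_tangent = TRUE`) and all downstream variance analyses
consume these tangent coordinates.  `tangent_check()` quantifies the
quality of the linearization: for each configuration the geodesic
Procrustes distance $\rho = \arccos\langle x, \hat c\rangle$ to the
unit consensus is compared with its Euclidean tangent distance (which
equals $\sin\rho$ under orthogonal projection), via a through-origin
regression slope and a correlation.  Because $\sin\rho \le \rho$, the
slope cannot exceed 1; values near 1 mean the linear approximation is
safe.  Datasets whose largest $\rho$ is below $10^{-6}$ have no shape
variation and the regression is refused as undefined.

**Sliding semilandmarks.** Points digitized along outline curves carry
no information in their spacing along the curve.  During GPA each
semilandmark may therefore slide along the chord joining its two
neighbours (the `before`/`after` indices of its slider triplet), with
all of a configuration's displacements solved jointly to minimize
either the thin-plate-spline bending energy of the configuration
relative to the consensus (`bending_energy`, the default, matching the
common default of the field's superimposition tools) or its Procrustes
distance to the consensus (`procrustes_distance`).  Sliding uses the
bending-energy matrix of the current consensus and is followed by
re-centering, re-scaling and re-rotation.

How many sliding iterations to run is genuinely open.  We limit sliding
to the first `slide_iters = 3` GPA iterations and then let
rotation-only iterations converge.  The reason is structural: the
sliding criterion is invariant under a *collective* drift of all
configurations' semilandmarks along their curves, so sliding on every
iteration lets the whole spacing pattern creep indefinitely (the
consensus change plateaus instead of converging), while the spacing
relative to the consensus stabilizes within two to three passes.  The
cap is configurable for users who want strict one-pass or
more-aggressive sliding.

## Variance decomposition and ordination

`procrustes_anova()` fits sequential (Type I) linear models to the
tangent coordinates treated as a single multivariate response, with
sums of squares measured as summed squared Euclidean (Procrustes)
distances.  The statistic per factor is Goodall's $F$, the ratio of
factor to residual mean squares; degrees of freedom are the univariate
ones, since the coordinate dimension cancels in the ratio.
Significance comes from randomized residual permutation (RRPP): for
each factor the residuals of the reduced model containing all preceding
terms are permuted (seeded, default `n_perm = 999`) and the statistic
recomputed, with $p = (\#\{F^* \ge F\} + 1)/(n_\mathrm{perm} + 1)$.

The canonical model for digitized datasets is `species`, then `site`,
then `replicate_id`.  Sites are geographic subsets of a species'
samples, so by default a `site` term following `species` is fitted as
site-within-species (the species:site interaction,
`nest_site_in_species = TRUE`); the digitization replicate enters last
so that measurement error is quantified after the biological factors.
Constant factors and factors confounded with preceding terms are
rejected.

`relative_warps()` computes principal components of the tangent
coordinates with warp-weighting exponent $\alpha = 0$ and the uniform
component included, in which case warp scores are exactly PC scores and
the full score space is an isometry of tangent space.  Axis signs are
fixed by making the largest-magnitude loading positive; eigenvalue ties
are broken by the stable ordering of the decomposition.

`between_group_pca()` eigen-decomposes the covariance of the *equally
weighted* group means and projects all individuals onto the axes, so
group separation is displayed regardless of within-group variance.
Percent variance is reported both as the share of group-mean variance
and as the share of total projected variance; the former is the
conventional headline number, the latter is what a screeplot of the
projected individuals would show.  The two differ whenever group sizes
are unbalanced or within-group variance is anisotropic, which is why
both are kept.

## Thin-plate splines and deformation grids

`fit_tps()` solves the standard bordered system with kernel
$U(r) = r^2\log r^2$.  The kernel convention matters only by a constant
factor in the weights ($r^2 \log r$ would halve them); it is fixed and
stated here.  The interpolant maps every reference landmark exactly
onto its target; the bending energy $w^\top K w$ (summed over both
coordinates) is zero precisely for affine deformations and equals
$1/(16\pi)$ times the integral of the squared second derivatives of the
interpolant over the plane, a relation the test suite verifies by
adaptive numeric quadrature.  Collinear or duplicated reference
landmarks make the system singular and raise an error.

`jacobian_grid()` evaluates the analytic Jacobian determinant of the
warp at the cell centers of a regular grid: $\det J > 1$ is local
expansion, $< 1$ contraction; plots use $\log_2 \det J$ on a symmetric
grey scale (a purely presentational choice).  Grids along an ordination
axis are built by warping the consensus to
$\text{consensus} + c\cdot\text{axis}$ with $c$ spanning the observed
score range, which mirrors how shape change along principal or
canonical axes is conventionally displayed; the magnification is
reproduced qualitatively, not pixel-for-pixel against any particular
figure.

## Discrimination

`cva()` solves the generalized eigenproblem of between-group (group
means weighted by group size) against pooled within-group covariance,
scaling the canonical axes so the pooled within-group covariance is
spherical — Euclidean distance in canonical space is then Mahalanobis
distance in the input space.  Because warp scores can outnumber
specimens, input dimensions are truncated first: the default rule keeps
the leading variance-ordered columns explaining 99% of variance,
bounded by $n - g - 1$.  The rule is configurable (`retain` accepts a
proportion or an explicit count), and a still-singular within-group
covariance is reported with the advice to truncate harder rather than
silently regularized.

`jackknife_classify()` estimates classification accuracy by
leave-one-out: the full CVA is refitted without each individual, the
individual is projected and assigned to the nearest canonical group
mean, and results are tallied into a confusion matrix.  Refitting the
whole CVA per specimen is the strict reading of jackknifed
cross-validation; a cheaper variant that only recomputes group means
(`refit = "means"`) is provided for large datasets.  Groups of size one
cannot be left out and are rejected.

`pairwise_permanova()` runs one-way PERMANOVA on Euclidean distances
between score rows for every group pair: pseudo-
$F = (SS_b/(g-1))/(SS_w/(n-g))$ with $g = 2$, computed from the
pairwise distance matrix (the test suite checks the equivalent
centered-coordinate route, the Gower identity), permutation of group
membership (default `n_perm = 9999`, seeded), and Bonferroni correction
across pairs ($p_\mathrm{adj} = \min(1, p \cdot \#\text{pairs})$).
Whether to analyse all digitized configurations (including replicates)
or replicate means is a modelling decision surfaced as the pipeline's
`replicate_policy`; the default keeps all configurations, matching how
datasets with digitization replicates are typically summarized, and
`average` collapses replicates per specimen first.  Note that
permutation tests assume exchangeable rows: with replicates retained,
within-specimen dependence makes the species test anticonservative, so
inference-focused runs should use `replicate_policy: average` (the
package's calibration simulations use one configuration per specimen
for exactly this reason).

## Barcodes

`p_distance_matrix()` computes uncorrected p-distances with pairwise
deletion: sites with `N` or a gap in either sequence leave both
numerator and denominator.  Ambiguity codes other than `N` are recoded
to `N`; treating gaps as missing rather than as differences is the
package default and is configurable only by pre-recoding the input,
a deliberate simplification.  Pairs with zero comparable sites get a
flagged `NA` distance; such pairs contribute no edge to the clustering
graph (with a warning).

`objective_cluster()` returns the connected components of the
$d \le t$ graph — the clustering criterion of the objective-clustering
protocol; thresholds are inclusive.  The identification-success variant
of "best close match" (querying unknowns against a reference library)
is out of scope.  `merge_profile()` computes the single-linkage
hierarchy (via `stats::hclust`; the test suite checks it against a
brute-force $O(n^3)$ agglomeration), whose cut at any height
reproduces the threshold clustering exactly; heights are reported as
percentages to one decimal in printed summaries, and `profile_newick()`
exports the dendrogram.

## The synthetic-data generator

`simulate_shapes()` builds each digitized configuration as
$\text{nuisance}(\text{template} + \text{species effect} +
\text{site effect} + \text{specimen noise} + \text{replicate noise})$.
Species and site displacement fields are drawn once per dataset as
smooth low-bending-energy thin-plate-spline deformations of the
template — white-noise mean offsets would make discrimination
unrealistically easy, whereas smooth fields differ the way biological
shapes do.  Defaults: a 33-point head-like template (13 fixed
landmarks, two outline curves of 10 semilandmarks, so slider logic is
exercised), species effect RMS 0.02 and site effect 0.01 in units of
template centroid size, specimen noise sd 0.005, replicate
(digitization) noise sd 0.001 (an order of magnitude below specimen
noise, consistent with digitization error being a fraction of a percent
of total shape variance when one trained operator digitizes twice), two
replicates per specimen, and nuisance rotation/translation/scale drawn
uniformly from $[0, 2\pi)$, $[-1, 1]$ and $[0.5, 2]$.

`simulate_sequences()` places one ancestor per group by mutating a
random root at disjoint sites, with per-group site counts solved by
least squares on the star model $d(i,j) = x_i + x_j$ from the target
between-group distances; matrices that violate additivity beyond
`feasibility_tol` (default 0.005) are rejected.  Targets are corrected
for the apparent divergence added by within-group mutation (computed
from the exact per-site mismatch probabilities of the
uniform-substitution model), so realized between-group mean p-distances
match the targets in expectation; at the default sizes (313 bp, around
ten sequences per group) the sampling standard deviation of the
realized mean is a few tenths of a percent.  Mutations are placed
uniformly without back-mutation correction — exact for uncorrected
distances, but not a substitution-model simulator.

What the generator does *not* emulate: allometry (shape–size
covariance), correlated landmark noise, digitizer drift between
sessions, outline curves whose semilandmark counts differ between
specimens, coalescent genealogies, rate heterogeneity among sites, or
indels.  Passing tests on synthetic data therefore validate the
algorithms and their calibration, not the biological adequacy of any
particular model for real specimens.

## Validation problem sizes

The test suite and the acceptance script validate at desk scale,
chosen to finish in about a minute on one CPU while keeping Monte-Carlo
error small relative to the tolerances: permutation-test calibration
uses 1,000 simulated null datasets of 40 independent specimens (two
species of twenty; one configuration per specimen, because permutation
tests assume exchangeable rows and replicate pairs are not) with 199
permutations per test; chance-level classification uses 200 null
datasets; rotation optimality is checked against a 0.001-radian grid
search on 50 random pairs; brute-force single-linkage comparisons run
at $n \le 30$; exhaustive permutation enumeration at $n = 6$.

## Known limitations

Two-dimensional landmarks only; no missing-landmark estimation; no
relative-warp weighting with $\alpha \ne 0$; no phylogenetically
corrected ANOVA; no quadratic discriminants or non-Euclidean PERMANOVA
distances; no model-corrected genetic distances (K2P etc.) and no
tree-based delimitation (GMYC/PTP).  Sequence input must be pre-aligned.
Statistical significance of shape differences between allopatric
populations is not, by itself, evidence of heterospecificity — the
geographic `site` term exists precisely to keep that confound visible.
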