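---
title: "A hierarchical geometric-morphometric protocol for leaf shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical geometric-morphometric protocol for leaf shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgmm)
```

## The problem and the model

A taxonomic comparison of leaf form asks whether geographic populations
differ in leaf size and shape, given that leaves also vary between trees of
one population, between leaves of one tree, and between repeated
digitizations of one leaf. `leafgmm` treats a leaf as a configuration of
`k` labelled 2D landmarks (11 by default, on one half of the blade — index
`i` is the same anatomical point in every specimen) and separates size from
shape with a generalized Procrustes analysis (GPA):

* **size** is the centroid size `CS = sqrt(sum of squared landmark
  distances from the centroid)`, in mm;
* **shape** is what remains after translation, scale and rotation are
  removed: each configuration is centered, scaled to unit CS, and rotated
  onto the consensus by least squares; the consensus is re-estimated and
  the loop repeats until it is stable.

Shape space is curved, so the aligned pre-shapes are orthogonally projected
onto the Euclidean space tangent to the unit sphere at the consensus.  All
downstream statistics (PCA, ANOVA, Hotelling T², discriminant analysis,
MANCOVA) operate on these tangent coordinates.  The quality of the flat
approximation is checked by `tangent_space_check()`, which regresses (through
the origin) the tangent Euclidean distances on the Riemannian Procrustes
distances `rho = acos(<pre-shape, consensus>)`; slope and correlation near 1
mean the approximation is excellent, which holds for any biologically
plausible leaf sample.

Four degrees of freedom are absorbed by the 2D superimposition, so `2k`
coordinates carry `2k − 4` shape dimensions.  Every multivariate test runs
on the principal-component subspace with eigenvalues above `1e-12` of the
largest, which makes degrees of freedom honest (18 dimensions for 11
landmarks on full-rank data).

## The hierarchical ANOVA

`procrustes_anova()` decomposes variation sequentially along the sampling
hierarchy *populations → trees → leaves → replicas*: each stratum's sum of
squares is the deviation of its group means from the parent stratum's means,
summed over observations (and over coordinates, for shape — the isotropic
model, which assumes equal, direction-free variation at every landmark; it
buys a simple univariate-style F table at the cost of a restrictive
assumption, so P values should be read cautiously when variation is strongly
anisotropic).  The components always add up to the total SS, balanced or
not.  F ratios follow the hierarchy — populations over trees (the corrected
ratio that treats trees as a random effect), trees over leaves, leaves over
replicas (measurement error).

Two degrees-of-freedom conventions are provided because both occur in
practice.  The default `morphoj` convention reproduces the widely used
desktop-software output for this design: populations `P − 1`, trees
`T − 1`, leaves `(L − 1) − (P − 1) − (T − 1)`, error `n − L` (1, 43, 43, 88
in the reference design), each multiplied by `2k − 4` for shape.  The
orthodox `nested` convention instead assigns trees `T − P` and leaves
`L − T` (1, 42, 44, 88).  The printed convention effectively double-counts
one df between populations and trees; we replicate it by default for
comparability and document the alternative.

## Tree averaging and the test battery

Leaves of one tree share genes and microenvironment: they are
pseudoreplicates.  `average_by_tree()` collapses each tree to its mean shape
and mean size before any population-level test.  The battery
(`group_test_battery()`) then reports, side by side, parametric and
permutation tests: pooled-variance t on size, ±1 dummy regression (percent
of variance explained), Hotelling T² with its F approximation
(df `p, n − p − 1`), Mahalanobis- and Procrustes-distance permutation tests
(`P = (1 + #{permuted ≥ observed}) / (B + 1)`, B = 10000 by default), Box's
M for covariance homogeneity, and a two-group discriminant analysis.  The
identities `T² = n1 n2 / (n1 + n2) · d²` (Mahalanobis d) and the Pillai-F
conversion are re-checked on every `run_protocol()` call and violations are
fatal.

Classification accuracy is only reported honestly by leave-one-out
cross-validation: the jackknife refits group means, pooled covariance and
the rule with each specimen held out.  Resubstitution tables are also
returned, exactly because their inflation (near-perfect accuracy on pure
noise when `p` approaches `n`) is worth demonstrating; on null data the
jackknifed accuracy sits at chance while resubstitution does not.  Ties in
the classification distance go to the first group (a measure-zero event).

## Allometry and size-correction

`shape_size_regression()` fits every shape coordinate on (optionally log)
centroid size; `mancova()` tests, with Pillai's trace on the PC subspace,
the slopes (group × size interaction: separate-slopes vs parallel-lines
models), the intercepts (parallel lines vs a single line), and the size
effect itself.  All three hypotheses have one df here (two groups, one
covariate), so `F = V/(1 − V) · df2/p` exactly, with
`df2 = n − rank(model) − p + 1`.  Two "percent explained" summaries are
reported per term — the sequential incremental gain and the total fit of
the fuller model — because published tables are ambiguous about which is
meant; the Pillai/F/df values are the unambiguous quantities.

`size_correct()` estimates the pooled within-group slope `B` from
within-group-centered data and reconstructs every shape at a common size
(the grand mean by default; the choice provably does not affect group mean
differences when lines are parallel, and the function re-verifies the
residual within-group allometry is < 1e-8 % of variance).  Because the
procedure assumes parallel allometries, the function refuses to run when
the slopes test is significant at 0.05 unless explicitly forced — with
large samples, tiny but significant slope differences can be tolerable, and
the override exists for that case.

## Thin-plate-spline geometry

Visualization uses the thin-plate spline with kernel `U(r) = r² log r²`
(`U(0) = 0`); the factor-of-two difference from the `r² log r` convention
found elsewhere is absorbed into the weights and affects nothing
observable.  `tps_fit()` solves the standard bordered system so landmarks
interpolate exactly; the bending energy `trace(WᵀKW)` is zero iff the map
is affine.  Deformation grids default to 20 × 20 cells over the reference
bounding box expanded by 10% (no published convention exists; both are
configurable), with the analytic Jacobian determinant at every node —
values above 1 are local expansions, below 1 contractions, and negative
values (fold-over, possible under large magnification) are reported with a
warning rather than an error.  Magnified targets
(`reference + m (target − reference)`) are not observed shapes and the
factor `m` should always be stated.

`partial_warps()` eigendecomposes the bending-energy matrix of the
consensus (`k − 3` nonzero eigenvalues), projects specimen deviations on
the principal warps, and completes the tangent space with a 2-dimensional
uniform basis computed numerically as the orthogonal complement of the
partial-warp subspace — this avoids committing to any closed-form uniform
parameterization while guaranteeing, by construction, that partial-warp
plus uniform scores preserve all pairwise shape distances (asserted to
1e-9 in the tests).

## The synthetic generator

`generate_dataset()` emulates the reference study design: 2 populations ×
22 trees × 2 leaves × 2 replicas, 11 landmarks.  Effects are added in the
tangent space at a fixed template (a synthetic 11-point half-leaf fixture;
no result depends on its exact coordinates) after projecting out the
similarity directions, so the generating per-coordinate SDs map directly
onto ANOVA strata; replicas share their leaf's shape and size except for
digitizing noise; each configuration is then scaled to its size in mm and
given a random rotation and translation so the superimposition is actually
exercised; labels follow the `Popul_Txx_Ly_Rz` convention so classifier
extraction round-trips.

Defaults are fixed once to mirror the reference conditions:
per-coordinate tangent SDs `sigma_tree = 0.0217 > sigma_leaf = 0.0160 >>
sigma_error = 0.00086`, a fixed population shape offset of norm 0.0388, a
common allometric trend of 0.0143 shape units per mm, population mean sizes
70.6 and 69.4 mm with lognormal tree (1.67 mm) and leaf (1.41 mm)
components — lognormal keeps sizes positive and mildly right-skewed, as
real leaf samples are.  Under these conditions the recovered percent-SS
pattern matches the reference qualitatively: measurement error < 1%, trees
above leaves, populations smallest.  The percentages are not matched
numerically, and cannot be while keeping `sigma_tree > sigma_leaf`: a tree
mean aggregates its leaves and replicas, so the tree stratum's SS absorbs
part of the leaf and error variance, and reproducing a 63%/34% split
exactly would require `sigma_tree² < sigma_leaf²` — the opposite ordering.
We keep the SD ordering (it is the stated condition, and it is what the
parameter-recovery tests check) and accept a more tree-dominated split.

What the generator does **not** emulate: anisotropic landmark-specific
variation, digitizing error that differs between landmarks, asymmetry,
outliers, unbalanced sampling, and any genuine biological covariance
structure between landmarks.  Tests passing on these data therefore
demonstrate correctness of the computations under the isotropic
small-variation model, not robustness to every property of real leaf data.

## Numerical choices

* GPA: partial fit by default (unit CS retained; the full fit rescaling by
  `cos(rho)` is available), convergence when the summed squared consensus
  change is below 1e-10, at most 100 iterations; the consensus is aligned
  to its principal axes with deterministic signs so results are
  reproducible; reflections are never allowed in the optimal rotation.
* Outlier rule: squared distance to the consensus against the `1 − 1/n`
  quantile of a moment-matched scaled chi-square (Satterthwaite scale and
  effective dimensionality from the eigenvalue spectrum).  The published
  procedure is described only as a normal-model comparison, so this
  concrete rule is ours and configurable.
* Quartiles: Tukey five-number summaries (`stats::fivenum`).
* UPGMA through `stats::hclust`; cophenetic correlation is `NA` for
  degenerate trees whose cophenetic distances are all equal.
* Permutation tests: B = 10000 by default, two-sided via absolute
  statistics, `P = (1 + #{≥ observed})/(B + 1)`; all randomness flows from
  the caller's seed (`run_protocol(seed = )` seeds once for the whole run).
* Multivariate tests reduce to the PC subspace with eigenvalues above
  `1e-12` of the largest, further capped so error df stay positive on
  small samples (with a warning).

Problem sizes used by the test-suite simulations — e.g. 200 replicates for
the null discriminant calibration, 50 seeds for parameter recovery, 200–400
replicates for type-I calibrations at the 99% binomial band — were chosen
as the smallest runs that give those binomial checks useful power.

## Known limitations

* 2D landmarks only; no semilandmarks, sliders or outline analysis (the
  outline file is display geometry, never data).
* The isotropic Procrustes ANOVA is a simplification; a MANOVA-style
  multivariate test per stratum is not implemented.
* Variance components (random-effect magnitudes) are not estimated;
  percent-of-total-SS is reported instead, which is a different summary.
* The two-group discriminant path is the implemented and tested one; three
  or more groups would need a CVA ordination, which is out of scope.
* Typicality probabilities are not computed.
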