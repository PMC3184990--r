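# leafgmm

Landmark-based geometric morphometrics for hierarchical taxonomic comparison
of leaf form.

Plant taxonomists routinely compare leaves between populations or species, but
leaves vary at every level of sampling: between populations, between trees of
a population, between leaves of a tree, and between repeated digitizations of
the same leaf (measurement error). `leafgmm` implements the complete
landmark-based protocol for that comparison in one tested R package:

1. **File handling** — read/write TPS and NTS landmark files, apply digitizing
   scale factors, extract nested classifiers (population / tree / leaf /
   replica) from fixed character ranges of specimen labels, import outline
   polylines and wireframe link lists for visualization.
2. **Superimposition** — centroid size
   `CS = sqrt(sum_i ||x_i - x̄||²)`; generalized Procrustes analysis (partial
   fit: center, scale to unit CS, least-squares 2D rotation, iterate) with
   orthogonal projection onto the tangent space at the consensus; tangent-space
   diagnostics (no-intercept regression of tangent on Procrustes distances);
   Bookstein baseline superimposition for comparison.
3. **Ordination and screening** — PCA of shape coordinates, normal-model
   outlier screening, UPGMA phenograms with cophenetic correlation.
4. **Hierarchical Procrustes ANOVA** — sequential sums of squares for the
   nested design *populations ⊃ trees ⊃ leaves ⊃ replicas*, for centroid size
   and (under the isotropic model) shape, with the corrected F ratio
   `F_populations = MS_populations / MS_trees` that treats trees as the random
   effect, and percent-of-total-SS summaries.
5. **Two-group tests on tree means** — after averaging leaves within trees to
   remove pseudoreplication: pooled t and permutation tests on size,
   dummy-coded regression tests, Hotelling T², Mahalanobis- and
   Procrustes-distance permutation tests, Box's M, and two-group discriminant
   analysis with jackknife (leave-one-out) cross-validated classification
   tables.
6. **Allometry** — multivariate regression of shape on size, Pillai-trace
   MANCOVA for slopes (group × size interaction) and intercepts, and pooled
   within-group size-correction
   `corrected_i = shape_i − B (size_i − common size)`.
7. **Visualization geometry** — thin-plate-spline warps
   (`U(r) = r² log r²`), deformation grids, Jacobian expansion factors, warped
   outlines and wireframes, displacement (lollipop) vectors, magnification,
   partial warps and uniform components. Only geometry is produced; any
   plotting layer can render it.
8. **Synthetic data** — a generator emulating a balanced
   2-population × 22-tree × 2-leaf × 2-replica sampling design with
   hierarchical shape variance components, population size offsets and a weak
   common allometric trend, so the whole pipeline is testable without any
   download.

## Worked example

```r
library(leafgmm)

ds <- generate_dataset(synthetic_spec(seed = 42))   # 176 leaves, 11 landmarks
bundle <- run_protocol(dataset = ds, n_perm = 999, seed = 42)

bundle$tangent_check
#> Tangent-space check: slope 0.997, correlation 1.000
#>   Procrustes distance to consensus: mean 0.124, max 0.195

bundle$anova_shape
#> Hierarchical shape ANOVA (morphoj df convention)
#>       effect pct_SS      SS        MS   df       F         P
#>  populations   4.2% 0.11662 6.479e-03   18   2.291 1.737e-03
#>        trees  78.9% 2.18908 2.828e-03  774   4.697 2.985e-94
#>       leaves  16.8% 0.46610 6.022e-04  774 815.467 0.000e+00
#>        error   0.0% 0.00117 7.385e-07 1584      NA        NA
#> total SS = 2.773

bundle$battery$da
#> Two-group discriminant analysis on 18 PCs
#>   resubstitution accuracy: 88.6%
#>   jackknife accuracy:      59.1%
```

Reading the output: the tangent-space approximation is excellent (slope and
correlation ≈ 1), so Euclidean statistics are safe. Measurement error explains
< 0.1% of shape variation while trees explain more than leaves within trees,
so averaging leaves within trees is justified before testing the populations.
The resubstitution accuracy of the discriminant analysis is heavily inflated
(88.6%) relative to the honest jackknifed accuracy (59.1%) — only the
cross-validated table should be interpreted. `bundle$mancova` tests allometric
slopes and intercepts with Pillai's trace, and `bundle$battery_corrected`
repeats the test battery after pooled within-group size-correction.

`reproduce_oak_analysis(path)` runs the same deterministic pipeline on the
published two-population sessile-oak raw dataset (176 × 11 landmarks, NTS)
when a copy is supplied; it is third-party data and not bundled.

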