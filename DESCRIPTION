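Package: leafgmm
Title: Landmark-Based Geometric Morphometrics for Hierarchical Comparison of Leaf Form
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete landmark-based geometric-morphometric protocol for
    hierarchical taxonomic comparison of leaf form. Reads and writes TPS and
    NTS landmark files, performs generalized Procrustes superimposition with
    tangent-space projection and diagnostics, principal component ordination
    and UPGMA phenograms, hierarchical Procrustes ANOVA with measurement-error
    partitioning, tree-averaged two-group test batteries (t, Hotelling T-squared,
    Mahalanobis and Procrustes distance permutation tests, Box's M),
    discriminant analysis with jackknife cross-validation, multivariate
    allometric regression with Pillai-trace MANCOVA and pooled within-group
    size-correction, and thin-plate-spline visualization geometry (deformation
    grids, warped outlines and wireframes, displacement vectors, Jacobian
    expansion factors, partial warps and uniform components). Includes a
    synthetic leaf-landmark generator emulating a balanced
    population/tree/leaf/replica sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
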