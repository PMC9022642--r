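---
title: "Truss networks and geometric morphometrics for phenotypic stock discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Truss networks and geometric morphometrics for phenotypic stock discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trussmorph)
```

## The problem

Fisheries management needs to know whether a species sampled from several
rivers is one homogeneous population or a set of *phenotypic stocks* —
population units with distinguishable body shape. `trussmorph` implements the
complete analysis chain used for this question in landmark-based fish
morphometrics: a small set of homologous anatomical points (here nine:
snout tip, nape, dorsal-fin origin, posterior end of the vertebral column, a
point on the anal fin perpendicular to the dorsal-fin origin, the anal-fin
origin, the pectoral-fin insertion, the maxilla end, and a point
perpendicular to it) is digitized on each specimen, and two complementary
descriptions are derived from the same coordinates:

* the **truss network** — every inter-landmark Euclidean distance,
  $\binom{9}{2} = 36$ variables named `i_j`, analysed with multivariate
  ordination and discriminant methods after size correction;
* the **Procrustes shape space** — configurations superimposed by
  generalized Procrustes analysis (GPA), analysed with shape PCA,
  permutation tests, thin-plate-spline (TPS) warps and landmark-subset
  modularity.

## Size correction of truss distances

Raw distances are dominated by body size. The allometric (Elliott)
adjustment rescales each measurement $M$ to the common size
$M_{adj} = M\,(L_s/L_0)^b$, where $L_0$ is the specimen's standard length
(truss variable `1_4`, snout to vertebral end, in mm), $L_s$ is the overall
mean standard length, and $b$ is the growth exponent of that variable.

Choices the package makes where practice varies:

* $b$ is the slope of the pooled ordinary-least-squares regression of
  $\log_{10} M$ on $\log_{10} L_0$ over all specimens. A group-centred
  ("pooled within") slope is available via `fit_allometry(pooled_within =
  TRUE)` for sensitivity analysis; the pooled slope is the common reading of
  the Elliott approach and is the default.
* Logs are base 10. The base only shifts scales uniformly; correlations,
  correlation-matrix PCA and discriminant results are unaffected.
* After adjustment `1_4` is removed (it is the constant $L_s$), leaving the
  35 analysis variables; the analysis matrix is $\log_{10}$ of the adjusted
  distances. A `log-only` mode keeps size in the data for comparison.
* Under exact isometry and no noise the adjustment is exact: every variable
  collapses to its mean-size value with zero residual variance (this is
  tested to 1e-9 relative).

The one-way ANOVA screen (`anova_screen`, default $\alpha = 0.01$) *reports*
which variables separate the groups and the N/P ratio (specimens per
variable, recommended band 3.5–8; 149/35 = 4.26 for the full design) but
does not drop variables unless asked (`drop_nonsig = TRUE`): retaining the
complete 35-variable matrix keeps the multivariate analyses comparable
across runs, and the screen's role is diagnostic.

## Ordination and discrimination

* `truss_pca` — PCA of the **correlation** matrix (all variables
  standardized). This is fixed, not an option: percent-variance entries are
  eigenvalue/35, which is the self-consistency the package tests. Retention
  follows the Kaiser criterion (eigenvalue > 1); loadings are reported as
  variable–component correlations with |loading| > 0.13 flagged; each
  component's sign is fixed so its largest-magnitude loading is positive, so
  tables are reproducible.
* `cdfa` — canonical discriminant function analysis via the generalized
  eigenproblem of between- versus pooled within-group covariance. For
  function $k$: share of discriminant variance $\lambda_k/\sum\lambda$,
  canonical correlation $\sqrt{\lambda_k/(1+\lambda_k)}$, Wilks'
  $\Lambda_k = \prod_{j\ge k} (1+\lambda_j)^{-1}$ with Bartlett's
  $\chi^2 = -(n-1-(p+g)/2)\ln\Lambda_k$ on $(p-k+1)(g-k)$ df.
  Coefficients are unstandardized, scaled so each function has unit pooled
  within-group variance (the SPSS convention), largest coefficient positive.
* `dapc` — discriminant analysis of principal components: the discriminant
  step runs on the first `n_pcs` (default 6) correlation-PCA scores, which
  keeps the within-group covariance well conditioned. Function coefficients
  are back-projected to the truss variables (PCA eigenvector row times
  discriminant coefficient vector) so a per-variable coefficient table is
  still available. Membership probabilities are Gaussian class posteriors in
  the (whitened) discriminant space; priors are proportional to group size
  by default (`priors = "uniform"` is available) — the choice matters for
  unequal designs like 43 vs 10 and is recorded in the pipeline log.
* `roc_auc` — one-vs-rest ROC per group. The score is the group's
  membership probability (recorded in the output metadata; other scores are
  possible and none is canonical). AUC uses the Mann–Whitney pair-counting
  identity with ties counted 1/2, and is graded 0.9–1.0 "outstanding",
  0.8–0.9 "excellent".

A near-singular pooled within-group covariance (condition beyond ~1e13) in
`cdfa` is refused with a pointer to DAPC rather than silently regularized.

## Procrustes shape analysis

`gpa` iterates translate/scale/rotate-to-consensus with the closed-form
optimal 2D rotation (reflections disallowed — specimens are digitized in a
consistent orientation), to a 1e-10 consensus tolerance, 100-iteration cap.
Aligned shapes have zero centroid and unit centroid size.

* **Distances.** Group-mean comparisons use the *full* Procrustes distance
  (relative scale optimized between unit-size shapes); `type = "partial"` is
  available everywhere. Residuals are computed elementwise rather than via
  $\sqrt{1-T^2}$, which would lose half the floating-point precision near
  zero. The distance choice is recorded in the output.
* **Procrustes ANOVA.** Centroid size: one-way ANOVA on log centroid size.
  Shape: Goodall-style F with shape dimensions pooled ($2k-4$ per specimen
  df) and p by label permutation, $p = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$,
  seeded and reproducible bit-for-bit. The permutation test is exactly
  calibrated (its type-I rate is the nominal level up to the granularity of
  $n_{perm}$).
* **Pairwise mean-shape tests** (`group_mean_tests`): per pair, full
  Procrustes distance between mean shapes with a within-pair label
  permutation p; Mahalanobis distance between means in a shape-PCA score
  space covering ≥ 95% of variance, capped at (pair size − 3) components so
  the pooled covariance stays invertible; leave-one-out cross-validated
  two-group assignment; and per-landmark mean-difference ("lollipop")
  vectors. Groups under 3 specimens are skipped with a warning.
* **Shape PCA rank.** GPA removes the 4 similarity degrees of freedom to
  first order only — the unit-size constraint is a sphere — so eigenvalues
  beyond $2k-4 = 14$ are not exactly zero but second-order small; the
  package's tests bound them at 1e-4 of the leading eigenvalue.

## Thin-plate splines, warp scores, modularity

`tps_fit` solves the bordered system for the kernel $U(r) = r^2\log r^2$;
the bending-energy matrix is the upper-left block of the inverse, which
annihilates affine functions of the reference. Energy is zero iff the target
is affine in the reference, and is invariant under rigid motions of the
target (general affine maps of the *target* rescale it — only the affine
*null space* is exact).

`relative_warps(alpha)` weights the non-affine eigendirections of the
consensus bending energy by $\lambda^{-\alpha/2}$ ($\alpha = 0$, the
default, is exactly `shape_pca`; $\alpha > 0$ emphasizes small-scale
deformation). Two group-level summaries are reported per shape PC:

* **Principal score ratio (PSR)** — the ratio of the tabulated extreme
  deformation pair, maximum-score extreme over minimum-score extreme, *as
  printed* (the "max" entry of a published pair may be the smaller number,
  giving PSR < 1 — the published ratios themselves behave this way, which is
  how the formula was fixed). In-package extremes are the square-root
  bending energy of the TPS warp from the consensus to the shape
  reconstructed at the group's extreme score; any proportional definition
  gives the same ratio.
* **Warp density score (WDS)** — no published definition exists, so the
  package defines it as the sum over the group's specimens of weight ×
  score, with bending-energy weights normalized to mean 1 by default; the
  formula is pluggable (`weights =`) and stamped into the result, and WDS is
  excluded from any cross-study comparison.

`rv_modularity` computes the Escoufier RV between a landmark block (presets:
hump {1, 8, 9}, fins {4, 5, 6}) and its complement on the aligned
coordinates, and situates it among all cyclically contiguous partitions of
the same sizes plus seeded random partitions.

## The synthetic-data generator

There is no public generative model for this kind of data, so the package
defines the simplest one that exercises every stage (`shape_model`,
`generate_dataset`): group mean shape = a stylized knifefish template plus a
per-group, per-landmark offset; specimen size = standard length drawn
uniformly from `size_range`; coordinates = size × mean shape + isotropic
Gaussian digitization noise. The template is expressed in units of standard
length (so the size factor *is* SL in mm and generated coordinates are mm);
offsets are in template units. Non-isometric growth is available by letting
one landmark's displacement from the body centroid grow as $s^b$
(`allometry_b`, default 1 = isometry). `known_truth` returns the exact group
mean shapes and their pairwise full Procrustes distances for
parameter-recovery tests, independent of the seed.

`study_design_model` fixes the conditions used throughout the tests: seven
river groups of 43/16/31/16/13/20/10 specimens (149 total), nine landmarks,
standard lengths 250–600 mm, digitization noise 0.5 mm, and offset
directions touching the hump, fin and head landmarks. The default offset
magnitude (0.004 template units ≈ 1.7 mm at the mean size, ~3 noise SDs per
displaced landmark) was chosen once as a realistic degree of phenotypic
overlap — groups separate well but not trivially.

What the generator deliberately does **not** emulate: size differences
between groups (sizes are i.i.d. across groups, so centroid-size ANOVAs are
null here while real populations often differ); allometric curvature of the
whole configuration (only one landmark bends); correlated digitization error
(noise is i.i.d. per coordinate, whereas operator error is often shared
within an image); and any specific river's actual mean shape. Passing tests
therefore demonstrate correctness of the computations and calibration of the
tests, not agreement with any particular river's published statistics — the
published per-river tables can only be reproduced from the original
specimens, and the package's checks against them are limited to the
quantities whose inputs are printed (e.g. the PSR extreme pairs).

## Numerical and reproducibility choices

* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; pairwise tests derive per-pair seeds from the master
  seed so results do not depend on pair order.
* GPA tolerance 1e-10, cap 100 iterations (convergence for this data is
  2–4 iterations); eigen-sign conventions as above; permutation p-values
  use the add-one form so $p \in (0, 1]$.
* Degenerate inputs fail loudly and by name: zero-size configurations,
  constant variables, nonpositive values under log, collinear TPS
  references, groups below minimum sizes.
* All text output (TPS, CSV) uses fixed 6-decimal formatting, so rerunning
  a pipeline with the same config and seed is byte-identical.
* The end-to-end pipeline runs in seconds at study scale (149 × 9
  landmarks, 999 permutations); no stage caching is implemented — rerunning
  from scratch is cheaper than maintaining cache state, and the flat-CSV
  bundle stays the only artifact.
* Test problem sizes: convergence checks use up to 200 specimens per group;
  calibration of the shape permutation test uses 200 null datasets of 36
  specimens at 199 permutations; oracle comparisons (rotation grid search,
  AUC pair counting) run at desk scale.

## Worked pipeline

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 42, n_perm = 199))
res$pca            # eigenvalues, Kaiser retention
res$dapc           # functions, Wilks, centroids, posteriors
res$pair_tests     # pairwise mean-shape tests
list.files(res$config$out_dir)
```

## Known limitations

* 2D landmarks only; no sliding semilandmarks, no 3D.
* CDFA coefficient *magnitudes* depend on the preprocessing scale;
  comparisons with published coefficient tables are meaningful for sign and
  ordering only.
* The Mahalanobis distances of `group_mean_tests` depend on the retained
  shape-PCA dimension (95% coverage by default, configurable); published
  values from other software may use a different cap.
* The PSR extreme magnitudes and WDS are package-defined summaries (see
  above); their ratios/shapes are comparable across runs of this package,
  not across software.
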