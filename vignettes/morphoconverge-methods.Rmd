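---
title: "morphoconverge: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphoconverge: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoconverge)
```

## The scientific setting

The package analyses 3D landmark configurations from a crossed two-factor
design: *lineage* (two domestic breeding lines, DE and DL, plus a wild
out-group) by *time period* (historic vs modern). The scientific question is
whether the two domestic lineages, kept genetically separate but bred under
the same industrial selection goals, have **converged** in skull shape over
roughly a century. The analysis chain is: Procrustes superimposition with
object symmetry → shape PCA → permutation ANOVA and pairwise tests on size
and shape → a convergence index with a randomization null.

## Superimposition

Shape is what remains of a landmark configuration after position,
orientation and scale are removed. `gpa()` implements the full Procrustes
fit: every configuration is centered, scaled to unit centroid size
(CS, the square root of summed squared landmark distances from the
centroid), and rotated to minimize its summed squared distance to a
consensus; the consensus is the mean of the aligned configurations,
re-scaled to unit CS, and the procedure iterates until the summed squared
change of the consensus falls below `tol = 1e-10` (cap 100 iterations; both
arguments are exposed). No partial-Procrustes re-scaling step is applied:
configurations stay at unit CS, matching the default behaviour of the
standard morphometrics toolchains. Reflections are never allowed in the
rotation solution (`det(R) = +1` is enforced by sign-flipping the smallest
singular direction), because biological left and right are not
interchangeable.

Two deliberate numerical choices:

- **Canonical orientation.** After convergence the whole sample is rotated
  so the consensus sits in its principal-axes frame. Axis signs are fixed by
  the cube-sum of the landmark coordinates along each axis; for a
  bilaterally symmetric consensus that functional vanishes identically along
  the symmetry axis, so only the two axes where it is largest are sign-fixed
  directly and the third follows from right-handedness. This makes GPA
  output invariant (to ~1e-11) to the position, orientation, scale *and
  input order* of the specimens — without it, results would depend on which
  specimen happens to be the initial reference.
- **Polish pass.** One extra align-and-average pass runs after the tolerance
  is met, so the endpoint does not inherit an O(sqrt(tol)) dependence on the
  starting reference.

**Object symmetry.** A skull is a single bilaterally symmetric object, so
`symmetric_gpa()` superimposes the doubled sample — each configuration plus
its reflected copy with left/right landmark labels swapped
(`reflect_relabel()`) — and keeps, per specimen, the average of the two
aligned copies. This *symmetric component* is what all downstream statistics
consume; the asymmetric remainder (fluctuating asymmetry) is out of scope.
The symmetric component of a unit-CS configuration has CS marginally below 1
(averaging shrinks), which is why the package does not re-scale it: the
shrinkage is part of the standard construction. Tangent-space projection is
available (`tangent = TRUE`) but off by default; in the small-variation
regime of this design it changes coordinates by well under 1e-3 and no
downstream conclusion.

## Ordination

`shape_pca()` is covariance PCA of the mean-centered flattened
`(x1, y1, z1, ..., xk, yk, zk)` coordinates, computed by SVD. Numerically
null components (singular value below 1e-10 of the largest) are dropped;
variance proportions are taken over the full trace, so they sum to 1.
Axis signs follow one deterministic convention — the largest-magnitude
loading of each axis is positive — so scores are reproducible across
platforms and runs. `project()` maps any shape (group means, consensus,
new specimens superimposed in the same system) into a fitted morphospace;
because PCA is linear, projected group means land exactly on the centroids
of their members' scores, which the tests exploit as an oracle.

## Permutation statistics (RRPP)

All hypothesis tests use residual randomization in a permutation procedure:
the response (n × q matrix; q = 1 for log CS, q = 3k for shape) is never
permuted raw. For a term of the model `~ period + lineage + period:lineage`,
the *reduced* model contains exactly the terms the tested term is adjusted
for under **Type II** sums of squares (each main effect adjusted for the
other main effect; the interaction adjusted for both). Each of `n_perm`
iterations permutes the reduced-model residual rows, adds back the
reduced-model fitted values, and recomputes the term's F on the randomized
response. Conventions, all visible in the output:

- `p = (1 + #{F* >= F_obs}) / (1 + n_perm)` — the observed statistic counts
  in its own null, so the smallest attainable p with 999 permutations is
  0.001. Ties count as `>=` (conservative) with a 1e-8 relative tolerance,
  which matters when a permutation reproduces the observed statistic exactly
  (e.g. the group-complement assignment in a two-group design).
- Effect size `Z` is computed on ln F for ANOVA terms (the F null is
  right-skewed) and on the raw statistic for pairwise distances and variance
  differences; negative Z simply means the observed value sits below the
  null mean.
- The same integer seed reproduces every p and Z bit-identically.

On balanced orthogonal designs Type II SS coincides with sequential Type I
SS (tested to 1e-9), and for q = 1 one-way balanced designs the F statistic
equals the classical ANOVA F to 1e-10 with the permutation p matching
exhaustive enumeration exactly on n = 8 designs.

## Pairwise tests and their null models

`pairwise_means()` compares least-squares cell means (for the full factorial
these are the cell means) by Euclidean distance in the flattened coordinate
space, by default only for the study's nested contrasts: historic vs modern
within each lineage. The null distribution permutes reduced-model residuals.
**The choice of reduced model is the one genuinely open design decision in
this package, and it has teeth:**

- The reference tooling's scheme — and this package's default,
  `null_model = "additive"` — permutes residuals of `~ lineage + period`.
  Because the fitted period effect is added back into every randomized
  dataset, each null distance contains a fixed vector whose *norm* adds to
  the permuted noise. In high dimension (here ~125 effective shape
  dimensions) norms concentrate, so the null distances sit systematically
  above the observed one whenever the true period effect is small: observed
  Z becomes strongly negative and p approaches 1. Measured under a true
  null, the type-I rate of this scheme is 0 (not ~0.05): it is *valid* but
  badly conservative for within-lineage contrasts on shape data. The
  original study's tables carry the same signature (a null contrast printed
  with Z ≈ −4.5 and p = 1.000), which is strong evidence this is what its
  software did — so the faithful scheme stays the default.
- `null_model = "lineage_only"` permutes residuals of `~ lineage`, treating
  *any* period-linked difference (main effect or interaction) as signal for
  the nested contrasts. Under a true period-free null this variant is
  essentially calibrated (measured rejection 0.06–0.08 at α = 0.05, mildly
  liberal on the full-size design), and it is the variant
  a user should choose when the question is "did this lineage change at
  all between periods".

When only one of the two factors varies (a two-group comparison), the
additive reduced model would contain the tested difference itself; the null
then drops to the intercept, recovering the classic one-way RRPP test.

`procrustes_variance()` uses the disparity convention: mean *squared*
distance from the group mean, divided by n (not n − 1).
`pairwise_variances()` tests |PV_a − PV_b| by permuting the residuals of the
full factorial model — deviations from cell means — which homogenizes group
variances while leaving mean structure intact; group mean offsets cancel
exactly in PV, so this test does not suffer the norm-inflation issue and is
calibrated as measured (type-I ≈ 0.05).

## The convergence index

`mci()` computes

> MCI = PV(pooled historic DE + DL) / PV(pooled modern DE + DL)

with each pooled Procrustes variance taken about the pooled sample's own
mean. Two documented interpretive choices:

- **Orientation.** The index is oriented so values above 1 indicate
  convergence (the modern pooled variance is the denominator). The source
  study's prose describes the ratio in the opposite order but applies the
  ">1 means convergence" decision rule, and reports an MCI of 1.46 as
  convergence; the decision rule wins.
- **Pooled rather than summed within-lineage variance.** Convergence must
  register the shrinking *between*-lineage separation, which only the pooled
  variance about the joint mean contains. This is the single biggest
  interpretive choice in the package. With cell fractions f1, f2 of a pooled
  period sample and lineage means ±d·u, the between part contributes
  4·f1·f2·d² to the pooled PV, which is how the generator's
  `expected_mci()` oracle is built.

`mci_test()` randomizes the historic/modern labels `n_rand` times —
**stratified within lineage** by default, preserving the unbalanced per-cell
counts (28/20 and 23/16 in the emulated design) — and reports the one-sided
`p = (1 + #{MCI* >= MCI_obs}) / (1 + n_rand)` toward convergence, plus the
null mean. Unstratified shuffling is available behind
`stratified = FALSE` for sensitivity analysis. Exact identities hold by
construction: swapping the period labels inverts the index, and relabeling
which lineage is DE vs DL changes nothing.

## The synthetic world

`simulate_dataset()` states a world rather than tuning one:

| parameter | default | meaning |
|---|---|---|
| `k_pairs`, `k_midline` | 35, 12 | 82 landmarks, as in the emulated protocol |
| `n_per_cell` | 28/20, 23/16, 33/15 | historic/modern cell sizes for DE, DL, wild |
| `lineage_offset` d | 0.02 | half-separation of DE and DL means along a shared shape direction u (template has unit CS, so these are Procrustes units) |
| `period_shift` τ | 0.01 | shift of all modern means along a second direction v |
| `convergence` c | 0 | modern lineage offsets scaled by (1 − c); c > 0 converges, c < 0 diverges |
| `wild_offset` | 0.06 | wild group displacement along its own direction w (creates the dominant PC1 separation) |
| `noise_sd` σ | 0.002 | per-coordinate Gaussian noise in shape space |
| `size_mean`, `size_cv` | 600/620, 590/615, 420/430; 0.06 | lognormal centroid sizes, wild smaller than domestic as observed |

Effect directions u, v, w are drawn once per seed: random vectors
symmetrized under reflect-relabel, projected off the template's
similarity-transform tangent space (translations, rotations, scaling), and
orthonormalized. Symmetry makes them survive the symmetric-component
averaging; tangent-orthogonality makes the nominal effect sizes survive
superimposition approximately unchanged. Noise is applied in shape space
*before* the random rotation/translation/scaling, so σ maps directly onto
Procrustes-variance expectations. Where the emulated study fixes no value
(σ, d, τ, sizes), the defaults were chosen once so that the c = 0.5 world
has an expected MCI of about 1.5 — the regime the study reports — and were
not revisited afterwards.

`expected_mci()` is the analytic oracle:

> MCI ≈ [(n_h−1)/n_h · (σ_e² + 4 f1h f2h d²)] /
> [(n_m−1)/n_m · (σ_e² + 4 f1m f2m ((1−c) d)²)]

where σ_e² = σ²(d_s − 4) is the post-superimposition symmetric-component
noise variance: the symmetric subspace has d_s = 3·k_pairs + 2·k_midline
dimensions, of which 4 similarity directions (the two in-plane translations,
the rotation about the symmetry axis, and scaling) are removed by GPA. The
oracle was verified against brute-force simulation *before* being used in
any test (agreement within 1% at c ∈ {0, 0.25, 0.5}; the acceptance suite
re-checks within 5% at 500 replicates). Note the exact-balance corollary:
with equal cell sizes and c = 0 the expression is exactly 1, while the
emulated unbalanced design gives ≈ 1.01 — the mixture weights, not an
error.

## What a green test establishes — and what it does not

The generator emulates the *statistical structure* the analysis assumes:
crossed factors, isotropic landmark noise, linear effect directions,
lognormal sizes, exact bilateral symmetry of the template. Real skulls
violate several of these gracefully: measurement error is landmark-specific
and correlated, within-group covariance is structured (allometry, modules),
asymmetry is biological signal, and effects need not be low-dimensional.
Green tests therefore establish that the *machinery* is correct (invariances
hold, statistics match their oracles, tests hold their levels in the stated
world), not that the pipeline would recover truth under arbitrary real-data
pathologies. In particular no test here validates landmarking protocols,
scanning, or imputation — specimens with missing landmarks are rejected, by
design.

## Degenerate inputs and numerical policies

- Configurations with non-finite coordinates, or fewer than 4 landmarks, are
  rejected at construction with the specimen and landmark named (1-based).
- Zero centroid size (all landmarks coincident) raises a degenerate-
  configuration error when scaling is attempted.
- Collinear configurations make the rotation non-unique and raise an error.
- Empty lineage × period cells are named in ANOVA/pairwise errors; constant
  responses are an error (nothing to test).
- Coordinates are written with 17 significant digits; all file round trips
  are lossless to below 1e-12.
- GPA tolerance 1e-10 (summed squared consensus change), cap 100 iterations,
  both configurable; non-convergence is an error reporting the last change.

## Pipeline

`run_pipeline()` executes the full study workflow from one `run_config()`
(mandatory seed): load or simulate → symmetric GPA → log-CS ANOVA with
within-lineage pairwise mean/variance tests → shape PCA and ANOVA on the
full dataset (A) → shape PCA/ANOVA on the domestic-only dataset (B) → MCI
test. Dataset B is **re-superimposed by default** (the study reports a
separate PCA with its own variance percentages, implying a fresh fit);
`refit_subset = FALSE` reuses the full-data superimposition, and the report
records which was done. Every stochastic stage derives its seed from the
config seed, so a rerun is reproducible; each stage logs its elapsed time
and a failure writes a FAILED marker naming the stage while retaining
earlier outputs.

## Known limitations

- No sliding semilandmarks, no missing-landmark imputation, no allometry
  regression, no sexual-dimorphism testing, no mesh/surface handling —
  all outside the emulated study's analysis chain or explicitly unexamined
  by it.
- The default pairwise mean test inherits the reference tooling's
  conservatism on high-dimensional responses (see above); users wanting
  calibrated nested contrasts must opt into `null_model = "lineage_only"`.
- The MCI null under stratified randomization is slightly above 1 on
  average in unbalanced designs (the emulated study's own null mean was
  1.144); the test is one-sided against that empirical null, so this is
  accounted for, but the index itself should not be read as unbiased.
- `expected_mci()` is a small-noise tangent-space approximation; it flags
  parameter sets outside that regime rather than pretending accuracy.
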