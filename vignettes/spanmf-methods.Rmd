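---
title: "Methods: SPA-initialized NMF for tissue segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPA-initialized NMF for tissue segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanmf)
```

## The model

The package factorizes a non-negative feature matrix `X` (m features ×
n voxels) as `X ≈ W H` with `W ≥ 0` (m × r source signatures) and
`H ≥ 0` (r × n abundances), minimizing the Frobenius misfit
`½‖X − WH‖²_F`. In tumor imaging the sources are tissue signatures
(normal brain, edema, active tumor, necrosis) and the abundance rows are
their per-voxel proportions. The problem is non-convex; every solver
here finds a local optimum whose quality depends on the starting point
`(W₀, H₀)`.

### Geometry and the SPA initializer

When every tissue appears *pure* in at least one voxel and abundances
(approximately) sum to one — the near-separable regime — the voxel
columns of `X` lie in the convex hull of the pure columns, and the
sources are the hull's vertices. The successive projection algorithm
exploits this: it repeatedly selects the column of maximal squared ℓ₂
norm and projects the working matrix onto the orthogonal complement of
the selected column. The maximal-norm point of a polytope is a vertex,
so under separability each step returns a pure voxel of a new source.
`spa_select_columns()` implements exactly this recursion; `init_spa()`
stores the selected *original* columns as `W₀` (the projected residuals
are only internal state) and computes `H₀` by exact non-negative least
squares. The construction is deterministic and costs O(mnr).

Two conventions are fixed where the procedure itself is silent:

* **Tie-breaking.** An argmax tie in the norm selection is broken toward
  the smallest column index, making selections bit-reproducible.
  Duplicated pure voxels are all eligible; whichever has the smallest
  index wins.
* **Indexing.** All column indices are 1-based, as everywhere in R.

A selection step whose best remaining squared norm falls below
`1e-12 · ‖X‖²_F` aborts with a rank-deficiency error naming the step:
asking for more sources than the data's numerical rank is a user error
we refuse to hide.

### Comparison initializers

* `init_random()`: i.i.d. Uniform(0, 1) factors from a seeded stream —
  the field's benchmark, used inside best-of-k restarts.
* `init_nndsvd()`: truncated SVD with each rank-1 term replaced by the
  dominant non-negative part of its singular-vector split. Of the two
  candidate sign combinations the one with the larger product of factor
  norms is kept, following the original construction. Exact zeros left
  by the positive-part split would be frozen forever by multiplicative
  and squared-variable solvers, so every zero is replaced by 1% of the
  mean positive entry of its factor. SVD signs are canonicalized
  (largest-magnitude entry of each left singular vector made positive)
  so repeated runs are bit-identical.
* `init_fcm()`: fuzzy c-means on the voxel columns; centroids become
  `W₀`, membership rows become `H₀`. Fuzzifier 2.0, stopping when the
  largest membership change drops below 1e-5 or after 300 sweeps —
  standard defaults, all exposed as arguments. FCM is initialized with
  random memberships (the classical algorithm), so like random
  initialization it runs under the restart scheme.

For convex NMF every initializer's `H₀` is converted to starting weights
by `A ≈ H₀ᵀ(H₀H₀ᵀ)⁻¹`, clipped to its positive part and shifted by
0.2 × the mean absolute nonzero entry, which keeps `A₀` strictly
positive. If `H₀H₀ᵀ` is numerically singular a ridge of
`1e-10 · trace/r` is added — the construction assumes invertibility and
the ridge only guards against degenerate inputs.

## Solvers and the common stopping contract

All solvers record `‖X − WH‖_F` per outer iteration, **including
iteration 0**, so "head-start" comparisons between initializations are
computable from the traces. Every solver stops when the relative change
of the residual between successive outer iterations falls below `tol`
(default 1e-5) or after `max_iter` (default 10000) iterations; the
reported iteration counts are therefore comparable across solvers.
These defaults are the study settings used throughout; both live in
`nmf_control()`.

* **aHALS** — alternating exact rank-one coordinate updates of the rows
  of `H` and columns of `W`, with cheap inner passes repeated up to
  `1 + ⌊α · flop-ratio⌋` times (α = 0.5) and an early exit when a pass
  moves the factor by less than 1% of the first pass. Denominators and
  updated entries are floored at 1e-16: division safety without
  perturbing converged values. A block that collapses to zero is reset
  to small random values with a warning — the standard HALS safeguard.
* **Gauss–Newton trust region (GD)** — substituting `W = U∘U`,
  `H = V∘V` removes the constraints; the resulting nonlinear
  least-squares problem is attacked with Gauss–Newton steps globalized
  by a trust region. The linearized subproblem is solved by truncated
  conjugate gradients on Jacobian–vector products (the Jacobian is never
  formed), with relative tolerance `min(0.1, √‖g‖)` and at most 100 CG
  iterations. Radius management uses the standard 0.25/0.75 acceptance
  thresholds with ×0.25 / ×2 updates from an initial radius of 1.0; a
  rejected step shrinks the radius and retries *within* the same outer
  iteration, so the recorded trace only ever sees accepted (descending)
  steps, and a radius collapse below 1e-14 is reported as convergence to
  tolerance. No CG preconditioning is applied. Because squared variables
  freeze exact zeros, strictly positive starts (e.g. NNDSVD after its
  zero fix) are recommended.
* **Projected gradient (PG)** — alternating non-negative least-squares
  subproblems, each solved by projected gradient with the Armijo rule
  along the projection arc (sufficient decrease σ = 0.01, backtracking
  ratio β = 0.1, step size carried across iterations). Subproblem
  tolerances start at 1e-3 × the initial gradient norm and shrink by
  ×0.1 whenever a subproblem converges immediately.
* **Convex NMF** — constrains sources to the data's column space,
  `W = XA`, and updates `A` and `H` multiplicatively with the standard
  square-root rules. Because the input is non-negative, the Gram matrix
  `K = XᵀX` is non-negative and the negative-part terms of the general
  rules vanish; the implementation additionally routes all products
  through `W = XA` so the n × n Gram matrix is never formed (n is
  typically thousands of voxels). Denominators are floored at 1e-16.

`run_with_restarts()` makes the non-deterministic initializers
reproducible: seeds `base_seed … base_seed + k − 1`, return the run with
the lowest final residual, ties to the smallest seed, all finals
recorded. Fuzzy clustering is re-run with a fresh seed on every restart
— the closest reading of "repeatedly run NMF with randomly initialized
FCM".

### Hierarchical NMF

`hnmf()` splits the problem in two levels: a rank-2 aHALS factorization
separates two broad compartments; each voxel joins the branch of its
larger level-1 abundance (ties to branch 1); each branch is factorized
again at ranks `r₁` and `r − r₁` (default split `⌈r/2⌉`, user-settable);
the pooled sources are recombined over *all* voxels by exact NNLS. The
dominant-abundance branch rule is the simplest quantitative reading of
"assign tissue types most similar to the same source"; tissue-semantic
assignment heuristics are out of scope. The chosen initializer is
applied at both levels. A branch receiving fewer voxels than its rank is
an error naming the branch.

### Why convex NMF plateaus

On noiseless separable phantoms the unconstrained solvers reach relative
residuals below 1e-3 from an SPA start. Convex NMF does not: the
mandatory dense offset in `A₀` starts it far from the sparse exact
solution, and multiplicative pruning of superfluous weights is
sublinear, so the relative-change rule fires (after thousands of
iterations) while a residual of order 1e-2 remains. This mirrors the
known behavior of the constrained formulation — it trades residual for
interpretability — and is asserted as such in the tests rather than
pretended away.

## Segmentation and validation

`segment_abundances()` turns abundances into hard labels by k-means
(k = r) on the abundance columns with centroids initialized at the
one-hot vectors, so cluster k inherits source k's identity. Columns are
sum-normalized first (default): mixed voxels then live on the simplex
where the one-hot centroids are commensurate. Lloyd iterations run to a
1e-6 centroid-shift tolerance (300 max); an emptied cluster keeps its
previous centroid; all-zero columns get label 0 and are excluded.
Whether to cluster raw or normalized abundances is genuinely open; the
normalized default is exposed as an argument.

NMF returns sources in arbitrary order, so `match_sources()` resolves
the permutation against a reference by maximizing summed cosine
similarity (scale-invariant, matching NMF's scale ambiguity), solved
exactly by dynamic programming over subsets. In clinical work the
radiologist's labels anchor tissue identity; on phantoms the generator's
ground truth plays that role.

Validation uses the Dice score `2|A∩B|/(|A|+|B|)` over the three nested
tumor classes (active ⊂ core ⊂ whole). Conventions: two empty masks
score 1 (perfect agreement on absence), empty vs non-empty scores 0.
Paired method comparisons use a one-tailed Wilcoxon signed-rank test
with zero differences dropped and midranks under ties; the null
distribution is enumerated exactly (a generating-function convolution
over doubled ranks, valid under ties) for up to 25 nonzero pairs, and a
tie- and continuity-corrected normal approximation beyond.

## The phantom generator

`make_phantom()` emulates the *statistical structure* the method
assumes, not the physics that produces it:

* **Geometry**: concentric tumor (necrotic center ⊂ active rim ⊂ edema
  halo ⊂ normal background) on a 64 × 64 grid by default — chosen so the
  three nested evaluation classes are non-trivial.
* **Signatures** `W*`: per-source log-uniform feature profiles on
  [0.1, 10] (feature intensities in arbitrary units spanning two
  decades), redrawn until pairwise cosine similarity ≤ 0.97 so no two
  tissues are near-collinear. m = 24 features matches a realistic
  multi-parametric feature count.
* **Abundances** `H*`: interior voxels are pure with probability
  `purity` (default 0.6), otherwise Dirichlet-mixed with concentration
  `mixing_sharpness` (default 8) on the region's tissue; boundary voxels
  are two-tissue Dirichlet mixtures of the adjacent tissues. Columns sum
  to one exactly. Setting `pure_pixel[k] = FALSE` demotes tissue k's
  pure voxels to fixed 0.9/0.1 mixtures with the spatially adjacent
  tissue — the partial-volume mechanism by which low-resolution
  spectroscopic channels break the pure-pixel assumption.
* **Ground truth labels** are the argmax of `H*` per voxel: a rater
  labels the *dominant* tissue. On interior voxels this provably agrees
  with the geometric region (mixed draws are re-oriented so the region's
  tissue stays dominant); on boundary voxels it resolves the mixture
  honestly. The geometric stencil is kept as `region_map`. Defining
  truth by the stencil instead would systematically reward endmembers
  contaminated toward the neighboring tissue, which is exactly the
  failure mode the pure-pixel experiments are meant to expose.
* **Noise**: additive Gaussian scaled to a target SNR (dB, Frobenius
  power ratio; default 30), truncated at zero to keep `X` non-negative.
  At the default SNR the truncation is negligible and the realized SNR
  (recorded in the object) sits within a fraction of a dB of the target.
  Clinical acquisitions come with no usable noise characterization; the
  truncated-Gaussian model is a modeling choice, not a data fact.

What the phantom does **not** emulate: MR acquisition physics,
metabolite spectra, spatial noise correlation, rater variability, or
multi-subject heterogeneity. Passing the phantom suite shows the
pipeline recovers the structure it assumes, at the assumed noise level —
not that it matches clinical Dice ranges, which depend on data that
cannot be shipped.

## Initialization versus direct extraction

SPA can be used two ways: its `(W₀, H₀)` segmented directly, or as the
start of an NMF solver. On phantoms where one pathologic tissue has no
pure voxel, the solver demonstrably refines the contaminated source
(its angle to the true signature shrinks), yet the *hard-label* Dice
comparison between the two uses is essentially a tie at the package's
study conditions: a 0.9/0.1 vertex contamination displaces the endmember
by only a degree or two, and nearest-centroid labeling is invariant to
basis shifts that small, so per-class Dice differs by single boundary
voxels with no stable sign. The refinement benefit is real but lives in
source and abundance accuracy, below the resolution of hard
segmentation overlap on these phantoms. Stronger violations (larger
contamination, lower SNR, less pure data) would be needed for the
ordering to show up in Dice — a useful caution when interpreting
segmentation-level comparisons of initialization strategies in general.

## Problem sizes and tolerances in the tests

Unit tests run on small random instances (matrices around 10 × 50) and
24 × 24 phantoms; end-to-end and stability properties run on the default
64 × 64 phantom across 20–50 seeds with the study stopping settings.
Descent properties are asserted to 1e-9 (exact block-coordinate and
multiplicative updates are monotone up to the 1e-16 safety floors),
orthogonality and column-space invariants to 1e-8, and oracle
equivalences (combinatorial NNLS vs per-column active set, projected
gradient vs NNLS, exact Wilcoxon vs brute-force enumeration) to 1e-8 or
tighter. Independent oracles are kept independent: the NNLS engine is
checked against a separate active-set implementation, fuzzy c-means and
k-means against their reference implementations, and the signed-rank
test against full enumeration of all sign patterns.

## Known limitations

* SPA is sensitive to outliers (a gross outlier is a hull vertex);
  outlier-robust variants and pre-screening are deliberately out of
  scope.
* Convex NMF inherits the slow tail convergence of multiplicative
  updates; expect thousands of iterations and a residual floor above the
  unconstrained solvers.
* The rank `r` is an input; rank estimation is out of scope.
* The hierarchical split is purely data-driven (dominant rank-2
  abundance); no anatomical priors are used.
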