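# spanmf

Non-negative matrix factorization (NMF) for tissue segmentation of
multi-parametric imaging data, built around the **successive projection
algorithm (SPA)** as a fast, deterministic initializer.

## The problem

Multi-parametric MRI of brain tumors yields, per voxel, a vector of `m`
non-negative features (structural intensities, perfusion, diffusion,
metabolite levels). Arranged as a matrix `X` (m features × n voxels), an
additive mixture model

```
X ≈ W H,   W ∈ R+^{m×r},  H ∈ R+^{r×n},
min_{W,H ≥ 0}  ½ ‖X − WH‖²_F
```

decomposes each voxel into `r` tissue-specific source signatures (columns
of `W`) weighted by per-voxel abundances (rows of `H`). Thresholding /
clustering the abundances segments the image into tissue compartments —
here the glioma classes **active tumor**, **tumor core** (active +
necrosis) and **whole tumor** (core + edema).

NMF is non-convex: the solution quality depends on the initialization of
`(W₀, H₀)`. Under near-separability (every tissue appears pure in at
least one voxel, abundances approximately sum to one), the data columns
span a convex hull whose vertices are the pure voxels. SPA finds those
vertices greedily: pick the column of largest ℓ₂ norm, project all
columns onto its orthogonal complement, repeat `r` times. The selected
columns seed `W₀`; `H₀` follows by exact non-negative least squares. The
package is for researchers comparing NMF initialization strategies
(SPA, NNDSVD, fuzzy c-means, repeated random starts) across solvers
(accelerated HALS, Gauss–Newton trust region, projected gradient, convex
NMF, two-level hierarchical NMF) with segmentation-quality validation.

Since clinical cohorts are not distributable, the package ships a
synthetic phantom generator (`make_phantom()`) that emulates the data's
statistical structure: concentric tumor geometry, sum-to-one mixing,
controllable pure-pixel fractions and SNR, with full ground truth for
validation.

## Worked example

```r
library(spanmf)

ph  <- make_phantom(seed = 1)            # 64 x 64 grid, 24 features, SNR 30 dB
fit <- nmf(ph$X, r = 4, init = "spa", solver = "ahals")
fit
#> <nmf_fit> solver = ahals, init = spa, rank = 4
#>   74 iterations, converged = TRUE, ||X - WH||_F = 29.0

# align estimated sources with the ground truth and score the segmentation
perm <- match_sources(fit$W, ph$W_true)
cls  <- character(4); cls[perm] <- ph$class_of_source
seg  <- segment_abundances(fit$H)
dice_report(seg$labels, cls, ph$label_map_true, ph$class_of_source)
#> # A tibble: 3 × 5
#>   class   dice n_est n_ref n_intersect
#>   <chr>  <dbl> <int> <int>       <int>
#> 1 active 0.969   473   476         460
#> 2 core   0.987   731   732         722
#> 3 whole  0.991  1804  1804        1788
```

The aHALS solver, started from the deterministic SPA initialization,
converges in 74 iterations (relative residual change < 1e-5) and the
k-means segmentation of the abundances overlaps the ground-truth masks
with Dice scores of 0.97–0.99 for the three nested tumor classes.

Full comparison grids (initializers × solvers, with best-of-30 restarts
for the non-deterministic initializers and a direct-SPA baseline) run
through `run_pipeline()`; results come back as a tibble plus residual
traces, and `autoplot()` draws the convergence comparison. A thin
command-line wrapper with `phantom` / `factorize` / `benchmark` /
`validate` verbs lives at `inst/cli/spanmf.R`.

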