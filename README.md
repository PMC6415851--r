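# csvd — constrained singular value decomposition

Sparse SVD whose left and right pseudo-singular vectors are **sparse,
unit-norm, and mutually orthogonal at the same time**.

Sparse matrix decompositions are everywhere in high-dimensional biology and
psychometrics: only a handful of genes, voxels or questionnaire items should
carry each component, so the loadings are constrained in L1 norm.  The
standard tool — the penalized matrix decomposition (PMD) of Witten,
Tibshirani & Hastie — sparsifies one rank-one term at a time and relies on
deflation for orthogonality, which the non-linear thresholding silently
breaks: components beyond the true rank of the signal correlate with the
earlier ones and re-explain the same variance.  The constrained SVD (CSVD)
implemented here instead solves, for each component ℓ,

    max  pᵀXq   s.t.  ‖p‖₂ ≤ 1, ‖p‖₁ ≤ c₁, p ⊥ p₁…p_{ℓ−1}
    p,q               ‖q‖₂ ≤ 1, ‖q‖₁ ≤ c₂, q ⊥ q₁…q_{ℓ−1}

by block relaxation, where each update is a projection onto the intersection
of convex sets (POCS).  The intersection of the L1 ball and the unit L2
sphere is handled by a fast *exact* sort-based projection (`proj_l1l2()`):
the soft-threshold λ with ‖S(x,λ)‖₁/‖S(x,λ)‖₂ = c is located exactly via the
monotone ratio function ψ and a closed-form quadratic root.  The feasible
radii are c₁ ∈ [1, √I], c₂ ∈ [1, √J] (Cauchy–Schwarz both ways); the upper
bound reproduces the plain SVD.

The package ships:

* `csvd()` — the constrained decomposition (orthogonal + sparse);
* `pmd()` — the deflation-based baseline (sparse, not orthogonal);
* `power_svd_deflate()` / `power_svd_pocs()` — plain power-iteration SVD;
* `proj_l1()`, `proj_l2()`, `proj_l1l2()`, `proj_ortho()`, `pocs()`,
  `soft_threshold_vec()` — the projection toolbox;
* `make_ground_truth()`, `simulate_X()`, `run_benchmark()` and recovery
  metrics — a block-sparse rank-5 simulation benchmark;
* `cli_main()` / `inst/cli/csvd-cli.R` — a command-line interface
  (`decompose`, `simulate`, `evaluate`, `benchmark`) for delimited-text
  matrices.

## Worked example

A 40 × 60 matrix with one planted sparse rank-one signal on rows 1–8 and
columns 1–10, decomposed with L1 budgets 2.5 (left) and 3 (right):

```r
library(csvd)
set.seed(1)
X <- matrix(rnorm(40 * 60), 40, 60) +
  6 * tcrossprod(replace(numeric(40), 1:8, 0.35), replace(numeric(60), 1:10, 0.32))
dec <- csvd(X, R = 2, c1 = 2.5, c2 = 3)
dec
#> <csvd decomposition: 40 x 60, 2 component(s)>
#>   delta: 10.63  9.34
#>   converged: TRUE TRUE
colSums(abs(dec$Q))            # L1 budgets are active: 3 3
colSums(abs(dec$Q) > 1e-8)     # only 19-20 of 60 loadings survive
```

The first pseudo-singular value (10.63) captures the planted signal with a
sparse loading pattern; the second is orthogonal to it by construction.

The simulation benchmark (150 × 600, rank-5 signal with singular values
15…11, Gaussian noise sd 0.01; CSVD/PMD radii c₁ = 5, c₂ = 11, 7 components
requested):

```r
round(run_benchmark(seed = 1), 2)
#>      Order  CSVD   PMD   SVD GroundTruth
#> [1,]     1 14.80 14.80 15.00          15
#> [2,]     2 13.85 13.87 13.99          14
#> [3,]     3 12.63 12.69 13.01          13
#> [4,]     4 11.81 11.83 12.01          12
#> [5,]     5 10.93 10.94 11.02          11
#> [6,]     6  0.29  2.80  0.36           0
#> [7,]     7  0.28  2.16  0.36           0
```

Rows 6–7 are the point: past the true rank, the CSVD's extra components are
orthogonal residual noise (≈ 0.3), while PMD keeps extracting sizeable
pseudo-singular values (≈ 2–3) that correlate with components 1–5 — the
failure mode the orthogonality constraint removes.

The same pipeline from the shell:

```sh
Rscript inst/cli/csvd-cli.R benchmark --seed 1
Rscript inst/cli/csvd-cli.R simulate --outdir fixture --seed 1
Rscript inst/cli/csvd-cli.R decompose --input fixture/X.csv --outdir out \
    --method csvd --rank 7 --c1 5 --c2 11
Rscript inst/cli/csvd-cli.R evaluate --decomp out --truth fixture
```

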