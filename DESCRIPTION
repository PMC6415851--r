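Package: csvd
Title: Constrained Singular Value Decomposition with Sparse Orthogonal
    Components
Version: 0.1.0
Authors@R:
    person("Analysis", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse singular value decomposition whose left and right
    pseudo-singular vectors satisfy an L1 sparsity bound, a unit L2 norm,
    and mutual orthogonality simultaneously.  Constraints are imposed by
    projection onto intersections of convex sets (POCS) inside a power
    iteration, with a fast exact operator for the intersection of an L1
    and an L2 ball.  Includes the penalized matrix decomposition (PMD)
    baseline, an unconstrained power-iteration SVD with deflation, a
    block-sparse rank-5 simulation benchmark with recovery metrics, and
    a command-line interface for delimited-text matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
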