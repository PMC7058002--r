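Package: dvms
Title: Dynamic Voronoi Metropolis Sampling of Electronic Wavefunctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions the 3N-dimensional configuration space of an
    N-electron wavefunction into tiles related by permutations of
    like-spin electrons, locates self-consistent tile centroids by
    Metropolis sampling with node-crossing rejection (dynamic Voronoi
    Metropolis sampling), and Monte-Carlo-integrates the relative
    occupancy of competing tiles.  Includes Slater-determinant evaluation
    over Gaussian-basis molecular orbitals, Molden and CI-vector readers,
    linear-assignment permutation folding, truncation analysis of CAS-CI
    expansions, two-state occupancy kinetics, and cube/XYZ export of tile
    cross-sections.  Ships benzene RHF/6-31G(d) and CAS-CI fixtures used
    to analyse the competition between eclipsed and staggered Kekule
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
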