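# Analytic toy systems with known nodes and tiles.  All toys are built
# from the same Gaussian-basis machinery as the molecular systems, so
# every pipeline stage can be exercised against low-dimensional ground
# truth obtained by quadrature.

.TOY_REGISTRY <- c("two_electron_triplet", "two_plus_two", "double_well_ci")

#' Construct an analytic toy system
#'
#' Available toys:
#' \describe{
#'   \item{two_electron_triplet}{Two same-spin electrons in s-Gaussians
#'     (exponent 0.5) displaced to (+/-1, 0, 0) bohr.  The exact node is
#'     the hyperplane \eqn{x_1 = x_2}; the two tiles are its half-spaces
#'     and their centroids follow from quadrature.}
#'   \item{two_plus_two}{The separable 2 alpha + 2 beta product of two
#'     such pairs; 4 tiles indexed by each spin's ordering.}
#'   \item{double_well_ci}{One electron in a 2-configuration expansion
#'     \eqn{c_1 \phi_g + c_2 \phi_u} over symmetric/antisymmetric
#'     combinations of two wells at (+/-1.5, 0, 0); the coefficient
#'     ratio tunes the relative occupancy of the two wells --- the
#'     minimal analogue of competing resonance structures.}
#' }
#'
#' @param name toy name (see Details).
#' @param coef length-2 coefficients for \code{double_well_ci}
#'   (default \code{c(1, 0)}: symmetric, 50/50 occupancy).
#' @return list of class \code{dvms_toy} with \code{wf}
#'   (a \code{dvms_wavefunction}), \code{name}, \code{sites} (reference
#'   tile sites), and \code{reference} notes.
#' @export
make_toy <- function(name, coef = c(1, 0)) {
  if (!name %in% .TOY_REGISTRY)
    stop("unknown toy '", name, "'; registry: ",
         paste(.TOY_REGISTRY, collapse = ", "))
  if (name == "two_electron_triplet") {
    basis <- ao_basis(list(
      list(center = c(-1, 0, 0), l = 0L, exps = 0.5, coefs = 1),
      list(center = c(+1, 0, 0), l = 0L, exps = 0.5, coefs = 1)))
    mo <- list(C = diag(2), energy = c(0, 0), occupation = c(1, 1),
               orig_index = 1:2, label = c("occupied", "occupied"))
    ci <- single_determinant(2, 0)
    wf <- wavefunction(basis, mo, ci)
    sites <- list(
      voronoi_site(c(-1, 0, 0, 1, 0, 0), 2, 0, "left-right"),
      voronoi_site(c(1, 0, 0, -1, 0, 0), 2, 0, "right-left"))
    ref <- list(node = "x1 = x2 (sign of Psi follows sign of x2 - x1)",
                tiles = "two half-spaces; centroids symmetric under swap")
  } else if (name == "two_plus_two") {
    basis <- ao_basis(list(
      list(center = c(-1, 0, 0), l = 0L, exps = 0.5, coefs = 1),
      list(center = c(+1, 0, 0), l = 0L, exps = 0.5, coefs = 1)))
    mo <- list(C = diag(2), energy = c(0, 0), occupation = c(2, 2),
               orig_index = 1:2, label = c("occupied", "occupied"))
    ci <- single_determinant(2, 2)
    wf <- wavefunction(basis, mo, ci)
    s <- c(-1, 0, 0, 1, 0, 0)
    sw <- c(1, 0, 0, -1, 0, 0)
    sites <- list(voronoi_site(c(s, s), 2, 2, "LR-LR"),
                  voronoi_site(c(s, sw), 2, 2, "LR-RL"),
                  voronoi_site(c(sw, s), 2, 2, "RL-LR"),
                  voronoi_site(c(sw, sw), 2, 2, "RL-RL"))
    ref <- list(tiles = "4 product tiles, all equally probable")
  } else {
    basis <- ao_basis(list(
      list(center = c(-1.5, 0, 0), l = 0L, exps = 1.0, coefs = 1),
      list(center = c(+1.5, 0, 0), l = 0L, exps = 1.0, coefs = 1)))
    # MO 1 = symmetric, MO 2 = antisymmetric well combination
    mo <- list(C = cbind(c(1, 1), c(1, -1)), energy = c(0, 0),
               occupation = c(1, 0), orig_index = 1:2,
               label = c("occupied", "virtual"))
    ci <- ci_expansion(matrix(c(1L, 2L), 2, 1), matrix(integer(), 2, 0),
                       coef)
    wf <- wavefunction(basis, mo, ci)
    sites <- list(voronoi_site(c(-1.5, 0, 0), 1, 0, "left"),
                  voronoi_site(c(+1.5, 0, 0), 1, 0, "right"))
    ref <- list(cells = "x < 0 and x > 0",
                note = paste("well amplitudes (c1 + c2) and (c1 - c2);",
                             "equal coefficients concentrate the left well"))
  }
  structure(list(name = name, wf = wf, sites = sites, reference = ref),
            class = "dvms_toy")
}

#' @export
print.dvms_toy <- function(x, ...) {
  cat("dvms toy system '", x$name, "': ", sep = "")
  print(x$wf)
  invisible(x)
}

#' Grid quadrature of tile centroid and occupancy for small systems
#'
#' Deterministic (midpoint-rule) quadrature of \eqn{\Psi^2} over a
#' regular grid in the full 3N-dimensional configuration space,
#' restricted to the Voronoi cell of one site among the listed sites
#' under the plain (unfolded) Euclidean metric.  This is the right
#' notion for tiles given explicitly as permutation images of one
#' another (permutation folding would make such sites exactly
#' equidistant from every point).  Practical for 3N <= 6.
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param sites list of reference \code{dvms_site}s partitioning space.
#' @param which index of the tile of interest.
#' @param lim half-width of the integration cube per coordinate (bohr).
#' @param n grid points per dimension.
#' @return list with \code{centroid} (3N vector), \code{prob} (tile
#'   probability mass among the listed sites), \code{mass}.
#' @export
tile_quadrature <- function(wf, sites, which = 1, lim = 5, n = 13) {
  D <- 3 * wf$n_electron
  if (D > 6) stop("grid quadrature practical only for 3N <= 6")
  # midpoints of n equal cells over [-lim, lim]: no point ever sits on a
  # symmetry plane (cell boundary), where assignment would be arbitrary
  h <- 2 * lim / n
  g <- seq(-lim + h / 2, lim - h / 2, length.out = n)
  grids <- rep(list(g), D)
  X <- as.matrix(do.call(expand.grid, grids))
  w2 <- psi_value(wf, X)^2
  d2 <- vapply(sites, function(s)
    rowSums(sweep(X, 2, s$x)^2), numeric(nrow(X)))
  idx <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_len(nrow(d2)), idx)]
  d2[cbind(seq_len(nrow(d2)), idx)] <- Inf
  dsec <- do.call(pmin, as.data.frame(d2))
  on_boundary <- (dsec - dmin) < 1e-12 * (1 + dmin)  # cell boundary set
  sel <- idx == which & w2 > 0 & !on_boundary
  w2[on_boundary] <- 0
  mass <- sum(w2[sel])
  list(centroid = as.numeric(crossprod(X[sel, , drop = FALSE], w2[sel]) /
                               mass),
       prob = mass / sum(w2[w2 > 0]),
       mass = mass * h^D)
}
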