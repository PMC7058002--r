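# Permutation folding: map a configuration point into the reference
# Voronoi tile by the optimal like-spin relabelling (a linear-assignment
# problem per spin), with parity tracking.

#' Voronoi site
#'
#' A reference configuration-space point x-bar whose Voronoi cell (among
#' its like-spin permutation images) defines a wavefunction tile.
#'
#' @param x numeric 3N vector (alpha electron triples first, bohr).
#' @param n_alpha,n_beta electron counts per spin.
#' @param label descriptive label (e.g. \code{"eclipsed-A"}).
#' @return An object of class \code{dvms_site}.
#' @export
voronoi_site <- function(x, n_alpha, n_beta, label = "site") {
  x <- as.numeric(x)
  if (length(x) != 3 * (n_alpha + n_beta))
    stop("site length ", length(x), " != 3*(n_alpha+n_beta)")
  if (!all(is.finite(x))) stop("non-finite site coordinates")
  structure(list(x = x, n_alpha = n_alpha, n_beta = n_beta, label = label),
            class = "dvms_site")
}

#' @export
print.dvms_site <- function(x, ...) {
  cat(sprintf("dvms Voronoi site '%s': %d alpha + %d beta electrons\n",
              x$label, x$n_alpha, x$n_beta))
  invisible(x)
}

#' Parity of a permutation
#'
#' @param perm integer vector: a bijection of \code{1:length(perm)}.
#' @return +1 for even, -1 for odd permutations.
#' @export
permutation_parity <- function(perm) {
  perm <- as.integer(perm)
  if (length(perm) == 0) return(1L)
  if (!identical(sort(perm), seq_along(perm)))
    stop("not a permutation of 1..n")
  seen <- logical(length(perm))
  swaps <- 0L
  for (i in seq_along(perm)) {
    if (seen[i]) next
    j <- i
    len <- 0L
    while (!seen[j]) {
      seen[j] <- TRUE
      j <- perm[j]
      len <- len + 1L
    }
    swaps <- swaps + len - 1L
  }
  if (swaps %% 2L == 0L) 1L else -1L
}

#' Optimal fold of a configuration onto a Voronoi site
#'
#' Finds the like-spin relabelling (independently per spin, by solving a
#' linear-assignment problem with squared-distance costs) that minimises
#' the squared distance between the configuration and the site.  This is
#' equivalent to picking the nearest permutation image of the site, i.e.
#' to Voronoi classification among the Na! Nb! permuted sites.
#'
#' @param x numeric 3N configuration vector.
#' @param site a \code{dvms_site} (or bare 3N vector with \code{n_alpha},
#'   \code{n_beta} supplied).
#' @param n_alpha,n_beta electron counts, taken from \code{site} when it
#'   is a \code{dvms_site}.
#' @return list with \code{folded} (the relabelled configuration),
#'   \code{alpha_perm}, \code{beta_perm} (site slot j receives electron
#'   \code{perm[j]}), \code{parity} (product of the two permutation
#'   signs) and \code{sq_distance} (bohr^2).
#' @export
best_fold <- function(x, site, n_alpha = site$n_alpha,
                      n_beta = site$n_beta) {
  sx <- if (inherits(site, "dvms_site")) site$x else as.numeric(site)
  x <- as.numeric(x)
  if (length(x) != length(sx)) stop("configuration/site dimension mismatch")
  res <- .best_fold_cpp(x, sx, n_alpha, n_beta)
  res$folded <- as.numeric(res$folded)
  res
}

#' Nearest reference site under permutation folding
#'
#' @param x numeric 3N configuration vector.
#' @param sites list of \code{dvms_site} objects (>= 1).
#' @return list with \code{index} of the winning site (ties broken by
#'   lowest index), \code{fold} (its \code{best_fold} result) and
#'   \code{sq_distance}.
#' @export
nearest_site <- function(x, sites) {
  if (!length(sites)) stop("at least one site is required")
  na <- sites[[1]]$n_alpha
  nb <- sites[[1]]$n_beta
  S <- do.call(rbind, lapply(sites, function(s) s$x))
  res <- .nearest_site_cpp(as.numeric(x), S, na, nb)
  fold <- best_fold(x, sites[[res$index]])
  list(index = res$index, fold = fold, sq_distance = res$sq_distance,
       label = sites[[res$index]]$label)
}

#' Solve a square linear-assignment problem
#'
#' Minimises \code{sum(cost[perm[j], j])} over permutations.  Exposed for
#' diagnostics and testing; \code{best_fold} uses it internally per spin.
#'
#' @param cost square cost matrix.
#' @return list with \code{row_of_col} (assigned row per column) and
#'   \code{cost}.
#' @export
solve_assignment <- function(cost) {
  .lap_cpp(as.matrix(cost))
}
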