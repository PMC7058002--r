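# Metropolis sampling of |Psi|^2 with node-crossing rejection.

#' Propose Gaussian walker steps
#'
#' Every coordinate of every walker is perturbed by an independent
#' Gaussian of variance \code{step_variance} (bohr^2).
#'
#' @param positions numeric matrix (walkers x 3N).
#' @param step_variance per-dimension step variance in bohr^2.
#' @return matrix of proposed positions.
#' @export
propose_step <- function(positions, step_variance = 0.2) {
  stopifnot(step_variance >= 0)
  positions + matrix(rnorm(length(positions), sd = sqrt(step_variance)),
                     nrow = nrow(positions))
}

#' Metropolis acceptance with node-crossing rejection
#'
#' A step is always rejected if the wavefunction changes sign
#' (node-crossing); otherwise it is accepted with probability
#' \code{min(1, psi_new^2 / psi_old^2)}.
#'
#' @param psi_old,psi_new signed wavefunction values (vectorised).
#' @param u uniform random numbers (drawn internally if omitted).
#' @return logical vector: accept each step?
#' @export
accept_step <- function(psi_old, psi_new, u = runif(length(psi_old))) {
  if (any(psi_old == 0)) stop("walker sits on a node (psi_old = 0)")
  same_sign <- sign(psi_new) == sign(psi_old) & psi_new != 0
  ratio <- (psi_new / psi_old)^2
  same_sign & (ratio >= 1 | u < ratio)
}

#' Initialise a walker ensemble
#'
#' All walkers start at the same configuration point (typically a local
#' maximum of |Psi|, see \code{\link{find_psi_maximum}}).
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param x0 numeric 3N start configuration.
#' @param n_walkers number of walkers.
#' @return list with \code{positions} (walkers x 3N), \code{psi},
#'   \code{tile_sign}.
#' @export
init_walkers <- function(wf, x0, n_walkers) {
  x0 <- as.numeric(x0)
  p0 <- psi_value(wf, x0)
  if (p0 == 0)
    stop("|Psi| = 0 at the initial point; walkers may not start on a node. ",
         "Choose a different start (e.g. a Lewis-like guess).")
  positions <- matrix(rep(x0, each = n_walkers), nrow = n_walkers)
  list(positions = positions, psi = rep(p0, n_walkers),
       tile_sign = rep(sign(p0), n_walkers))
}

#' Run a Metropolis walk
#'
#' Advances all walkers \code{n_steps} whole-configuration Gaussian steps
#' with Metropolis acceptance on \eqn{|\Psi|^2} and node-crossing
#' rejection.  Optional per-step hooks: classification of every walker
#' among reference sites (occupancy counting "on the fly") and fold-back
#' of walkers into the cell of one site, with parity bookkeeping and
#' centroid accumulation after a burn-in fraction.
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param walkers ensemble from \code{\link{init_walkers}} (or a bare
#'   positions matrix).
#' @param n_steps number of Metropolis steps.
#' @param step_variance Gaussian step variance per dimension (bohr^2),
#'   default 0.2.
#' @param sites optional list of \code{dvms_site} for classification.
#' @param fold_to optional index into \code{sites} (or a single
#'   \code{dvms_site}): accepted moves are folded back to this site's
#'   cell.
#' @param burn_frac fraction of initial steps excluded from the centroid
#'   accumulator.
#' @param scheme electron-update scheme per step: \code{"sweep"} tries
#'   every electron once (fast mixing, the default for site location);
#'   \code{"single"} tries one uniformly chosen electron (the
#'   literal one-trial-per-step reading used for occupancy kinetics,
#'   where step counts set the time unit).
#' @return An object of class \code{dvms_walk}: final \code{positions},
#'   \code{psi}, per-step \code{counts} (steps x sites), \code{centroid}
#'   of post-burn-in folded positions, \code{acceptance} rate, and fold /
#'   sign-rejection diagnostics.
#' @export
run_walk <- function(wf, walkers, n_steps, step_variance = 0.2,
                     sites = NULL, fold_to = NULL, burn_frac = 0,
                     scheme = c("sweep", "single")) {
  scheme <- match.arg(scheme)
  pos <- if (is.list(walkers)) walkers$positions else as.matrix(walkers)
  if (ncol(pos) != 3 * wf$n_electron) stop("walker dimension != 3N")
  if (n_steps == 0) {
    return(structure(list(positions = pos, psi = psi_value(wf, pos),
                          counts = NULL, centroid = colMeans(pos),
                          acceptance = NA_real_, n_steps = 0,
                          n_walkers = nrow(pos),
                          sites = sites, n_sign_reject = 0, n_fold = 0,
                          n_odd_fold = 0),
                     class = "dvms_walk"))
  }
  fold_idx <- 0L
  if (!is.null(fold_to)) {
    if (inherits(fold_to, "dvms_site")) {
      sites <- c(sites, list(fold_to))
      fold_idx <- length(sites)
    } else fold_idx <- as.integer(fold_to)
  }
  S <- if (length(sites))
    do.call(rbind, lapply(sites, function(s) s$x)) else
    matrix(0, 0, ncol(pos))
  res <- .run_walk_cpp(pos, .wf_data(wf), as.integer(n_steps),
                       sqrt(step_variance), S, fold_idx, burn_frac,
                       if (scheme == "single") 1L else 0L)
  out <- list(positions = res$positions, psi = as.numeric(res$psi),
              counts = res$counts, centroid = as.numeric(res$centroid),
              acceptance = res$acceptance, n_steps = n_steps,
              n_walkers = nrow(pos), sites = sites,
              n_sign_reject = res$n_sign_reject, n_fold = res$n_fold,
              n_odd_fold = res$n_odd_fold)
  if (!is.null(out$counts) && length(sites))
    colnames(out$counts) <- vapply(sites, function(s) s$label, "")
  class(out) <- "dvms_walk"
  out
}

#' @export
print.dvms_walk <- function(x, ...) {
  cat(sprintf("dvms walk: %d walkers x %d steps, acceptance %.3f\n",
              x$n_walkers, x$n_steps,
              if (is.na(x$acceptance)) NA else x$acceptance))
  if (!is.null(x$counts))
    cat("  classified among", ncol(x$counts), "sites; final counts:",
        paste(colnames(x$counts), utils::tail(x$counts, 1), sep = "="),
        "\n")
  if (x$n_odd_fold > 0)
    cat("  note:", x$n_odd_fold, "odd-parity folds (see diagnostics)\n")
  invisible(x)
}

#' Locate a local maximum of |Psi|
#'
#' Gradient ascent on log|Psi| with a numerical central-difference
#' gradient and adaptive step size, used to construct walker start
#' points.
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param x0 start configuration (|Psi(x0)| must be > 0).
#' @param tol convergence threshold on the step norm (bohr).
#' @param max_iter iteration cap.
#' @param h finite-difference displacement (bohr).
#' @return list with \code{x} (the maximiser), \code{psi}, \code{iter},
#'   \code{converged}.
#' @export
find_psi_maximum <- function(wf, x0, tol = 1e-6, max_iter = 300, h = 1e-4) {
  x0 <- as.numeric(x0)
  f0 <- psi_value(wf, x0)
  if (f0 == 0) stop("|Psi| = 0 at start point")
  sgn <- sign(f0)
  D <- length(x0)
  # maximise log|Psi| (sign-fixed) by BFGS with a central-difference
  # gradient evaluated in one batched call
  fn <- function(x) {
    v <- psi_value(wf, x) * sgn
    if (v <= 0) return(1e10)  # crossed a node: strongly penalised
    -log(v)
  }
  gr <- function(x) {
    X <- matrix(rep(x, each = 2 * D), nrow = 2 * D)
    idx <- rep(seq_len(D), each = 2)
    X[cbind(seq_len(2 * D), idx)] <-
      X[cbind(seq_len(2 * D), idx)] + rep(c(h, -h), D)
    fv <- psi_value(wf, X) * sgn
    fv[fv <= 0] <- 1e-300
    -(log(fv[seq(1, 2 * D, 2)]) - log(fv[seq(2, 2 * D, 2)])) / (2 * h)
  }
  opt <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol^2))
  list(x = opt$par, psi = psi_value(wf, opt$par), iter = opt$counts[1],
       converged = opt$convergence == 0)
}

#' Lewis-like benzene start configuration
#'
#' Places, per spin: one electron at each carbon (cores), one at each C-H
#' bond midpoint, and a Kekule arrangement over the C-C bonds --- double
#' bonds hold a banana pair displaced above/below the ring plane, single
#' bonds one in-plane midpoint electron.  Kekule structure "A" puts
#' double bonds on C1-C2, C3-C4, C5-C6; "B" on the alternate set.  Both
#' spins use the same structure (an eclipsed configuration).
#'
#' @param geom benzene \code{dvms_geometry} from \code{\link{build_benzene}}.
#' @param kekule \code{"A"} or \code{"B"}.
#' @param kekule_beta structure for the beta spin set (defaults to
#'   \code{kekule}: eclipsed).
#' @param banana_dz out-of-plane displacement of double-bond pairs (bohr).
#' @return numeric 3N vector (21 alpha triples then 21 beta).
#' @export
lewis_guess_benzene <- function(geom, kekule = "A", kekule_beta = kekule,
                                banana_dz = 0.6) {
  spin_block <- function(kek) {
    cc <- geom$xyz[1:6, ]
    hh <- geom$xyz[7:12, ]
    pts <- cc                                   # 6 cores
    pts <- rbind(pts, (cc + hh) / 2)            # 6 C-H electrons
    dbl <- if (kek == "A") c(1, 3, 5) else c(2, 4, 6)
    for (b in 1:6) {
      mid <- (cc[b, ] + cc[b %% 6 + 1, ]) / 2
      if (b %in% dbl) {
        pts <- rbind(pts, mid + c(0, 0, banana_dz),
                     mid - c(0, 0, banana_dz))
      } else {
        pts <- rbind(pts, mid)
      }
    }
    as.numeric(t(pts))
  }
  c(spin_block(kekule), spin_block(kekule_beta))
}
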