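# The "dynamic" part of DVMS: self-consistent tile-centroid iteration and
# the staged-truncation protocol.

#' Tile centroid from folded walker positions
#'
#' Metropolis walkers are |Psi|^2-distributed, so the plain mean of the
#' folded positions estimates the Psi^2-weighted centroid of the tile.
#'
#' @param folded_positions numeric matrix (walkers x 3N) of positions
#'   already folded into one tile.
#' @param n_alpha,n_beta electron counts (for the returned site).
#' @param label site label.
#' @param weights optional per-walker weights.
#' @return A \code{dvms_site} at the (weighted) mean position.
#' @export
update_site <- function(folded_positions, n_alpha, n_beta,
                        label = "centroid", weights = NULL) {
  P <- as.matrix(folded_positions)
  if (nrow(P) < 1) stop("at least one folded position is required")
  m <- if (is.null(weights)) colMeans(P) else
    as.numeric(crossprod(P, weights) / sum(weights))
  voronoi_site(m, n_alpha, n_beta, label)
}

#' Self-consistent DVMS iteration
#'
#' Alternates Metropolis sampling blocks (with fold-back into the current
#' site's cell) and centroid updates until the site stops moving:
#' convergence when the max-norm site displacement, averaged over
#' \code{settle} consecutive cycles, falls below \code{tol}.
#' Non-convergence at \code{max_cycles} is reported in the result, not
#' thrown.
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param x0 start configuration (3N vector); also the initial site.
#' @param n_walkers walkers in the ensemble (all start at \code{x0}).
#' @param block_steps Metropolis steps per cycle (default 2000).
#' @param step_variance Gaussian step variance (bohr^2).
#' @param tol convergence threshold on the cycle displacement (bohr).
#' @param settle number of consecutive cycles averaged for the test.
#' @param max_cycles cycle cap.
#' @param burn_frac fraction of each block excluded from the centroid.
#' @param verbose print per-cycle displacement.
#' @return An object of class \code{dvms_result}: final \code{site},
#'   \code{history} data frame (cycle, displacement, psi at site,
#'   acceptance, odd folds), \code{converged}, final \code{walkers}.
#' @export
run_dvms <- function(wf, x0, n_walkers = 100, block_steps = 2000,
                     step_variance = 0.2, tol = 0.05, settle = 3,
                     max_cycles = 40, burn_frac = 0.25, verbose = FALSE) {
  ens <- init_walkers(wf, x0, n_walkers)
  site <- voronoi_site(as.numeric(x0), wf$n_alpha, wf$n_beta, "dvms")
  hist <- data.frame()
  disp <- rep(NA_real_, 0)
  converged <- FALSE
  pos <- ens$positions
  for (cyc in seq_len(max_cycles)) {
    walk <- run_walk(wf, pos, block_steps, step_variance,
                     fold_to = site, burn_frac = burn_frac)
    pos <- walk$positions
    new_site <- voronoi_site(walk$centroid, wf$n_alpha, wf$n_beta, "dvms")
    d <- max(abs(new_site$x - site$x))
    disp <- c(disp, d)
    hist <- rbind(hist, data.frame(
      cycle = cyc, displacement = d,
      psi_site = psi_value(wf, new_site$x),
      acceptance = walk$acceptance, n_odd_fold = walk$n_odd_fold))
    site <- new_site
    if (verbose)
      message(sprintf("cycle %d: displacement %.4f bohr, acceptance %.3f",
                      cyc, d, walk$acceptance))
    if (length(disp) >= settle &&
        mean(utils::tail(disp, settle)) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(site = site, history = hist, converged = converged,
                 walkers = list(positions = pos, psi = walk$psi),
                 wf = wf),
            class = "dvms_result")
}

#' @export
print.dvms_result <- function(x, ...) {
  cat(sprintf("DVMS %s after %d cycle(s); final displacement %.4f bohr\n",
              if (x$converged) "converged" else "NOT converged",
              nrow(x$history), utils::tail(x$history$displacement, 1)))
  invisible(x)
}

#' Staged truncation protocol
#'
#' Recreates the staged analysis of the correlated wavefunction: the CI
#' expansion is enlarged stage by stage (adding configurations in
#' decreasing |c| order, degenerate groups intact); at each stage a
#' sampling block is run for each site lineage (walkers restarted at the
#' lineage's previous site), the site is re-centred, and the
#' wavefunction value at both lineage sites is recorded together with
#' the cumulative completeness.
#'
#' @param wf the full-CI \code{dvms_wavefunction}.
#' @param schedule strictly increasing configuration counts, one per
#'   stage.
#' @param lineages named list of start sites (conventionally
#'   \code{eclipsed} and \code{staggered} \code{dvms_site}s).
#' @param n_walkers,block_steps,step_variance,burn_frac sampling block
#'   parameters (see \code{\link{run_dvms}}).
#' @param verbose print per-stage values.
#' @return An object of class \code{dvms_staged}: \code{table} (stage,
#'   n_configs requested and kept, completeness, |Psi| at each lineage
#'   site), \code{sites} (final site per lineage per stage),
#'   \code{crossing_stage}: first stage at which the second lineage's
#'   |Psi| exceeds the first's.
#' @export
staged_truncation_run <- function(wf, schedule, lineages,
                                  n_walkers = 100, block_steps = 500,
                                  step_variance = 0.2, burn_frac = 0.25,
                                  verbose = FALSE) {
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  if (length(lineages) < 1) stop("at least one lineage site required")
  nm <- names(lineages)
  sites <- lineages
  tab <- data.frame()
  all_sites <- list()
  for (st in seq_along(schedule)) {
    wft <- truncate_ci(wf, schedule[st])
    kept <- length(wft$ci$coef)
    comp <- ci_completeness(wf, wft)
    row <- data.frame(stage = st, n_configs = schedule[st],
                      n_kept = kept, completeness = comp)
    for (ln in nm) {
      p0 <- psi_value(wft, sites[[ln]]$x)
      if (p0 == 0) {
        warning("stage ", st, ": |Psi| = 0 at the previous '", ln,
                "' site; stage skipped for this lineage")
        row[[paste0("psi_", ln)]] <- NA_real_
        next
      }
      if (block_steps > 0) {
        ens <- init_walkers(wft, sites[[ln]]$x, n_walkers)
        walk <- run_walk(wft, ens$positions, block_steps, step_variance,
                         fold_to = sites[[ln]], burn_frac = burn_frac)
        sites[[ln]] <- voronoi_site(walk$centroid, wf$n_alpha, wf$n_beta,
                                    sites[[ln]]$label)
      }
      row[[paste0("psi_", ln)]] <- abs(psi_value(wft, sites[[ln]]$x))
    }
    tab <- rbind(tab, row)
    all_sites[[st]] <- sites
    if (verbose) message(sprintf(
      "stage %d (%d configs, %.4f complete): %s", st, kept, comp,
      paste(sprintf("|Psi_%s| = %.3e", nm,
                    unlist(row[paste0("psi_", nm)])), collapse = ", ")))
  }
  # persistent crossing: the first stage from which the second lineage's
  # |Psi| stays above the first's.  (At low truncation the two sites can
  # be symmetry-equivalent, so single-stage comparisons are noise.)
  crossing <- NA_integer_
  if (length(nm) >= 2) {
    a <- tab[[paste0("psi_", nm[1])]]
    b <- tab[[paste0("psi_", nm[2])]]
    below <- which(!(b > a))
    cand <- if (length(below)) max(below) + 1L else 1L
    if (cand <= length(a)) crossing <- cand
  }
  structure(list(table = tab, sites = all_sites,
                 crossing_stage = crossing, lineages = nm),
            class = "dvms_staged")
}

#' @export
print.dvms_staged <- function(x, ...) {
  cat("DVMS staged truncation run:\n")
  print(x$table, row.names = FALSE)
  if (!is.na(x$crossing_stage))
    cat(sprintf("'%s' overtakes '%s' at stage %d (%d configurations)\n",
                x$lineages[2], x$lineages[1], x$crossing_stage,
                x$table$n_kept[x$crossing_stage]))
  invisible(x)
}
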