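# Kekule reference sites, walker classification traces, equilibrium
# occupancies with decorrelation-corrected errors, and the two-state
# kinetic fit.

#' Partition a benzene site's electrons into core / C-H / C-C sets
#'
#' Classifies each electron of one spin block by its nearest anchor:
#' carbon nucleus (core), C-H bond midpoint, or C-C bond midpoint.
#'
#' @param block numeric matrix (n x 3) of one spin's electron positions.
#' @param geom benzene \code{dvms_geometry}.
#' @param tol ambiguity tolerance (bohr): an electron whose two nearest
#'   anchors are closer than this triggers an error.
#' @return list of index vectors \code{core}, \code{ch}, \code{cc}.
#' @export
classify_benzene_electrons <- function(block, geom, tol = 1e-6) {
  cc <- geom$xyz[1:6, , drop = FALSE]
  hh <- geom$xyz[7:12, , drop = FALSE]
  mid_ch <- (cc + hh) / 2
  mid_cc <- (cc + cc[c(2:6, 1), ]) / 2
  anchors <- rbind(cc, mid_ch, mid_cc)
  type <- rep(c("core", "ch", "cc"), each = 6)
  out <- list(core = integer(), ch = integer(), cc = integer())
  for (i in seq_len(nrow(block))) {
    d <- sqrt(colSums((t(anchors) - block[i, ])^2))
    o <- order(d)
    if (abs(d[o[1]] - d[o[2]]) < tol &&
        type[o[1]] != type[o[2]])
      stop("ambiguous electron assignment: electron ", i,
           " is equidistant from anchors of different types")
    out[[type[o[1]]]] <- c(out[[type[o[1]]]], i)
  }
  out
}

#' Build the four Kekule reference sites
#'
#' From a converged (eclipsed) benzene site, constructs the four
#' reference Voronoi sites related by 60-degree rotations (about the C6
#' axis, z) of the C-C bonding electron set of either or both spins:
#' base (eclipsed-A), alpha rotated (staggered-A), beta rotated
#' (staggered-B), both rotated (eclipsed-B).  Core and C-H electrons are
#' left untouched.
#'
#' @param site the base \code{dvms_site} (eclipsed, both spins in the
#'   same Kekule structure).
#' @param geom benzene \code{dvms_geometry}.
#' @return list of 4 \code{dvms_site}s labelled \code{eclipsed-A},
#'   \code{staggered-A}, \code{staggered-B}, \code{eclipsed-B}.
#' @export
build_reference_sites <- function(site, geom) {
  na <- site$n_alpha
  nb <- site$n_beta
  rot60 <- function(p) {
    th <- pi / 3
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    p %*% t(R)
  }
  blocks <- list(alpha = matrix(site$x[1:(3 * na)], ncol = 3, byrow = TRUE),
                 beta = matrix(site$x[-(1:(3 * na))], ncol = 3,
                               byrow = TRUE))
  cc_idx <- lapply(blocks, function(b) {
    idx <- classify_benzene_electrons(b, geom)
    if (length(idx$core) != 6 || length(idx$ch) != 6)
      stop("could not identify 6 core and 6 C-H electrons per spin ",
           "(got ", length(idx$core), " and ", length(idx$ch), "); ",
           "is this a converged benzene Kekule site?")
    idx$cc
  })
  make <- function(rot_a, rot_b, label) {
    b <- blocks
    if (rot_a) b$alpha[cc_idx$alpha, ] <- rot60(b$alpha[cc_idx$alpha, ])
    if (rot_b) b$beta[cc_idx$beta, ] <- rot60(b$beta[cc_idx$beta, ])
    voronoi_site(c(t(b$alpha), t(b$beta)), na, nb, label)
  }
  list(make(FALSE, FALSE, "eclipsed-A"),
       make(TRUE, FALSE, "staggered-A"),
       make(FALSE, TRUE, "staggered-B"),
       make(TRUE, TRUE, "eclipsed-B"))
}

#' Per-spin C-C bond-region electron counts
#'
#' Counts, for each of the six C-C bonds, the electrons of one spin
#' block whose nearest C-C bond midpoint is that bond (core and C-H
#' electrons excluded first).  A converged Kekule site shows the
#' alternating 2-1-2-1-2-1 pattern.
#'
#' @param site a benzene \code{dvms_site}.
#' @param geom benzene \code{dvms_geometry}.
#' @param spin \code{"alpha"} or \code{"beta"}.
#' @return integer vector of length 6 (bonds C1-C2, C2-C3, ..., C6-C1).
#' @export
bond_electron_counts <- function(site, geom, spin = "alpha") {
  na <- site$n_alpha
  block <- if (spin == "alpha")
    matrix(site$x[1:(3 * na)], ncol = 3, byrow = TRUE) else
    matrix(site$x[-(1:(3 * na))], ncol = 3, byrow = TRUE)
  idx <- classify_benzene_electrons(block, geom)
  cc <- geom$xyz[1:6, , drop = FALSE]
  mid_cc <- (cc + cc[c(2:6, 1), ]) / 2
  counts <- integer(6)
  for (i in idx$cc) {
    d <- sqrt(colSums((t(mid_cc) - block[i, ])^2))
    counts[which.min(d)] <- counts[which.min(d)] + 1L
  }
  counts
}

#' Occupancy trace from an on-the-fly classified walk
#'
#' Runs a Metropolis walk with per-step nearest-site classification of
#' every walker and aggregates the four Kekule sites into the two-class
#' eclipsed/staggered trace.
#'
#' @param wf a \code{dvms_wavefunction} (typically a truncated expansion).
#' @param sites list of reference sites from
#'   \code{\link{build_reference_sites}}.
#' @param x0 start configuration; conventionally the eclipsed-A site, so
#'   the ensemble starts all-eclipsed.
#' @param n_walkers,n_steps,step_variance sampling parameters.
#' @param scheme electron-update scheme (see \code{\link{run_walk}});
#'   the default sweep counting equilibrates the ensemble well inside
#'   the conventional 500-step discard window, which the slower
#'   one-trial-per-step counting does not.
#' @return An object of class \code{dvms_trace}: \code{counts} (steps x
#'   sites), \code{eclipsed}, \code{staggered} per-step class counts,
#'   \code{n_walkers}, \code{acceptance}, and metadata.
#' @export
classify_trace <- function(wf, sites, x0, n_walkers = 500, n_steps = 2000,
                           step_variance = 0.2, scheme = "sweep") {
  ens <- init_walkers(wf, x0, n_walkers)
  walk <- run_walk(wf, ens$positions, n_steps, step_variance,
                   sites = sites, scheme = scheme)
  lab <- colnames(walk$counts)
  ecl <- grepl("^eclipsed", lab)
  trace <- list(counts = walk$counts,
                eclipsed = rowSums(walk$counts[, ecl, drop = FALSE]),
                staggered = rowSums(walk$counts[, !ecl, drop = FALSE]),
                n_walkers = n_walkers, n_steps = n_steps,
                n_configs = length(wf$ci$coef),
                acceptance = walk$acceptance,
                n_sign_reject = walk$n_sign_reject)
  class(trace) <- "dvms_trace"
  trace
}

#' @export
print.dvms_trace <- function(x, ...) {
  cat(sprintf("dvms occupancy trace: %d walkers x %d steps (%d-config wavefunction)\n",
              x$n_walkers, x$n_steps, x$n_configs))
  cat(sprintf("  final step: eclipsed %d, staggered %d; acceptance %.3f\n",
              utils::tail(x$eclipsed, 1), utils::tail(x$staggered, 1),
              x$acceptance))
  invisible(x)
}

#' Synthetic two-state Markov occupancy trace
#'
#' Independent walkers hop between the eclipsed and staggered classes
#' with a fixed per-step crossing probability; used to calibrate the
#' equilibrium and kinetics estimators against analytic moments.
#'
#' @param n_walkers walkers.
#' @param n_steps steps.
#' @param rate per-step crossing probability (per direction).
#' @param p0 initial probability of the staggered class.
#' @return A \code{dvms_trace} with known dynamics: the staggered
#'   fraction relaxes to 1/2 with rate \code{2 * rate} per step.
#' @export
synthetic_markov_trace <- function(n_walkers = 500, n_steps = 2000,
                                   rate = 0.005, p0 = 0) {
  state <- stats::rbinom(n_walkers, 1, p0)
  stag <- integer(n_steps)
  for (k in seq_len(n_steps)) {
    flip <- stats::runif(n_walkers) < rate
    state <- ifelse(flip, 1L - state, state)
    stag[k] <- sum(state)
  }
  counts <- cbind(`eclipsed-A` = n_walkers - stag, `staggered-A` = stag,
                  `staggered-B` = 0L, `eclipsed-B` = 0L)
  structure(list(counts = counts, eclipsed = n_walkers - stag,
                 staggered = stag, n_walkers = n_walkers,
                 n_steps = n_steps, n_configs = NA_integer_,
                 acceptance = NA_real_, n_sign_reject = 0),
            class = "dvms_trace")
}

#' Equilibrium occupancy with decorrelation-corrected errors
#'
#' Class means over a post-equilibration window.  Walker positions
#' decorrelate over roughly \code{decorrelation} steps, so the standard
#' error of the mean divides the per-step standard deviation by
#' \code{sqrt(n_window / decorrelation)} rather than \code{sqrt(n_window)}.
#'
#' @param trace a \code{dvms_trace}.
#' @param window integer vector \code{c(first, last)} step of the
#'   averaging window (default 501 to the end).
#' @param decorrelation decorrelation length in steps (default 200).
#' @return data frame with one row per class: mean count, standard
#'   error, and the 2-sigma interval.
#' @export
equilibrium_occupancy <- function(trace, window = c(501, trace$n_steps),
                                  decorrelation = 200) {
  ks <- seq(window[1], window[2])
  if (length(ks) < decorrelation)
    stop("averaging window shorter than the decorrelation length")
  n_eff <- length(ks) / decorrelation
  out <- do.call(rbind, lapply(c("eclipsed", "staggered"), function(cl) {
    v <- trace[[cl]][ks]
    se <- stats::sd(v) / sqrt(n_eff)
    data.frame(class = cl, mean = mean(v), se = se,
               lo2 = mean(v) - 2 * se, hi2 = mean(v) + 2 * se)
  }))
  attr(out, "window") <- window
  attr(out, "decorrelation") <- decorrelation
  out
}

#' Two-state kinetic fit of an occupancy trace
#'
#' Fits the exponential relaxation
#' \deqn{N_{stag}(k) = N_{eq} + (N_0 - N_{eq}) e^{-k_{relax} k}}
#' to the staggered-count trace by nonlinear least squares.  Under a
#' symmetric two-state exchange with per-direction crossing rate
#' \eqn{k_x}, the relaxation rate is \eqn{k_{relax} = 2 k_x}; the
#' decorrelation length is \eqn{1/k_x}.
#'
#' Traces started from a single structure show a nucleation lag before
#' the first crossings (the count stays at \eqn{N_0} while walkers
#' diffuse towards the cell boundary), which a pure exponential cannot
#' represent; the fit therefore starts at the first step where the
#' trace has covered \code{lag_frac} of its distance to the plateau.
#' For a lag-free exponential trace this discards almost nothing.
#'
#' @param trace a \code{dvms_trace} starting away from equilibrium
#'   (conventionally all-eclipsed).
#' @param k_init initial guess for the relaxation rate (per step).
#' @param lag_frac plateau-distance fraction defining the fit start.
#' @return An object of class \code{dvms_kinetics}: \code{rate_relax},
#'   \code{rate_crossing} (= rate_relax / 2), \code{n_eq}, \code{n0},
#'   \code{fit_start}, \code{decorrelation_length} (= 1/k_x),
#'   \code{residual_sd}, \code{identifiable}.
#' @export
fit_kinetics <- function(trace, k_init = 0.01, lag_frac = 0.2) {
  y <- trace$staggered
  n_eq0 <- mean(utils::tail(y, max(100, trace$n_steps %/% 4)))
  n00 <- y[1]
  if (abs(n00 - n_eq0) < 3 * stats::sd(utils::tail(y, 200))) {
    return(structure(list(rate_relax = NA_real_, rate_crossing = NA_real_,
                          n_eq = n_eq0, n0 = n00, fit_start = NA_integer_,
                          decorrelation_length = NA_real_,
                          residual_sd = NA_real_, identifiable = FALSE),
                     class = "dvms_kinetics"))
  }
  covered <- abs(y - n00) >= lag_frac * abs(n_eq0 - n00)
  k0 <- if (any(covered)) which(covered)[1] else 1L
  ks <- seq(k0, trace$n_steps)
  fit <- minpack.lm::nlsLM(
    y ~ neq + (n0 - neq) * exp(-kr * (k - k0)),
    start = list(neq = n_eq0, n0 = y[k0], kr = k_init),
    lower = c(0, 0, 1e-6), upper = c(trace$n_walkers, trace$n_walkers, 1),
    data = data.frame(k = ks, y = y[ks]))
  co <- stats::coef(fit)
  structure(list(rate_relax = unname(co["kr"]),
                 rate_crossing = unname(co["kr"]) / 2,
                 n_eq = unname(co["neq"]), n0 = unname(co["n0"]),
                 fit_start = k0,
                 decorrelation_length = 2 / unname(co["kr"]),
                 residual_sd = stats::sd(stats::resid(fit)),
                 identifiable = TRUE),
            class = "dvms_kinetics")
}

#' @export
print.dvms_kinetics <- function(x, ...) {
  if (!x$identifiable) {
    cat("two-state kinetic fit: unidentifiable (trace starts at equilibrium)\n")
  } else {
    cat(sprintf(
      "two-state kinetic fit: crossing rate %.4f / step (relaxation %.4f), N_eq = %.1f, decorrelation ~ %.0f steps\n",
      x$rate_crossing, x$rate_relax, x$n_eq, x$decorrelation_length))
  }
  invisible(x)
}

#' Block stationarity check
#'
#' Compares staggered-class means between non-overlapping blocks with
#' decorrelation-corrected two-sample z-tests at the 0.05 level.
#'
#' @param trace a \code{dvms_trace}.
#' @param blocks list of \code{c(first, last)} step ranges (each at
#'   least \code{decorrelation} steps long).
#' @param decorrelation decorrelation length in steps.
#' @return data frame with one row per block pair: z statistic, p-value,
#'   pass (|z| below the 5 percent critical value).
#' @export
block_stationarity <- function(trace,
                               blocks = list(c(501, 1000), c(1001, 1500),
                                             c(1501, 2000)),
                               decorrelation = 200) {
  nb <- length(blocks)
  if (nb < 2) stop("at least two blocks are required")
  for (i in seq_len(nb)) {
    b <- blocks[[i]]
    if (diff(b) + 1 < decorrelation)
      stop("block ", i, " shorter than the decorrelation length")
    for (j in seq_len(i - 1))
      if (b[1] <= blocks[[j]][2] && blocks[[j]][1] <= b[2])
        stop("blocks ", j, " and ", i, " overlap")
  }
  stat <- lapply(blocks, function(b) {
    v <- trace$staggered[seq(b[1], b[2])]
    n_eff <- length(v) / decorrelation
    c(mean = mean(v), se = stats::sd(v) / sqrt(n_eff))
  })
  out <- data.frame()
  for (i in seq_len(nb - 1)) for (j in seq(i + 1, nb)) {
    z <- (stat[[i]]["mean"] - stat[[j]]["mean"]) /
      sqrt(stat[[i]]["se"]^2 + stat[[j]]["se"]^2)
    out <- rbind(out, data.frame(
      block_a = i, block_b = j, z = unname(z),
      p = 2 * stats::pnorm(-abs(unname(z))),
      pass = abs(unname(z)) < stats::qnorm(0.975)))
  }
  out
}
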