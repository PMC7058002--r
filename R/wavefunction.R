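# CI expansions over molecular orbitals and configuration-space evaluation
# of the many-electron wavefunction Psi(x) = sum_i c_i det_a(i) det_b(i).

#' CI expansion
#'
#' A (possibly truncated) configuration-interaction expansion
#' \eqn{\Psi = \sum_i c_i \psi_i} over spin-factored determinants.  Each
#' determinant is given by the ascending list of occupied orbital (column)
#' indices for each spin.  Terms are kept sorted by decreasing
#' \eqn{|c_i|}, ties broken by the determinant occupation strings.
#'
#' @param occ_alpha integer matrix (terms x n_alpha) of occupied orbital
#'   indices (1-based, ascending within a row).
#' @param occ_beta integer matrix (terms x n_beta).
#' @param coef numeric coefficient vector.
#' @return An object of class \code{dvms_ci}.
#' @export
ci_expansion <- function(occ_alpha, occ_beta, coef) {
  occ_alpha <- matrix(as.integer(occ_alpha), nrow = length(coef))
  occ_beta <- matrix(as.integer(occ_beta), nrow = length(coef))
  stopifnot(nrow(occ_alpha) == length(coef), nrow(occ_beta) == length(coef),
            all(is.finite(coef)))
  for (r in seq_len(nrow(occ_alpha))) {
    if (is.unsorted(occ_alpha[r, ], strictly = TRUE) ||
        (ncol(occ_beta) > 0 && is.unsorted(occ_beta[r, ], strictly = TRUE)))
      stop("occupied orbital indices must be strictly ascending per term")
  }
  key <- paste(apply(occ_alpha, 1, paste, collapse = ","),
               apply(occ_beta, 1, paste, collapse = ","))
  if (anyDuplicated(key)) stop("duplicate determinants in CI expansion")
  ord <- order(-abs(coef), key)
  structure(list(occ_alpha = occ_alpha[ord, , drop = FALSE],
                 occ_beta = occ_beta[ord, , drop = FALSE],
                 coef = coef[ord],
                 n_alpha = ncol(occ_alpha), n_beta = ncol(occ_beta)),
            class = "dvms_ci")
}

#' @export
print.dvms_ci <- function(x, ...) {
  cat(sprintf("dvms CI expansion: %d term(s), %d alpha + %d beta electrons, sum c^2 = %.6f\n",
              length(x$coef), x$n_alpha, x$n_beta, sum(x$coef^2)))
  invisible(x)
}

#' Single-determinant expansion over the lowest orbitals
#'
#' @param n_alpha,n_beta electron counts per spin.
#' @param occ_alpha,occ_beta optional explicit occupation index vectors
#'   (default: lowest \code{n} orbitals).
#' @return A one-term \code{dvms_ci}.
#' @export
single_determinant <- function(n_alpha, n_beta,
                               occ_alpha = seq_len(n_alpha),
                               occ_beta = seq_len(n_beta)) {
  ci_expansion(matrix(occ_alpha, 1), matrix(occ_beta, 1), 1.0)
}

#' Electronic wavefunction handle
#'
#' Bundles geometry, AO basis, molecular orbitals and a CI expansion into
#' the single object all sampling and analysis functions consume.
#'
#' @param basis a \code{dvms_basis}.
#' @param mo list with at least \code{C}, the AO x MO coefficient matrix.
#' @param ci a \code{dvms_ci}; orbital indices refer to columns of
#'   \code{mo$C}.
#' @param geometry optional \code{dvms_geometry} (toys may omit it).
#' @return An object of class \code{dvms_wavefunction}.
#' @export
wavefunction <- function(basis, mo, ci, geometry = NULL) {
  stopifnot(inherits(basis, "dvms_basis"), inherits(ci, "dvms_ci"))
  if (nrow(mo$C) != basis$nao)
    stop("MO coefficient rows (", nrow(mo$C), ") != AO count (", basis$nao,
         ")")
  if (!all(is.finite(mo$C))) stop("non-finite MO coefficients")
  mx <- max(c(ci$occ_alpha, ci$occ_beta, 0L))
  if (mx > ncol(mo$C))
    stop("CI expansion references orbital ", mx, " but only ",
         ncol(mo$C), " MOs are present")
  structure(list(geometry = geometry, basis = basis, mo = mo, ci = ci,
                 n_alpha = ci$n_alpha, n_beta = ci$n_beta,
                 n_electron = ci$n_alpha + ci$n_beta),
            class = "dvms_wavefunction")
}

#' @export
print.dvms_wavefunction <- function(x, ...) {
  cat(sprintf("dvms wavefunction: %d electrons (%d alpha, %d beta), %d AO, %d MO, %d CI term(s)\n",
              x$n_electron, x$n_alpha, x$n_beta, x$basis$nao,
              ncol(x$mo$C), length(x$ci$coef)))
  invisible(x)
}

# flat list handed to the C++ kernels
.wf_data <- function(wf) {
  list(lmn = wf$basis$lmn, cen = wf$basis$cen,
       nprim = as.integer(wf$basis$nprim),
       exps = wf$basis$exps, coefs = wf$basis$coefs, C = wf$mo$C,
       occA = wf$ci$occ_alpha - 1L, occB = wf$ci$occ_beta - 1L,
       coef = wf$ci$coef)
}

#' Evaluate all molecular orbitals at points
#'
#' @param wf a \code{dvms_wavefunction} (or list with \code{basis},
#'   \code{mo}).
#' @param points numeric matrix (n x 3) or length-3 vector, bohr.
#' @return matrix (n x n_mo) of MO values.
#' @export
eval_orbitals <- function(wf, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  stopifnot(all(is.finite(points)))
  ao <- .ao_values_cpp(.wf_data(wf), as.matrix(points))
  ao %*% wf$mo$C
}

#' Slater-determinant value
#'
#' Value of the determinant of the orbital-by-electron matrix; the
#' antisymmetrised amplitude of one spin block.
#'
#' @param M square numeric matrix, entry (i, j) = orbital j at electron i.
#' @return signed determinant value.
#' @export
slater_value <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("orbital-by-electron matrix must be square")
  if (!all(is.finite(M))) stop("non-finite matrix")
  det(M)
}

#' Wavefunction value at configuration points
#'
#' \eqn{\Psi(x) = \sum_i c_i \det A_i(x) \det B_i(x)} where the rows of
#' \eqn{A_i} are the alpha electrons and its columns the occupied alpha
#' orbitals of configuration i (likewise \eqn{B_i} for beta).  The
#' configuration vector lists alpha electron coordinate triples first.
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param x numeric 3N vector, or matrix (m x 3N) for batch evaluation.
#' @return numeric vector of signed wavefunction values.
#' @export
psi_value <- function(wf, x) {
  X <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(X) != 3 * wf$n_electron)
    stop("configuration length ", ncol(X), " != 3N = ", 3 * wf$n_electron)
  if (!all(is.finite(X))) stop("non-finite configuration")
  as.numeric(.psi_batch_cpp(.wf_data(wf), X))
}

#' Truncate a CI expansion by coefficient magnitude
#'
#' Keeps the leading \code{n_configs} terms by decreasing \eqn{|c_i|}.  If
#' the cut would split a group of terms whose \eqn{|c_i|} agree within
#' \code{degeneracy_tol}, the whole tied group is retained (the result may
#' then hold more than \code{n_configs} terms).  Coefficients are not
#' renormalised: Metropolis sampling of \eqn{|\Psi|^2} is invariant under
#' overall scaling.
#'
#' @param ci a \code{dvms_ci} (or \code{dvms_wavefunction}).
#' @param n_configs number of configurations to keep (>= 1).
#' @param degeneracy_tol absolute tolerance within which coefficient
#'   magnitudes count as degenerate.
#' @return truncated object of the same class as the input.
#' @export
truncate_ci <- function(ci, n_configs, degeneracy_tol = 1e-6) {
  if (inherits(ci, "dvms_wavefunction")) {
    out <- ci
    out$ci <- truncate_ci(ci$ci, n_configs, degeneracy_tol)
    return(out)
  }
  n <- length(ci$coef)
  if (n_configs < 1) stop("n_configs must be >= 1")
  if (n_configs >= n) return(ci)
  k <- n_configs
  while (k < n && abs(abs(ci$coef[k]) - abs(ci$coef[k + 1])) <= degeneracy_tol)
    k <- k + 1
  ci_expansion(ci$occ_alpha[1:k, , drop = FALSE],
               ci$occ_beta[1:k, , drop = FALSE], ci$coef[1:k])
}

#' Degenerate-group truncation sizes
#'
#' Cumulative configuration counts after adding each degenerate coefficient
#' group in decreasing-|c| order; the natural truncation schedule.
#'
#' @inheritParams truncate_ci
#' @return integer vector of cumulative term counts (one per group).
#' @export
ci_group_sizes <- function(ci, degeneracy_tol = 1e-6) {
  if (inherits(ci, "dvms_wavefunction")) ci <- ci$ci
  a <- abs(ci$coef)
  breaks <- which(abs(diff(a)) > degeneracy_tol)
  c(breaks, length(a))
}

#' Cumulative completeness of a truncated CI expansion
#'
#' The summed squared coefficients of the retained terms, as a fraction of
#' the full (normalised) expansion's summed squared coefficients.
#' Monotone non-decreasing in the truncation length and exactly 1 for the
#' full expansion.
#'
#' @param ci_full the full expansion (\code{dvms_ci} or
#'   \code{dvms_wavefunction}).
#' @param ci_truncated a truncation of it.
#' @return fraction in [0, 1].
#' @export
ci_completeness <- function(ci_full, ci_truncated) {
  if (inherits(ci_full, "dvms_wavefunction")) ci_full <- ci_full$ci
  if (inherits(ci_truncated, "dvms_wavefunction"))
    ci_truncated <- ci_truncated$ci
  keyf <- paste(apply(ci_full$occ_alpha, 1, paste, collapse = ","),
                apply(ci_full$occ_beta, 1, paste, collapse = ","))
  keyt <- paste(apply(ci_truncated$occ_alpha, 1, paste, collapse = ","),
                apply(ci_truncated$occ_beta, 1, paste, collapse = ","))
  if (!all(keyt %in% keyf))
    stop("truncated expansion contains terms absent from the full expansion")
  sum(ci_full$coef[keyf %in% keyt]^2) / sum(ci_full$coef^2)
}
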