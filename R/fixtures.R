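# Committed benzene fixtures: loaders, integrity checks, and the
# regeneration backend adapter.

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "dvms")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Verify fixture integrity
#'
#' Compares md5 checksums of the committed benzene fixture files against
#' the manifest.
#'
#' @return invisibly, a data frame of files and checksum status; errors
#'   if any checksum disagrees.
#' @export
verify_fixtures <- function() {
  man <- readLines(.extdata("MANIFEST"))
  man <- man[!grepl("^#", man) & nzchar(man)]
  parts <- strsplit(trimws(man), "\\s+")
  want <- vapply(parts, `[[`, "", 1L)
  files <- vapply(parts, `[[`, "", 2L)
  have <- unname(tools::md5sum(vapply(files, .extdata, "")))
  ok <- want == have
  if (!all(ok))
    stop("fixture checksum mismatch: ", paste(files[!ok], collapse = ", "))
  invisible(data.frame(file = files, md5 = have, ok = ok))
}

#' Load a benzene wavefunction from the committed fixtures
#'
#' Reads the RHF/6-31G(d) Molden fixture and, for correlated choices,
#' the corresponding CAS-CI vector file; absolute orbital indices in the
#' CI file are remapped onto the stored MO columns.
#'
#' @param which \code{"single"} (the RHF determinant), \code{"cas66"}
#'   (all-pi (6,6) CAS-CI) or \code{"cas3018"} (valence (30,18) CAS-CI,
#'   leading terms).
#' @param n_configs optional truncation length (degenerate groups kept
#'   whole, see \code{\link{truncate_ci}}).
#' @return A \code{dvms_wavefunction}; attribute \code{"civec"} carries
#'   the CI file metadata for the correlated choices.
#' @export
load_benzene <- function(which = c("single", "cas66", "cas3018"),
                         n_configs = NULL) {
  which <- match.arg(which)
  mol <- read_molden(.extdata("benzene_rhf_631gd.molden"))
  nocc <- sum(mol$mo$occupation > 0)
  if (which == "single") {
    occ_cols <- seq_along(mol$mo$occupation)[mol$mo$occupation > 0]
    ci <- single_determinant(nocc, nocc, occ_cols, occ_cols)
    wf <- wavefunction(mol$basis, mol$mo, ci, mol$geometry)
    return(wf)
  }
  cv <- read_civec(.extdata(sprintf("benzene_%s.civec", which)))
  remap <- function(m) {
    cols <- match(m, mol$mo$orig_index)
    if (anyNA(cols))
      stop("CI vector references orbitals absent from the MO fixture")
    matrix(cols, nrow = nrow(m))
  }
  ci <- ci_expansion(remap(cv$ci$occ_alpha), remap(cv$ci$occ_beta),
                     cv$ci$coef)
  if (!is.null(n_configs)) ci <- truncate_ci(ci, n_configs)
  wf <- wavefunction(mol$basis, mol$mo, ci, mol$geometry)
  attr(wf, "civec") <- cv[c("active", "frozen", "norb", "norm_total",
                            "norm_listed")]
  wf
}

#' Identify pi molecular orbitals
#'
#' For a planar molecule in the xy-plane, flags MOs that are
#' antisymmetric under reflection in the plane: their coefficient weight
#' on z-even AOs is below \code{tol}.
#'
#' @param basis a \code{dvms_basis}.
#' @param C AO x MO coefficient matrix.
#' @param tol in-plane weight threshold.
#' @return logical vector over MOs.
#' @export
pi_orbitals <- function(basis, C, tol = 1e-6) {
  z_even <- basis$lmn[, 3] %% 2 == 0
  w_in <- colSums(C[z_even, , drop = FALSE]^2)
  w_all <- colSums(C^2)
  w_in / w_all < tol
}

#' Regenerate the benzene fixtures with the bundled engine
#'
#' Runs the packaged Python RHF/CAS-CI engine (requires \code{python}
#' with numpy, scipy and numba on the PATH) to recompute the Molden and
#' CI fixture files from scratch.  The committed fixtures make this
#' optional; tests never require it.
#'
#' @param python python interpreter to use.
#' @return exit status of the engine, invisibly; a message and NULL if
#'   the engine environment is unavailable.
#' @export
request_wavefunction <- function(python = "python") {
  ok <- tryCatch({
    system2(python, c("-c", shQuote("import numpy, scipy, numba")),
            stdout = FALSE, stderr = FALSE) == 0
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    message("python with numpy/scipy/numba not available; ",
            "using the committed fixtures")
    return(invisible(NULL))
  }
  script <- system.file("engine", "make_fixtures.py", package = "dvms")
  invisible(system2(python, shQuote(script)))
}
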