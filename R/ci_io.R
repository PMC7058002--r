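# Plain-text CI vector files (format "civec-1").
#
# Header keys (one per line): format, norb, nalpha, nbeta, active (1-based
# MO indices of the active orbitals, ascending), frozen (doubly occupied
# MO indices), norm_total, norm_listed, nterm.  Then one determinant per
# line: alpha occupation string over the active list, beta occupation
# string, coefficient.  Coefficients refer to spin-factored determinants
# whose occupied orbitals (frozen + active occupied) are listed in
# ascending order.

#' Read a CI vector file
#'
#' @param path file path (see the package vignette for the format).
#' @return A list: \code{ci} (a \code{dvms_ci} with absolute orbital
#'   indices), \code{active}, \code{frozen}, \code{norb}, \code{nalpha},
#'   \code{nbeta}, \code{norm_total}, \code{norm_listed}.
#' @export
read_civec <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  kv <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), ln, value = TRUE)[1]
    if (is.na(hit)) stop("CI vector file missing header key: ", key)
    strsplit(trimws(sub(paste0("^", key), "", hit)), "\\s+")[[1]]
  }
  norb <- as.integer(kv("norb"))
  na <- as.integer(kv("nalpha")); nb <- as.integer(kv("nbeta"))
  active <- as.integer(kv("active"))
  frozen <- as.integer(kv("frozen"))
  nterm <- as.integer(kv("nterm"))
  norm_total <- as.numeric(kv("norm_total"))
  norm_listed <- as.numeric(kv("norm_listed"))
  rows <- grep("^[01]+\\s+[01]+\\s", ln, value = TRUE)
  if (length(rows) != nterm)
    stop("CI vector file: nterm = ", nterm, " but ", length(rows),
         " determinant lines found")
  parts <- strsplit(trimws(rows), "\\s+")
  stra <- vapply(parts, `[[`, "", 1L)
  strb <- vapply(parts, `[[`, "", 2L)
  coef <- as.numeric(vapply(parts, `[[`, "", 3L))
  occ_of <- function(s) {
    stopifnot(nchar(s) == length(active))
    sort(c(frozen, active[strsplit(s, "")[[1]] == "1"]))
  }
  occ_a <- t(vapply(stra, occ_of, integer(na), USE.NAMES = FALSE))
  occ_b <- t(vapply(strb, occ_of, integer(nb), USE.NAMES = FALSE))
  list(ci = ci_expansion(occ_a, occ_b, coef), active = active,
       frozen = frozen, norb = norb, nalpha = na, nbeta = nb,
       norm_total = norm_total, norm_listed = norm_listed)
}

#' Write a CI vector file
#'
#' @param ci a \code{dvms_ci} with absolute orbital indices.
#' @param path output path.
#' @param active,frozen active and frozen (doubly occupied) orbital index
#'   vectors; every determinant must occupy all of \code{frozen} plus a
#'   subset of \code{active}.
#' @param norb total MO count recorded in the header.
#' @param norm_total total squared norm of the (possibly longer) source
#'   vector; defaults to the listed norm.
#' @param comment optional comment line.
#' @return \code{path}, invisibly.
#' @export
write_civec <- function(ci, path, active, frozen, norb,
                        norm_total = NULL, comment = "") {
  if (inherits(ci, "dvms_wavefunction")) ci <- ci$ci
  str_of <- function(occ) {
    act <- setdiff(occ, frozen)
    if (length(act) + length(intersect(occ, frozen)) != length(occ) ||
        !all(act %in% active))
      stop("determinant occupations inconsistent with active/frozen lists")
    paste(as.integer(active %in% act), collapse = "")
  }
  stra <- apply(ci$occ_alpha, 1, str_of)
  strb <- apply(ci$occ_beta, 1, str_of)
  listed <- sum(ci$coef^2)
  if (is.null(norm_total)) norm_total <- listed
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# DVMS CI vector, one determinant per line",
               paste("#", comment),
               "format civec-1",
               paste("norb", norb),
               paste("nalpha", ci$n_alpha),
               paste("nbeta", ci$n_beta),
               paste("active", paste(active, collapse = " ")),
               paste("frozen", paste(frozen, collapse = " ")),
               sprintf("norm_total %.12f", norm_total),
               sprintf("norm_listed %.12f", listed),
               paste("nterm", length(ci$coef)),
               sprintf("%s %s % .12e", stra, strb, ci$coef)), con)
  invisible(path)
}
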