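#' @useDynLib dvms, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# bohr per Angstrom (CODATA 2018)
BOHR_PER_ANGSTROM <- 1 / 0.529177210903

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr")

#' Molecular geometry
#'
#' A minimal container for a molecular geometry: element symbols and
#' cartesian coordinates in bohr.
#'
#' @param symbols character vector of element symbols.
#' @param xyz numeric matrix (n atoms x 3), coordinates in bohr.
#' @return An object of class \code{dvms_geometry}.
#' @export
geometry <- function(symbols, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(is.character(symbols), nrow(xyz) == length(symbols),
            ncol(xyz) == 3, length(symbols) >= 1)
  if (!all(symbols %in% .ELEMENTS))
    stop("unknown element symbol(s): ",
         paste(setdiff(symbols, .ELEMENTS), collapse = ", "))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  structure(list(symbols = symbols, xyz = unname(xyz)),
            class = "dvms_geometry")
}

#' @export
print.dvms_geometry <- function(x, ...) {
  cat("dvms geometry:", length(x$symbols), "atoms (",
      paste(rle(sort(x$symbols))$values, rle(sort(x$symbols))$lengths,
            sep = "x", collapse = ", "), ")\n")
  invisible(x)
}

#' Ideal D6h benzene geometry
#'
#' Builds a regular hexagonal benzene in the xy-plane with the C6 axis
#' along z.  For a regular hexagon the ring circumradius equals the C-C
#' bond length.  Defaults are typical DFT-quality bond lengths.
#'
#' @param r_cc C-C bond length in Angstrom (1.2 < r_cc < 1.6).
#' @param r_ch C-H bond length in Angstrom (0.9 < r_ch < 1.3).
#' @return A \code{dvms_geometry} with 6 carbons then 6 hydrogens (bohr).
#' @export
build_benzene <- function(r_cc = 1.397, r_ch = 1.087) {
  if (!(r_cc > 1.2 && r_cc < 1.6)) stop("r_cc out of range (1.2, 1.6) A")
  if (!(r_ch > 0.9 && r_ch < 1.3)) stop("r_ch out of range (0.9, 1.3) A")
  th <- pi / 3 * (0:5)
  rc <- r_cc * BOHR_PER_ANGSTROM
  rh <- (r_cc + r_ch) * BOHR_PER_ANGSTROM
  xyz <- rbind(cbind(rc * cos(th), rc * sin(th), 0),
               cbind(rh * cos(th), rh * sin(th), 0))
  geometry(c(rep("C", 6), rep("H", 6)), xyz)
}

#' Read an XYZ file
#'
#' Standard XYZ: atom count, comment line, then \code{symbol x y z} rows in
#' Angstrom.  Coordinates are converted to bohr.
#'
#' @param path file path.
#' @return A \code{dvms_geometry}.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  geometry(sym, xyz * BOHR_PER_ANGSTROM)
}

#' Write an XYZ file (Angstrom)
#'
#' @param geom a \code{dvms_geometry} (coordinates in bohr).
#' @param path output file path.
#' @param comment comment line.
#' @param symbols optional replacement symbols (for pseudo-atom export).
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(geom, path, comment = "", symbols = NULL) {
  sym <- if (is.null(symbols)) geom$symbols else symbols
  xyz <- geom$xyz / BOHR_PER_ANGSTROM
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", length(sym)), comment), con)
  writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                     sym, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}
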