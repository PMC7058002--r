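# Real-space projections of wavefunction tiles: single-electron
# cross-section scalar fields (Gaussian cube export) and site geometry
# export (XYZ with electron pseudo-atoms).

.Z_OF <- stats::setNames(seq_along(.ELEMENTS), .ELEMENTS)

#' Cross-section of the wavefunction through one electron
#'
#' Evaluates Psi on a regular 3-D grid for one electron, holding all
#' other electrons fixed at the site: the real-space projection of the
#' tile in that electron's dimensions.  Sign is preserved.
#'
#' @param wf a \code{dvms_wavefunction}.
#' @param site a \code{dvms_site}.
#' @param electron electron index (1..N; alpha block first).
#' @param side cube edge length (bohr), centred on the electron's site
#'   position.
#' @param n grid points per axis.
#' @return An object of class \code{dvms_field}: \code{origin},
#'   \code{step} (3 axis steps), \code{values} (n x n x n array, z
#'   fastest when flattened), \code{electron}, \code{site}.
#' @export
cross_section <- function(wf, site, electron, side = 4, n = 40) {
  N <- wf$n_electron
  if (electron < 1 || electron > N) stop("electron index out of range")
  x0 <- site$x
  centre <- x0[(3 * electron - 2):(3 * electron)]
  g <- seq(-side / 2, side / 2, length.out = n)
  pts <- as.matrix(expand.grid(z = g, y = g, x = g))[, 3:1]  # z fastest
  X <- matrix(rep(x0, each = nrow(pts)), nrow = nrow(pts))
  X[, (3 * electron - 2):(3 * electron)] <-
    pts + rep(centre, each = nrow(pts))
  vals <- psi_value(wf, X)
  structure(list(origin = centre - side / 2,
                 step = rep(g[2] - g[1], 3), n = rep(n, 3),
                 values = array(vals, c(n, n, n)),  # [z, y, x]
                 electron = electron, site_label = site$label),
            class = "dvms_field")
}

#' @export
print.dvms_field <- function(x, ...) {
  cat(sprintf("dvms field: %dx%dx%d grid for electron %d, |Psi| range [%.3e, %.3e]\n",
              x$n[1], x$n[2], x$n[3], x$electron, min(abs(x$values)),
              max(abs(x$values))))
  invisible(x)
}

#' Write a Gaussian cube file
#'
#' Standard cube format: bohr units, atom block, values with z fastest.
#'
#' @param field a \code{dvms_field}.
#' @param geom a \code{dvms_geometry} (may be NULL for toy systems).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cube <- function(field, geom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nat <- if (is.null(geom)) 0L else nrow(geom$xyz)
  writeLines(c("dvms wavefunction cross-section",
               sprintf("electron %d of site %s", field$electron,
                       field$site_label)), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat,
                     field$origin[1], field$origin[2], field$origin[3]),
             con)
  n <- field$n
  writeLines(c(sprintf("%5d %11.6f %11.6f %11.6f", n[3], field$step[1], 0, 0),
               sprintf("%5d %11.6f %11.6f %11.6f", n[2], 0, field$step[2], 0),
               sprintf("%5d %11.6f %11.6f %11.6f", n[1], 0, 0, field$step[3])),
             con)
  if (nat > 0) {
    z <- .Z_OF[geom$symbols]
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, as.numeric(z),
                       geom$xyz[, 1], geom$xyz[, 2], geom$xyz[, 3]), con)
  }
  # values: x slowest, z fastest; array is [z, y, x]
  v <- as.numeric(field$values)  # z fastest already
  lines <- vapply(split(v, ceiling(seq_along(v) / 6)),
                  function(ch) paste(sprintf("%13.5e", ch), collapse = " "),
                  "")
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @return list with \code{origin}, \code{step}, \code{n},
#'   \code{values} array ([z, y, x], as written by
#'   \code{\link{write_cube}}), \code{atoms} (data frame or NULL).
#' @export
read_cube <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[3:6]), "\\s+")
  nat <- as.integer(hdr[[1]][1])
  origin <- as.numeric(hdr[[1]][2:4])
  nx <- as.integer(hdr[[2]][1]); ny <- as.integer(hdr[[3]][1])
  nz <- as.integer(hdr[[4]][1])
  step <- c(as.numeric(hdr[[2]][2]), as.numeric(hdr[[3]][3]),
            as.numeric(hdr[[4]][4]))
  atoms <- NULL
  at0 <- 7
  if (nat > 0) {
    arows <- strsplit(trimws(ln[at0:(at0 + nat - 1)]), "\\s+")
    atoms <- data.frame(
      Z = vapply(arows, function(r) as.integer(r[1]), 1L),
      x = vapply(arows, function(r) as.numeric(r[3]), 1.0),
      y = vapply(arows, function(r) as.numeric(r[4]), 1.0),
      z = vapply(arows, function(r) as.numeric(r[5]), 1.0))
  }
  v <- as.numeric(unlist(strsplit(trimws(ln[(at0 + nat):length(ln)]),
                                  "\\s+")))
  list(origin = origin, step = step, n = c(nz, ny, nx),
       values = array(v, c(nz, ny, nx)), atoms = atoms)
}

#' Export a Voronoi site as XYZ with electron pseudo-atoms
#'
#' Writes the molecular geometry plus one pseudo-atom per electron:
#' alpha electrons tagged \code{Xa}, beta electrons \code{Xb}.
#' Coordinates in Angstrom (XYZ convention).
#'
#' @param site a \code{dvms_site}.
#' @param geom a \code{dvms_geometry} (or NULL).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_site_xyz <- function(site, geom, path) {
  na <- site$n_alpha
  nb <- site$n_beta
  el <- matrix(site$x, ncol = 3, byrow = TRUE)
  sym <- c(if (!is.null(geom)) geom$symbols, rep("Xa", na), rep("Xb", nb))
  xyz <- rbind(if (!is.null(geom)) geom$xyz, el)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", nrow(xyz)),
               sprintf("dvms site %s (Xa/Xb = alpha/beta electrons)",
                       site$label)), con)
  A <- xyz / BOHR_PER_ANGSTROM
  writeLines(sprintf("%-3s %16.10f %16.10f %16.10f",
                     sym, A[, 1], A[, 2], A[, 3]), con)
  invisible(path)
}

#' Read a site XYZ written by \code{\link{export_site_xyz}}
#'
#' @param path file path.
#' @return list with \code{geometry} (\code{dvms_geometry} of the real
#'   atoms, or NULL), \code{site} (a \code{dvms_site} rebuilt from the
#'   pseudo-atoms, bohr).
#' @export
read_site_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[[`, "", 1L)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3))) *
    BOHR_PER_ANGSTROM
  isa <- sym == "Xa"; isb <- sym == "Xb"
  real <- !(isa | isb)
  geom <- if (any(real)) geometry(sym[real], xyz[real, , drop = FALSE])
  x <- c(t(xyz[isa, , drop = FALSE]), t(xyz[isb, , drop = FALSE]))
  list(geometry = geom,
       site = voronoi_site(x, sum(isa), sum(isb), "imported"))
}
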