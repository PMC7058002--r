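# Gaussian AO basis handling: shell lists expanded to flat per-AO arrays
# (one cartesian monomial per AO) consumed by the C++ evaluation kernels.

.CART <- list(
  matrix(c(0, 0, 0), 1, 3, byrow = TRUE),
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1), 3, 3, byrow = TRUE),
  matrix(c(2, 0, 0,  0, 2, 0,  0, 0, 2,  1, 1, 0,  1, 0, 1,  0, 1, 1),
         6, 3, byrow = TRUE))

.dfact <- function(n) if (n <= 0) 1 else prod(seq(n, 1, by = -2))

# norm of a primitive cartesian Gaussian x^l y^m z^n exp(-a r^2)
.prim_norm <- function(a, lmn) {
  L <- sum(lmn)
  (2 * a / pi)^0.75 * (4 * a)^(L / 2) /
    sqrt(.dfact(2 * lmn[1] - 1) * .dfact(2 * lmn[2] - 1) *
         .dfact(2 * lmn[3] - 1))
}

# closed-form self-overlap of a contracted cartesian Gaussian (same centre)
.contracted_self_overlap <- function(exps, coefs, lmn) {
  s <- 0
  for (p in seq_along(exps)) for (q in seq_along(exps)) {
    pp <- exps[p] + exps[q]
    s1 <- (pi / pp)^1.5 * prod(vapply(lmn, function(l)
      .dfact(2 * l - 1) / (2 * pp)^l, numeric(1)))
    s <- s + coefs[p] * coefs[q] * s1
  }
  s
}

#' Construct an AO basis from a shell list
#'
#' Each shell is a list with elements \code{center} (length-3, bohr),
#' \code{l} (0 = s, 1 = p, 2 = d, cartesian), \code{exps} (positive
#' exponents) and \code{coefs} (contraction coefficients, referring to
#' normalised primitives).  Cartesian components are expanded in the order
#' s; x,y,z; xx,yy,zz,xy,xz,yz, and each contracted component is
#' normalised to unit self-overlap.
#'
#' @param shells list of shells (see Details).
#' @return An object of class \code{dvms_basis} with flat per-AO arrays.
#' @export
ao_basis <- function(shells) {
  for (sh in shells) {
    stopifnot(length(sh$center) == 3, sh$l %in% 0:2,
              length(sh$exps) == length(sh$coefs), length(sh$exps) >= 1)
    if (any(sh$exps <= 0)) stop("primitive exponents must be positive")
  }
  lmn <- NULL; cen <- NULL; nprim <- integer(); exps <- list(); coefs <- list()
  shell_of <- integer()
  for (si in seq_along(shells)) {
    sh <- shells[[si]]
    comp <- .CART[[sh$l + 1]]
    for (ci in seq_len(nrow(comp))) {
      v <- comp[ci, ]
      cc <- .normalise_contraction(sh$exps, sh$coefs, v)
      lmn <- rbind(lmn, v)
      cen <- rbind(cen, as.numeric(sh$center))
      nprim <- c(nprim, length(sh$exps))
      exps <- c(exps, list(sh$exps))
      coefs <- c(coefs, list(cc))
      shell_of <- c(shell_of, si)
    }
  }
  nao <- length(nprim)
  mp <- max(nprim)
  em <- matrix(0, nao, mp); cm <- matrix(0, nao, mp)
  for (i in seq_len(nao)) {
    em[i, seq_len(nprim[i])] <- exps[[i]]
    cm[i, seq_len(nprim[i])] <- coefs[[i]]
  }
  structure(list(shells = shells, lmn = unname(lmn), cen = unname(cen),
                 nprim = nprim, exps = em, coefs = cm, nao = nao,
                 shell_of = shell_of),
            class = "dvms_basis")
}

#' @export
print.dvms_basis <- function(x, ...) {
  cat("dvms AO basis:", length(x$shells), "shells,", x$nao,
      "cartesian AOs\n")
  invisible(x)
}

# self-overlap based contracted normalisation, simplified entry point used
# by ao_basis above (kept separate for testability)
.normalise_contraction <- function(exps, coefs, lmn) {
  cc <- coefs * vapply(exps, .prim_norm, numeric(1), lmn = lmn)
  cc / sqrt(.contracted_self_overlap(exps, cc, lmn))
}

#' Read a Molden file
#'
#' Parses \code{[Atoms]}, \code{[GTO]} and \code{[MO]} sections with
#' cartesian d functions (\code{[6D]}; spherical \code{[5D]} files are
#' rejected).  Contraction coefficients are interpreted as referring to
#' normalised primitives and every contracted cartesian component is
#' renormalised to unit self-overlap.  If the \code{Sym=} labels carry a
#' leading integer (e.g. \code{Sym= 22a}) it is kept as the orbital's
#' original index.
#'
#' @param path Molden file path.
#' @return list with \code{geometry} (\code{dvms_geometry}),
#'   \code{basis} (\code{dvms_basis}) and \code{mo} (list: \code{C} AO x MO
#'   coefficient matrix, \code{energy}, \code{occupation},
#'   \code{orig_index}, \code{label}).
#' @export
read_molden <- function(path) {
  ln <- readLines(path)
  secs <- grep("^\\s*\\[", ln)
  sec_name <- tolower(gsub("\\[|\\].*", "", trimws(ln[secs])))
  if ("5d" %in% sec_name || "5d7f" %in% sec_name)
    stop("spherical-harmonic d shells ([5D]) are not supported; ",
         "use a cartesian (6d) Molden file")
  span <- function(nm) {
    i <- which(sec_name == nm)[1]
    if (is.na(i)) return(NULL)
    from <- secs[i] + 1
    to <- if (i < length(secs)) secs[i + 1] - 1 else length(ln)
    ln[seq(from, length.out = max(0, to - from + 1))]
  }
  # atoms
  head_atoms <- trimws(ln[secs[which(sec_name == "atoms")[1]]])
  unit <- if (grepl("au", tolower(head_atoms))) 1 else BOHR_PER_ANGSTROM
  arows <- strsplit(trimws(span("atoms")), "\\s+")
  arows <- arows[lengths(arows) >= 6]
  sym <- vapply(arows, `[[`, "", 1L)
  sym <- paste0(toupper(substr(sym, 1, 1)), tolower(substring(sym, 2)))
  xyz <- t(vapply(arows, function(r) as.numeric(r[4:6]), numeric(3))) * unit
  geom <- geometry(sym, xyz)
  # GTO
  gl <- span("gto")
  shells <- list()
  i <- 1
  lmap <- c(s = 0, p = 1, d = 2)
  while (i <= length(gl)) {
    line <- trimws(gl[i])
    if (line == "") { i <- i + 1; next }
    hdr <- strsplit(line, "\\s+")[[1]]
    atom_idx <- as.integer(hdr[1])
    i <- i + 1
    while (i <= length(gl) && trimws(gl[i]) != "") {
      sh <- strsplit(trimws(gl[i]), "\\s+")[[1]]
      typ <- tolower(sh[1])
      np <- as.integer(sh[2])
      prim <- t(vapply(strsplit(trimws(gl[i + seq_len(np)]), "\\s+"),
                       function(r) as.numeric(gsub("[dD]", "e", r)),
                       numeric(if (typ == "sp") 3 else 2)))
      if (typ == "sp") {
        shells <- c(shells,
                    list(list(center = geom$xyz[atom_idx, ], l = 0L,
                              exps = prim[, 1], coefs = prim[, 2]),
                         list(center = geom$xyz[atom_idx, ], l = 1L,
                              exps = prim[, 1], coefs = prim[, 3])))
      } else {
        if (!typ %in% names(lmap))
          stop("unsupported shell type in Molden file: ", typ)
        shells <- c(shells, list(list(center = geom$xyz[atom_idx, ],
                                      l = lmap[[typ]],
                                      exps = prim[, 1], coefs = prim[, 2])))
      }
      i <- i + np + 1
    }
  }
  basis <- ao_basis(shells)
  # MOs
  ml <- span("mo")
  idx_ene <- grep("^\\s*Ene\\s*=", ml)
  idx_sym <- grep("^\\s*Sym\\s*=", ml)
  idx_occ <- grep("^\\s*Occup\\s*=", ml)
  starts <- sort(if (length(idx_sym)) idx_sym else idx_ene)
  nmo <- length(starts)
  C <- matrix(0, basis$nao, nmo)
  energy <- numeric(nmo); occ <- numeric(nmo)
  orig <- integer(nmo); lab <- character(nmo)
  bounds <- c(starts, length(ml) + 1)
  for (k in seq_len(nmo)) {
    blk <- ml[bounds[k]:(bounds[k + 1] - 1)]
    g <- function(pat) {
      hit <- grep(pat, blk, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub(pat, "", hit[1]))
    }
    lab[k] <- g("^\\s*Sym\\s*=")
    energy[k] <- suppressWarnings(as.numeric(g("^\\s*Ene\\s*=")))
    occ[k] <- suppressWarnings(as.numeric(g("^\\s*Occup\\s*=")))
    oi <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1", lab[k])))
    orig[k] <- if (!is.na(oi)) oi else k
    rows <- grep("^\\s*[0-9]+\\s+[-0-9.eEdD+]+\\s*$", blk, value = TRUE)
    for (r in strsplit(trimws(rows), "\\s+")) {
      C[as.integer(r[1]), k] <- as.numeric(gsub("[dD]", "e", r[2]))
    }
  }
  if (anyNA(energy)) energy[is.na(energy)] <- 0
  if (anyNA(occ)) occ[is.na(occ)] <- 0
  label <- ifelse(occ > 0, "occupied", "virtual")
  list(geometry = geom, basis = basis,
       mo = list(C = C, energy = energy, occupation = occ,
                 orig_index = orig, label = label))
}
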