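# Committed benzene fixtures, Molden / CI-vector readers, toy registry.

test_that("fixture checksums verify", {
  expect_silent(verify_fixtures())
})

test_that("the benzene MO fixture loads with the right electron structure", {
  wf <- load_benzene("single")
  expect_identical(wf$n_electron, 42L + 0L)
  expect_identical(wf$n_alpha, 21L)
  expect_identical(wf$n_beta, 21L)
  expect_identical(wf$basis$nao, 102L)  # 6-31G(d), cartesian d
  expect_identical(nrow(wf$geometry$xyz), 12L)
  # six pi MOs among the stored orbitals
  expect_identical(sum(pi_orbitals(wf$basis, wf$mo$C)), 6L)
})

test_that("stored MO values match the generating engine's reference values", {
  wf <- load_benzene("single")
  ln <- readLines(system.file("extdata", "benzene_reference_values.tsv",
                              package = "dvms"))
  rows <- strsplit(grep("^MOVAL", ln, value = TRUE), "\\s+")
  pts <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  ref <- t(vapply(rows, function(r) as.numeric(r[-(1:4)]),
                  numeric(ncol(wf$mo$C))))
  vals <- eval_orbitals(wf, pts)
  expect_lt(max(abs(vals - ref)), 1e-8)
})

test_that("Psi at spot-check configurations matches the engine", {
  ln <- readLines(system.file("extdata", "benzene_reference_values.tsv",
                              package = "dvms"))
  rows <- strsplit(grep("^PSI", ln, value = TRUE), "\\s+")
  X <- t(vapply(rows, function(r) as.numeric(r[2:127]), numeric(126)))
  ref1 <- vapply(rows, function(r) as.numeric(r[128]), numeric(1))
  ref7 <- vapply(rows, function(r) as.numeric(r[129]), numeric(1))
  wf1 <- load_benzene("single")
  expect_lt(max(abs(psi_value(wf1, X) - ref1) / abs(ref1)), 1e-4)
  wf7 <- load_benzene("cas66", n_configs = 7)
  expect_identical(length(wf7$ci$coef), 7L)
  expect_lt(max(abs(psi_value(wf7, X) - ref7) / abs(ref7)), 1e-4)
})

test_that("the (6,6) CI fixture has the documented structure", {
  wf <- load_benzene("cas66")
  cv <- attr(wf, "civec")
  expect_lte(length(wf$ci$coef), 400)  # at most C(6,3)^2 determinants
  expect_identical(length(cv$active), 6L)
  expect_equal(cv$norm_total, 1.0, tolerance = 1e-9)
  # terms sorted by decreasing magnitude
  expect_true(all(diff(abs(wf$ci$coef)) <= 1e-12))
  # leading determinant is the closed-shell reference (both spins equal)
  expect_identical(wf$ci$occ_alpha[1, ], wf$ci$occ_beta[1, ])
  # degenerate-group truncation boundaries include 7 and 21
  gs <- ci_group_sizes(wf$ci)
  expect_true(all(c(7, 21) %in% gs))
})

test_that("the (30,18) CI fixture is a normalised leading-term vector", {
  wf <- load_benzene("cas3018")
  cv <- attr(wf, "civec")
  expect_identical(length(cv$active), 18L)
  expect_identical(length(cv$frozen), 6L)
  expect_equal(cv$norm_total, 1.0, tolerance = 1e-6)
  expect_gt(cv$norm_listed, 0.999)
  expect_gt(sum(wf$ci$coef[1]^2), 0.9)  # dominated by the reference
})

test_that("civec files round-trip", {
  wf <- load_benzene("cas66")
  cv <- attr(wf, "civec")
  p <- withr::local_tempfile(fileext = ".civec")
  # rebuild absolute indices for writing
  raw <- read_civec(system.file("extdata", "benzene_cas66.civec",
                                package = "dvms"))
  write_civec(raw$ci, p, active = raw$active, frozen = raw$frozen,
              norb = raw$norb, norm_total = raw$norm_total)
  back <- read_civec(p)
  expect_equal(back$ci$coef, raw$ci$coef)
  expect_identical(back$ci$occ_alpha, raw$ci$occ_alpha)
  expect_identical(back$active, raw$active)
})

test_that("the Molden reader handles a minimal handwritten file", {
  p <- withr::local_tempfile(fileext = ".molden")
  writeLines(c(
    "[Molden Format]",
    "[Atoms] AU",
    "H 1 1 0.0 0.0 -0.7",
    "H 2 1 0.0 0.0  0.7",
    "[GTO]",
    "1 0",
    " s 2 1.00",
    "  1.3000000000e+00 0.6000000000e+00",
    "  0.4000000000e+00 0.5000000000e+00",
    "",
    "2 0",
    " s 1 1.00",
    "  0.9000000000e+00 1.0000000000e+00",
    " p 1 1.00",
    "  0.8000000000e+00 1.0000000000e+00",
    "",
    "[MO]",
    " Sym= 1a",
    " Ene= -0.5",
    " Spin= Alpha",
    " Occup= 2.0",
    "    1 0.55",
    "    2 0.55",
    "    4 0.10",
    " Sym= 2a",
    " Ene= 0.3",
    " Spin= Alpha",
    " Occup= 0.0",
    "    1 0.8",
    "    2 -0.8"), p)
  mol <- read_molden(p)
  expect_identical(mol$basis$nao, 5L)  # s + s + px,py,pz
  expect_identical(dim(mol$mo$C), c(5L, 2L))
  expect_identical(mol$mo$orig_index, c(1L, 2L))
  expect_equal(mol$mo$occupation, c(2, 0))
  expect_equal(mol$geometry$xyz[, 3], c(-0.7, 0.7))
  # missing coefficient rows are zeros
  expect_equal(mol$mo$C[3, 1], 0)
  # spherical files are rejected with guidance
  writeLines(c("[Molden Format]", "[5D]"), p)
  expect_error(read_molden(p), "5D")
})

test_that("toy registry is closed and informative", {
  expect_error(make_toy("no_such_toy"), "registry")
  for (nm in c("two_electron_triplet", "two_plus_two", "double_well_ci")) {
    toy <- make_toy(nm)
    expect_s3_class(toy$wf, "dvms_wavefunction")
    expect_gte(length(toy$sites), 2)
  }
  # the triplet toy's node: Psi = 0 exactly on x1 = x2 symmetric points
  toy <- make_toy("two_electron_triplet")
  for (rep in 1:5) {
    p <- rnorm(3)
    x <- c(p, p + c(0, rnorm(2)))  # equal x-coordinates
    x[4] <- x[1]
    expect_equal(psi_value(toy$wf, x), 0, tolerance = 1e-14)
  }
})
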