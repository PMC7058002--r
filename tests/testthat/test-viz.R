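# Cross-section fields and cube / XYZ export.

test_that("cross-section values equal fresh psi evaluations pointwise", {
  toy <- make_toy("two_electron_triplet")
  site <- toy$sites[[1]]
  f <- cross_section(toy$wf, site, electron = 2, side = 3, n = 7)
  # the electron's own site position carries Psi(site)
  centre_idx <- (7 + 1) / 2
  expect_equal(f$values[centre_idx, centre_idx, centre_idx],
               psi_value(toy$wf, site$x), tolerance = 1e-12)
  set.seed(137)
  g <- seq(-1.5, 1.5, length.out = 7)
  for (rep in 1:40) {
    iz <- sample(7, 1); iy <- sample(7, 1); ix <- sample(7, 1)
    x <- site$x
    x[4:6] <- site$x[4:6] + c(g[ix], g[iy], g[iz])
    expect_equal(f$values[iz, iy, ix], psi_value(toy$wf, x),
                 tolerance = 1e-12)
  }
})

test_that("a one-electron cross-section is the orbital itself", {
  a <- 0.7
  basis <- ao_basis(list(list(center = c(0, 0, 0), l = 0L, exps = a,
                              coefs = 1)))
  mo <- list(C = matrix(1), energy = 0, occupation = 1, orig_index = 1,
             label = "occupied")
  wf <- wavefunction(basis, mo, single_determinant(1, 0))
  site <- voronoi_site(c(0, 0, 0), 1, 0)
  f <- cross_section(wf, site, 1, side = 2, n = 5)
  g <- seq(-1, 1, length.out = 5)
  for (ix in 1:5)
    expect_equal(f$values[3, 3, ix],
                 eval_orbitals(wf, c(g[ix], 0, 0))[1, 1],
                 tolerance = 1e-12)
})

test_that("cube files round-trip bit-identically", {
  toy <- make_toy("two_electron_triplet")
  f <- cross_section(toy$wf, toy$sites[[1]], 1, side = 2, n = 4)
  p1 <- withr::local_tempfile(fileext = ".cube")
  p2 <- withr::local_tempfile(fileext = ".cube")
  write_cube(f, NULL, p1)
  rd <- read_cube(p1)
  f2 <- f
  f2$origin <- rd$origin
  f2$step <- rd$step
  f2$values <- rd$values
  write_cube(f2, NULL, p2)
  expect_identical(readLines(p1), readLines(p2))
  # values recovered to the format's precision
  expect_equal(rd$values, f$values, tolerance = 1e-4)
  # all-zero field writes zeros
  fz <- f
  fz$values[] <- 0
  fz$n <- rep(dim(fz$values)[1], 3)
  write_cube(fz, NULL, p1)
  expect_true(all(read_cube(p1)$values == 0))
})

test_that("site XYZ export carries atoms plus spin-tagged pseudo-atoms", {
  geom <- build_benzene()
  site <- voronoi_site(lewis_guess_benzene(geom), 21, 21, "eclipsed-A")
  p <- withr::local_tempfile(fileext = ".xyz")
  export_site_xyz(site, geom, p)
  ln <- readLines(p)
  expect_identical(as.integer(ln[1]), 12L + 42L)
  back <- read_site_xyz(p)
  expect_equal(back$site$x, site$x, tolerance = 1e-8)
  expect_identical(back$geometry$symbols, geom$symbols)
  # the alpha-rotated (staggered) site differs in exactly 9 pseudo-atoms
  sites <- build_reference_sites(site, geom)
  p2 <- withr::local_tempfile(fileext = ".xyz")
  export_site_xyz(sites[[2]], geom, p2)
  b2 <- read_site_xyz(p2)
  d <- matrix(b2$site$x - back$site$x, ncol = 3, byrow = TRUE)
  expect_identical(sum(rowSums(d^2) > 1e-12), 9L)
})
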