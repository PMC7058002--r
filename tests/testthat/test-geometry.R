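test_that("benzene builder produces an ideal D6h ring", {
  g <- build_benzene(1.397, 1.087)
  expect_length(g$symbols, 12)
  cc <- g$xyz[1:6, ]
  # ring bond lengths all equal r_cc
  r_cc <- 1.397 / 0.529177210903
  for (b in 1:6) {
    d <- sqrt(sum((cc[b, ] - cc[b %% 6 + 1, ])^2))
    expect_equal(d, r_cc, tolerance = 1e-12)
  }
  # C-H bonds radial with length r_ch
  r_ch <- 1.087 / 0.529177210903
  for (b in 1:6)
    expect_equal(sqrt(sum((g$xyz[b + 6, ] - cc[b, ])^2)), r_ch,
                 tolerance = 1e-12)
  # invariant as a set under 60-degree rotation about z
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- g$xyz %*% t(R)
  for (i in 1:12) {
    d <- sqrt(rowSums((g$xyz - rep(rot[i, ], each = 12))^2))
    expect_lt(min(d[g$symbols == g$symbols[i]]), 1e-10)
  }
})

test_that("benzene inertia tensor is an oblate symmetric top", {
  g <- build_benzene()
  m <- ifelse(g$symbols == "C", 12.0, 1.008)
  xyz <- sweep(g$xyz, 2, colSums(g$xyz * m) / sum(m))
  I <- matrix(0, 3, 3)
  for (i in seq_len(12)) {
    r <- xyz[i, ]
    I <- I + m[i] * (sum(r^2) * diag(3) - outer(r, r))
  }
  ev <- sort(eigen(I, symmetric = TRUE)$values)
  expect_equal(ev[1], ev[2], tolerance = 1e-10)  # degenerate in-plane pair
  expect_equal(ev[3], ev[1] + ev[2], tolerance = 1e-10)  # planar: Ic=Ia+Ib
})

test_that("bond-length preconditions are enforced", {
  expect_error(build_benzene(r_cc = 1.7), "r_cc")
  expect_error(build_benzene(r_ch = 0.5), "r_ch")
  expect_error(geometry("Zz", matrix(0, 1, 3)), "element")
})

test_that("XYZ files round-trip through Angstrom", {
  g <- build_benzene()
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, f, comment = "benzene")
  g2 <- read_xyz(f)
  expect_equal(g2$symbols, g$symbols)
  expect_equal(g2$xyz, g$xyz, tolerance = 1e-9)
})
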