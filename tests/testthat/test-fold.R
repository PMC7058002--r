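# Permutation folding and nearest-site classification.

test_that("permutation_parity matches a swap-count oracle", {
  expect_identical(permutation_parity(1:5), 1L)
  expect_identical(permutation_parity(c(2L, 1L, 3L)), -1L)
  set.seed(41)
  for (rep in 1:50) {
    p <- sample(8)
    expect_identical(permutation_parity(p), bubble_parity(p))
  }
  # multiplicative under composition
  for (rep in 1:20) {
    p <- sample(6); q <- sample(6)
    expect_identical(permutation_parity(p[q]),
                     permutation_parity(p) * permutation_parity(q))
  }
  expect_error(permutation_parity(c(1L, 1L, 3L)), "permutation")
})

test_that("trivial folds behave as forced", {
  s <- voronoi_site(c(0, 0, 0, 2, 0, 0), 2, 0)
  f0 <- best_fold(s$x, s)
  expect_identical(f0$alpha_perm, 1:2)
  expect_identical(f0$parity, 1L)
  expect_equal(f0$sq_distance, 0)
  # swapped electrons: transposition, odd parity
  fx <- best_fold(c(2, 0, 0, 0, 0, 0), s)
  expect_identical(fx$alpha_perm, c(2L, 1L))
  expect_identical(fx$parity, -1L)
  expect_equal(fx$sq_distance, 0)
  expect_equal(fx$folded, s$x)
})

test_that("best_fold equals exhaustive permutation search", {
  set.seed(43)
  for (rep in 1:250) {
    na <- sample(1:5, 1)
    nb <- sample(0:4, 1)
    x <- rnorm(3 * (na + nb), sd = 2)
    sx <- rnorm(3 * (na + nb), sd = 2)
    f <- best_fold(x, sx, na, nb)
    o <- exhaustive_fold(x, sx, na, nb)
    expect_equal(f$sq_distance, o$sq_distance, tolerance = 1e-10)
    expect_identical(f$parity, o$parity)
    # folded config really is the stated relabelling, and its distance
    # to the site equals the minimum
    expect_equal(sum((f$folded - sx)^2), o$sq_distance, tolerance = 1e-10)
  }
})

test_that("folding is idempotent and invariant under pre-permutation", {
  set.seed(47)
  na <- 4; nb <- 3
  for (rep in 1:50) {
    x <- rnorm(3 * (na + nb), sd = 2)
    sx <- rnorm(3 * (na + nb), sd = 2)
    f <- best_fold(x, sx, na, nb)
    f2 <- best_fold(f$folded, sx, na, nb)
    expect_identical(f2$alpha_perm, seq_len(na))
    expect_identical(f2$beta_perm, seq_len(nb))
    # distance unchanged by relabelling x first
    xp <- permute_block(x, sample(na), 0)
    xp <- permute_block(xp, sample(nb), na)
    fp <- best_fold(xp, sx, na, nb)
    expect_equal(fp$sq_distance, f$sq_distance, tolerance = 1e-10)
  }
})

test_that("folding is consistent with the wavefunction's antisymmetry", {
  wf <- make_toy("two_plus_two")$wf
  set.seed(53)
  site <- voronoi_site(rnorm(12), 2, 2)
  for (rep in 1:30) {
    x <- rnorm(12, sd = 1.5)
    v <- psi_value(wf, x)
    f <- best_fold(x, site)
    vf <- psi_value(wf, f$folded)
    expect_equal(abs(vf), abs(v), tolerance = 1e-10 * max(abs(v), 1e-300))
    expect_equal(vf, f$parity * v, tolerance = 1e-10 * max(abs(v), 1e-300))
  }
})

test_that("nearest_site classifies like exhaustive enumeration", {
  toy <- make_toy("two_electron_triplet")
  set.seed(59)
  S <- do.call(rbind, lapply(toy$sites, function(s) s$x))
  for (rep in 1:200) {
    x <- rnorm(6, sd = 1.5)
    ns <- nearest_site(x, toy$sites)
    d <- vapply(seq_len(nrow(S)), function(i)
      exhaustive_fold(x, S[i, ], 2, 0)$sq_distance, numeric(1))
    expect_identical(ns$index, which.min(d))
  }
  # the toy's two sites are permutation images, so every point folds to
  # zero distance from both and the tie breaks to the lowest index
  ns <- nearest_site(toy$sites[[2]]$x, toy$sites)
  expect_identical(ns$index, 1L)
  expect_equal(ns$sq_distance, 0)
  # for sites that are NOT permutation images, a point equal to a site
  # lands on that site with zero distance
  dw <- make_toy("double_well_ci")
  ns2 <- nearest_site(dw$sites[[2]]$x, dw$sites)
  expect_identical(ns2$index, 2L)
  expect_equal(ns2$sq_distance, 0)
  expect_error(nearest_site(rnorm(6), list()), "site")
})
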