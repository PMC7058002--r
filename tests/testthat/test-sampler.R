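# Metropolis machinery: proposals, acceptance rule, determinism and
# stationary distributions on analytic targets.

test_that("propose_step has the stated per-dimension variance", {
  set.seed(61)
  p0 <- matrix(0, 1000, 3)
  d <- propose_step(p0, step_variance = 0.2) - p0
  v <- apply(d, 2, var)
  se <- 0.2 * sqrt(2 / (nrow(p0) - 1))
  expect_true(all(abs(v - 0.2) < 3 * se))
  # variance -> 0 limit: proposal equals the current position
  expect_equal(propose_step(p0, 0), p0)
})

test_that("accept_step implements Metropolis with node-crossing rejection", {
  # uphill same-sign moves always accepted
  expect_true(accept_step(0.1, 0.5, u = 0.999))
  expect_true(accept_step(-0.1, -0.5, u = 0.999))
  # sign changes always rejected, however large |psi_new|
  expect_false(accept_step(0.1, -1e6, u = 1e-12))
  expect_false(accept_step(-0.1, 1e6, u = 1e-12))
  # downhill accepted with probability (psi_new/psi_old)^2
  expect_true(accept_step(1, 0.5, u = 0.2))
  expect_false(accept_step(1, 0.5, u = 0.3))
  expect_error(accept_step(0, 1), "node")
})

test_that("runs are deterministic given the seed and scale-invariant in the CI vector", {
  toy <- make_toy("double_well_ci", coef = c(1, 0.3))
  ens <- init_walkers(toy$wf, c(-1.5, 0, 0), 10)
  set.seed(71)
  w1 <- run_walk(toy$wf, ens$positions, 50)
  set.seed(71)
  w2 <- run_walk(toy$wf, ens$positions, 50)
  expect_identical(w1$positions, w2$positions)
  # multiplying all coefficients by a nonzero constant changes nothing
  wf_scaled <- toy$wf
  wf_scaled$ci$coef <- wf_scaled$ci$coef * -17.3
  set.seed(71)
  w3 <- run_walk(wf_scaled, ens$positions, 50)
  expect_equal(w3$positions, w1$positions)
  # zero steps: unchanged ensemble
  w0 <- run_walk(toy$wf, ens$positions, 0)
  expect_equal(w0$positions, ens$positions)
})

test_that("walkers sample |Psi|^2 on a single-Gaussian target", {
  # one electron in one s Gaussian: |Psi|^2 is a Gaussian centred on the
  # orbital centre with per-axis sd 1/sqrt(4a)
  a <- 0.5
  basis <- ao_basis(list(list(center = c(1, -2, 0.5), l = 0L, exps = a,
                              coefs = 1)))
  mo <- list(C = matrix(1), energy = 0, occupation = 1, orig_index = 1,
             label = "occupied")
  wf <- wavefunction(basis, mo, single_determinant(1, 0))
  set.seed(73)
  ens <- init_walkers(wf, c(1, -2, 0.5), 100)
  w <- run_walk(wf, ens$positions, 600)
  keep <- w$positions  # final positions of 100 quasi-independent walkers
  m <- colMeans(keep)
  sd_th <- 1 / sqrt(4 * a)
  se <- sd_th / sqrt(nrow(keep))
  expect_true(all(abs(m - c(1, -2, 0.5)) < 4 * se))
  expect_gt(w$acceptance, 0.1)
})

test_that("stationary cell occupancy matches quadrature on the double-well toy", {
  toy <- make_toy("double_well_ci", coef = c(1, 0.25))
  q <- tile_quadrature(toy$wf, toy$sites, which = 1, lim = 5, n = 41)
  set.seed(79)
  ens <- init_walkers(toy$wf, c(-1.5, 0, 0), 200)
  w <- run_walk(toy$wf, ens$positions, 1500, sites = toy$sites)
  # discard the first third as burn-in
  ks <- 501:1500
  frac_left <- mean(w$counts[ks, 1]) / 200
  # MC error: decorrelation-corrected over the window
  se <- sd(w$counts[ks, 1] / 200) / sqrt(length(ks) / 100)
  expect_lt(abs(frac_left - q$prob), 4 * max(se, 0.01))
  # symmetric coefficients: both wells equally likely by symmetry
  toy0 <- make_toy("double_well_ci", coef = c(1, 0))
  q0 <- tile_quadrature(toy0$wf, toy0$sites, which = 1, lim = 5, n = 41)
  expect_equal(q0$prob, 0.5, tolerance = 1e-9)
})

test_that("no accepted step ever changes the sign of Psi", {
  toy <- make_toy("two_electron_triplet")
  set.seed(83)
  x0 <- c(-1, 0.2, 0, 1, -0.1, 0)  # in the x1 < x2 tile
  s0 <- sign(psi_value(toy$wf, x0))
  ens <- init_walkers(toy$wf, x0, 50)
  w <- run_walk(toy$wf, ens$positions, 400)
  expect_true(all(sign(w$psi) == s0))
  expect_gt(w$n_sign_reject, 0)  # near-node proposals do occur and die
})

test_that("the psi maximiser climbs to a stationary point", {
  toy <- make_toy("double_well_ci", coef = c(1, 0.3))
  mx <- find_psi_maximum(toy$wf, c(-1.4, 0.2, 0.1))
  # the left well dominates for c2 > 0; max near the left centre
  expect_lt(abs(mx$x[1] + 1.5), 0.2)
  expect_lt(sqrt(mx$x[2]^2 + mx$x[3]^2), 0.05)
  expect_gt(abs(mx$psi), abs(psi_value(toy$wf, c(-1.4, 0.2, 0.1))))
})
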