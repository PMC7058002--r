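# Self-consistent centroid iteration and the staged-truncation protocol.

test_that("update_site reduces to forced cases", {
  P1 <- matrix(rep(c(1, 2, 3, 4, 5, 6), 3), 3, 6, byrow = TRUE)
  s <- update_site(P1, 1, 1)
  expect_equal(s$x, c(1, 2, 3, 4, 5, 6))
  # two walkers symmetric about a point -> midpoint
  P2 <- rbind(c(0, 0, 0, 1, 1, 1), c(2, 2, 2, 3, 3, 3))
  expect_equal(update_site(P2, 1, 1)$x, c(1, 1, 1, 2, 2, 2))
  expect_error(update_site(P2[0, , drop = FALSE], 1, 1), "position")
})

test_that("DVMS centroid on the two-electron toy matches grid quadrature", {
  toy <- make_toy("two_electron_triplet")
  q <- tile_quadrature(toy$wf, toy$sites, which = 1, lim = 5, n = 15)
  set.seed(97)
  x0 <- toy$sites[[1]]$x
  res <- run_dvms(toy$wf, x0, n_walkers = 150, block_steps = 400,
                  tol = 0.05, max_cycles = 12)
  expect_true(res$converged)
  # Monte-Carlo standard error per coordinate from the final ensemble
  se <- apply(res$walkers$positions, 2, sd) /
    sqrt(nrow(res$walkers$positions) / 3)
  expect_true(all(abs(res$site$x - q$centroid) < 3 * pmax(se, 0.03)))
})

test_that("an exactly self-consistent start stays put", {
  toy <- make_toy("two_electron_triplet")
  q <- tile_quadrature(toy$wf, toy$sites, which = 1, lim = 5, n = 15)
  set.seed(101)
  res <- run_dvms(toy$wf, q$centroid, n_walkers = 200, block_steps = 400,
                  tol = 0.08, settle = 1, max_cycles = 4)
  expect_true(res$converged)
  expect_lt(nrow(res$history), 4)  # fixed point: converges immediately
})

test_that("staged truncation finds the analytic crossover of a two-config toy", {
  # two-configuration double well: with a small second coefficient the
  # left well dominates; as the truncation adds the second configuration
  # the right-well site's |Psi| drops below the left's
  toy <- make_toy("double_well_ci", coef = c(1, 0.4))
  lineages <- list(right = toy$sites[[2]], left = toy$sites[[1]])
  st <- staged_truncation_run(toy$wf, schedule = c(1, 2),
                              lineages = lineages,
                              n_walkers = 40, block_steps = 0)
  # direct evaluation oracle at the fixed sites
  wf1 <- truncate_ci(toy$wf, 1)
  expect_equal(st$table$psi_right[1],
               abs(psi_value(wf1, toy$sites[[2]]$x)), tolerance = 1e-10)
  expect_equal(st$table$psi_left[2],
               abs(psi_value(toy$wf, toy$sites[[1]]$x)), tolerance = 1e-10)
  # stage 1 (symmetric): equal values; stage 2: left overtakes right
  expect_equal(st$table$psi_right[1], st$table$psi_left[1],
               tolerance = 1e-10)
  expect_identical(st$crossing_stage, 2L)
  expect_true(all(diff(st$table$completeness) > 0))
  expect_error(staged_truncation_run(toy$wf, c(2, 2), lineages), "schedule")
})

test_that("a schedule of one full-length stage reduces to a plain DVMS block", {
  toy <- make_toy("two_electron_triplet")
  set.seed(103)
  st <- staged_truncation_run(
    toy$wf, schedule = 1,
    lineages = list(main = toy$sites[[1]]),
    n_walkers = 60, block_steps = 200)
  expect_equal(nrow(st$table), 1)
  expect_equal(st$table$completeness, 1.0)
  expect_true(is.finite(st$table$psi_main))
})
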