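# Kekule reference sites, occupancy statistics, kinetics.

.kekule_site <- function(geom) {
  # idealised converged site: the Lewis-like guess is already a clean
  # Kekule arrangement suitable for the construction tests
  x <- lewis_guess_benzene(geom)
  voronoi_site(x, 21, 21, "eclipsed-A")
}

test_that("the four reference sites have the stated structure", {
  geom <- build_benzene()
  base <- .kekule_site(geom)
  sites <- build_reference_sites(base, geom)
  expect_identical(vapply(sites, function(s) s$label, ""),
                   c("eclipsed-A", "staggered-A", "staggered-B",
                     "eclipsed-B"))
  # alpha-rotated site differs from base only in the 9 C-C bonding
  # electrons of the alpha block
  d <- matrix(sites[[2]]$x - sites[[1]]$x, ncol = 3, byrow = TRUE)
  moved <- which(rowSums(d^2) > 1e-12)
  expect_true(all(moved <= 21))
  expect_identical(length(moved), 9L)
  # rotating both spin sets twice by 60 degrees is a symmetry image of
  # the base site: folded distance ~ 0
  s2 <- build_reference_sites(sites[[4]], geom)
  f <- best_fold(s2[[4]]$x, sites[[1]])
  expect_lt(f$sq_distance, 1e-16)
  # the two staggered sites are related by swapping the spin labels
  na <- 21
  swap <- c(sites[[3]]$x[-(1:(3 * na))], sites[[3]]$x[1:(3 * na)])
  f2 <- best_fold(swap, sites[[2]])
  expect_lt(f2$sq_distance, 1e-16)
})

test_that("bond-region counts of a Kekule site alternate 2-1-2-1-2-1", {
  geom <- build_benzene()
  base <- .kekule_site(geom)
  ca <- bond_electron_counts(base, geom, "alpha")
  expect_setequal(unique(ca), c(1L, 2L))
  expect_true(all(abs(diff(c(ca, ca[1]))) == 1))  # strict alternation
  # the alternate Kekule guess gives the complementary assignment
  alt <- voronoi_site(lewis_guess_benzene(geom, kekule = "B"), 21, 21, "B")
  expect_identical(bond_electron_counts(alt, geom, "alpha"), 3L - ca)
})

test_that("ambiguous electron assignment is detected", {
  geom <- build_benzene()
  b <- matrix(rep(geom$xyz[1, ], 2), 2, 3, byrow = TRUE)
  # an electron exactly halfway between a core and a C-H anchor
  b[2, ] <- (geom$xyz[1, ] + (geom$xyz[1, ] + geom$xyz[7, ]) / 2) / 2
  expect_error(classify_benzene_electrons(b, geom), "ambiguous")
})

test_that("count conservation and the all-at-start condition hold on a real trace", {
  toy <- make_toy("double_well_ci", coef = c(1, 0.3))
  set.seed(107)
  tr <- classify_trace(toy$wf, toy$sites, toy$sites[[1]]$x,
                       n_walkers = 30, n_steps = 60)
  expect_true(all(tr$eclipsed + tr$staggered == 30))
  expect_true(all(rowSums(tr$counts) == 30))
  # step 1 is still all in the start site's cell (wells 3 bohr apart)
  expect_identical(unname(tr$counts[1, 1]), 30L)
})

test_that("equilibrium estimator reproduces analytic Markov-chain moments", {
  set.seed(109)
  rate <- 0.005
  W <- 400
  tr <- synthetic_markov_trace(n_walkers = W, n_steps = 2000, rate = rate,
                               p0 = 0.5)
  eq <- equilibrium_occupancy(tr, window = c(501, 2000),
                              decorrelation = 1 / rate)
  # analytic equilibrium: half the walkers in each class, sd sqrt(W)/2
  expect_lt(abs(eq$mean[eq$class == "staggered"] - W / 2),
            3 * eq$se[eq$class == "staggered"])
  expect_true(all(eq$se > 0))
  # constant trace: zero standard error
  trc <- tr
  trc$staggered <- rep(100L, 2000)
  trc$eclipsed <- rep(300L, 2000)
  eqc <- equilibrium_occupancy(trc, window = c(501, 2000))
  expect_equal(eqc$se[eqc$class == "staggered"], 0)
  expect_error(equilibrium_occupancy(tr, window = c(1901, 2000)),
               "window")
})

test_that("the 2-sigma interval calibrates on repeated synthetic traces", {
  set.seed(113)
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    tr <- synthetic_markov_trace(n_walkers = 200, n_steps = 1200,
                                 rate = 0.005, p0 = 0.5)
    eq <- equilibrium_occupancy(tr, window = c(201, 1200),
                                decorrelation = 200)
    m <- eq$mean[eq$class == "staggered"]
    se <- eq$se[eq$class == "staggered"]
    if (abs(m - 100) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("kinetic fit recovers a known relaxation rate", {
  set.seed(127)
  rate <- 0.005  # per-direction crossing rate; relaxation is 2x
  tr <- synthetic_markov_trace(n_walkers = 2000, n_steps = 2000,
                               rate = rate, p0 = 0)
  fit <- fit_kinetics(tr)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$rate_crossing - rate) / rate, 0.1)
  expect_lt(abs(fit$n_eq - 1000) / 1000, 0.05)
  expect_equal(fit$decorrelation_length, 1 / fit$rate_crossing)
  # a trace that starts at equilibrium is unidentifiable
  tr0 <- synthetic_markov_trace(n_walkers = 400, n_steps = 800,
                                rate = 0.005, p0 = 0.5)
  fit0 <- fit_kinetics(tr0)
  expect_false(fit0$identifiable)
})

test_that("block stationarity passes identical blocks and fails shifted ones", {
  set.seed(131)
  tr <- synthetic_markov_trace(n_walkers = 300, n_steps = 2000,
                               rate = 0.01, p0 = 0.5)
  bs <- block_stationarity(tr)
  expect_true(all(bs$pass))
  # inject a gross mean shift
  tr2 <- tr
  tr2$staggered[1501:2000] <- tr2$staggered[1501:2000] + 60L
  bs2 <- block_stationarity(tr2)
  expect_false(all(bs2$pass))
  expect_error(block_stationarity(tr, blocks = list(c(1, 300),
                                                    c(200, 500))),
               "overlap")
})
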