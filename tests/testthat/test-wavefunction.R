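# Orbital evaluation, Slater determinants and CI machinery.

test_that("a normalised s Gaussian has its closed-form value at the centre", {
  a <- 0.8
  basis <- ao_basis(list(list(center = c(0, 0, 0), l = 0L, exps = a,
                              coefs = 1)))
  mo <- list(C = matrix(1), energy = 0, occupation = 1, orig_index = 1,
             label = "occupied")
  wf <- wavefunction(basis, mo, single_determinant(1, 0))
  # N = (2a/pi)^(3/4) for a normalised s primitive
  expect_equal(eval_orbitals(wf, c(0, 0, 0))[1, 1], (2 * a / pi)^0.75,
               tolerance = 1e-12)
  # Gaussian decay: negligible far away
  expect_lt(abs(eval_orbitals(wf, c(50, 0, 0))[1, 1]), 1e-10)
})

test_that("contracted shells equal the hand-summed primitive expansion", {
  exps <- c(1.3, 0.4)
  coefs <- c(0.7, 0.5)
  basis <- ao_basis(list(list(center = c(0.2, -0.1, 0.3), l = 0L,
                              exps = exps, coefs = coefs)))
  mo <- list(C = matrix(1), energy = 0, occupation = 1, orig_index = 1,
             label = "occupied")
  wf <- wavefunction(basis, mo, single_determinant(1, 0))
  p <- c(0.9, 0.4, -0.2)
  r2 <- sum((p - c(0.2, -0.1, 0.3))^2)
  # hand evaluation: normalised primitives, then contracted renormalisation
  pn <- (2 * exps / pi)^0.75
  raw <- coefs * pn
  self <- 0
  for (i in 1:2) for (j in 1:2)
    self <- self + raw[i] * raw[j] * (pi / (exps[i] + exps[j]))^1.5
  hand <- sum(raw / sqrt(self) * exp(-exps * r2))
  expect_equal(eval_orbitals(wf, p)[1, 1], hand, tolerance = 1e-12)
})

test_that("slater_value matches a cofactor-expansion oracle", {
  expect_equal(slater_value(matrix(3.7)), 3.7)
  M2 <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)  # equal rows: Pauli zero
  expect_equal(slater_value(M2), 0)
  set.seed(11)
  for (rep in 1:5) {
    M <- matrix(rnorm(9), 3, 3)
    expect_equal(slater_value(M), cofactor_det(M), tolerance = 1e-12)
  }
  expect_error(slater_value(matrix(1, 2, 3)), "square")
})

.toy3 <- function() {
  # 3 alpha + 2 beta electrons in displaced Gaussians, 2-term CI
  basis <- ao_basis(list(
    list(center = c(-1, 0, 0), l = 0L, exps = 0.6, coefs = 1),
    list(center = c(1, 0.3, 0), l = 0L, exps = 0.5, coefs = 1),
    list(center = c(0, -1, 0.5), l = 1L, exps = 0.4, coefs = 1)))
  mo <- list(C = diag(5), energy = numeric(5), occupation = c(1, 1, 1, 0, 0),
             orig_index = 1:5, label = rep("occupied", 5))
  ci <- ci_expansion(rbind(c(1L, 2L, 3L), c(1L, 2L, 4L)),
                     rbind(c(1L, 2L), c(1L, 3L)), c(0.8, 0.5))
  wavefunction(basis, mo, ci)
}

test_that("psi_value is antisymmetric and matches brute-force antisymmetrisation", {
  wf <- .toy3()
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(15, sd = 1.2)
    v <- psi_value(wf, x)
    # same-spin transpositions flip the sign exactly
    expect_equal(psi_value(wf, swap_electrons(x, 1, 3)), -v,
                 tolerance = 1e-12)
    expect_equal(psi_value(wf, swap_electrons(x, 4, 5)), -v,
                 tolerance = 1e-12)
    # even permutation (3-cycle on alpha) leaves psi unchanged
    x3 <- permute_block(x, c(2L, 3L, 1L))
    expect_equal(psi_value(wf, x3), v, tolerance = 1e-12)
    # independent oracle: relative error below 1e-10
    expect_lt(abs(v - brute_force_psi(wf, x)),
              1e-10 * max(abs(v), 1e-10))
  }
})

test_that("a 1+1 electron single determinant factorises into orbitals", {
  basis <- ao_basis(list(
    list(center = c(-1, 0, 0), l = 0L, exps = 0.6, coefs = 1),
    list(center = c(1, 0, 0), l = 0L, exps = 0.5, coefs = 1)))
  mo <- list(C = diag(2), energy = c(0, 0), occupation = c(1, 1),
             orig_index = 1:2, label = c("occupied", "occupied"))
  ci <- ci_expansion(matrix(1L), matrix(2L), 1)
  wf <- wavefunction(basis, mo, ci)
  x <- c(0.3, 0.1, -0.2, -0.4, 0.7, 0.05)
  mo_at <- eval_orbitals(wf, matrix(x, ncol = 3, byrow = TRUE))
  expect_equal(psi_value(wf, x), mo_at[1, 1] * mo_at[2, 2],
               tolerance = 1e-12)
})

test_that("global phases of orbitals or coefficients do not change |Psi|", {
  wf <- .toy3()
  set.seed(31)
  x <- rnorm(15)
  v <- abs(psi_value(wf, x))
  # flipping an orbital's phase must be compensated by flipping the sign
  # of every CI coefficient whose determinant occupies it an odd number
  # of times; for orbital 3 (occupied by alpha term 1 and beta term 2)
  # both terms hold it exactly once
  wf_flip <- wf
  wf_flip$mo$C[, 3] <- -wf_flip$mo$C[, 3]
  wf_flip$ci$coef <- wf_flip$ci$coef * c(-1, -1)
  expect_equal(abs(psi_value(wf_flip, x)), v, tolerance = 1e-12)
  # orbital 1 is occupied once per spin in every term: flips cancel and
  # no coefficient adjustment is needed
  wf_flip1 <- wf
  wf_flip1$mo$C[, 1] <- -wf_flip1$mo$C[, 1]
  expect_equal(abs(psi_value(wf_flip1, x)), v, tolerance = 1e-12)
  wf_neg <- wf
  wf_neg$ci$coef <- -wf_neg$ci$coef        # flip the CI vector's phase
  expect_equal(abs(psi_value(wf_neg, x)), v, tolerance = 1e-12)
})

test_that("truncation keeps degenerate groups and is idempotent", {
  occ_a <- matrix(c(1L, 2L, 3L, 4L), 4, 1)
  occ_b <- matrix(c(1L, 1L, 1L, 1L), 4, 1)
  ci <- ci_expansion(occ_a, occ_b, c(0.9, 0.3, 0.3, 0.1))
  t2 <- truncate_ci(ci, 2)
  expect_length(t2$coef, 3)  # the tied 0.3 pair comes as a set
  expect_identical(truncate_ci(ci, 4), ci)
  expect_error(truncate_ci(ci, 0), "n_configs")
  # chained truncation equals direct truncation to the smaller length
  t31 <- truncate_ci(truncate_ci(ci, 3), 1)
  expect_equal(t31, truncate_ci(ci, 1))
  expect_equal(ci_group_sizes(ci), c(1, 3, 4))
})

test_that("completeness is the cumulative squared coefficient weight", {
  occ_a <- matrix(1:4, 4, 1)
  occ_b <- matrix(rep(1L, 4), 4, 1)
  coef <- c(0.9, sqrt(1 - 0.81 - 0.02), 0.1, 0.1)
  ci <- ci_expansion(occ_a, occ_b, coef)
  expect_equal(ci_completeness(ci, ci), 1.0)
  expect_equal(ci_completeness(ci, truncate_ci(ci, 1)), 0.81,
               tolerance = 1e-12)
  # monotone non-decreasing along the truncation ladder
  comp <- vapply(seq_along(coef), function(n)
    ci_completeness(ci, truncate_ci(ci, n)), numeric(1))
  expect_true(all(diff(comp) >= 0))
  expect_equal(comp[length(comp)], 1.0)
  # foreign term rejected
  bad <- ci_expansion(matrix(9L), matrix(1L), 1)
  expect_error(ci_completeness(ci, bad), "absent")
})
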