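# Independent oracles used across the suite.  These deliberately take the
# slow, explicit route (permutation sums, cofactor expansions, exhaustive
# enumeration, grid quadrature) so they share no code with the fast paths
# they check.

# all permutations of 1..n as a matrix (rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    m <- cbind(k, sub + (sub >= k))
    out <- rbind(out, m)
  }
  out
}

# parity by explicit bubble-sort swap counting
bubble_parity <- function(p) {
  p <- as.integer(p)
  swaps <- 0L
  repeat {
    done <- TRUE
    for (i in seq_len(length(p) - 1)) {
      if (p[i] > p[i + 1]) {
        tmp <- p[i]; p[i] <- p[i + 1]; p[i + 1] <- tmp
        swaps <- swaps + 1L
        done <- FALSE
      }
    }
    if (done) break
  }
  if (swaps %% 2L == 0L) 1L else -1L
}

# determinant by recursive cofactor expansion along the first row
cofactor_det <- function(M) {
  n <- nrow(M)
  if (n == 1) return(M[1, 1])
  s <- 0
  for (j in seq_len(n))
    s <- s + (-1)^(1 + j) * M[1, j] *
      cofactor_det(M[-1, -j, drop = FALSE])
  s
}

# Psi by brute-force antisymmetrisation: explicit signed sum over all
# like-spin permutations of a product of occupied orbitals (practical for
# <= 3 electrons per spin)
brute_force_psi <- function(wf, x) {
  na <- wf$n_alpha
  nb <- wf$n_beta
  pts <- matrix(x, ncol = 3, byrow = TRUE)
  mo <- eval_orbitals(wf, pts)   # N x nmo
  tot <- 0
  for (t in seq_along(wf$ci$coef)) {
    da <- 0
    if (na > 0) {
      occ <- wf$ci$occ_alpha[t, ]
      P <- all_perms(na)
      for (r in seq_len(nrow(P))) {
        prod_ <- 1
        for (i in seq_len(na)) prod_ <- prod_ * mo[P[r, i], occ[i]]
        da <- da + bubble_parity(P[r, ]) * prod_
      }
    } else da <- 1
    db <- 0
    if (nb > 0) {
      occ <- wf$ci$occ_beta[t, ]
      P <- all_perms(nb)
      for (r in seq_len(nrow(P))) {
        prod_ <- 1
        for (i in seq_len(nb)) prod_ <- prod_ * mo[na + P[r, i], occ[i]]
        db <- db + bubble_parity(P[r, ]) * prod_
      }
    } else db <- 1
    tot <- tot + wf$ci$coef[t] * da * db
  }
  tot
}

# exhaustive best fold: minimum squared distance over all per-spin
# relabellings (site slot j <- electron perm[j])
exhaustive_fold <- function(x, site_x, na, nb) {
  pts <- matrix(x, ncol = 3, byrow = TRUE)
  st <- matrix(site_x, ncol = 3, byrow = TRUE)
  best_block <- function(from, n) {
    if (n == 0) return(list(cost = 0, perm = integer()))
    P <- all_perms(n)
    costs <- apply(P, 1, function(p)
      sum((pts[from + p, , drop = FALSE] - st[from + seq_len(n), ,
                                              drop = FALSE])^2))
    k <- which.min(costs)
    list(cost = costs[k], perm = P[k, ])
  }
  a <- best_block(0, na)
  b <- best_block(na, nb)
  list(sq_distance = a$cost + b$cost, alpha_perm = a$perm,
       beta_perm = b$perm,
       parity = bubble_parity(c(a$perm, b$perm + na)))
}

# swap two same-spin electron coordinate triples in a configuration
swap_electrons <- function(x, i, j) {
  xi <- (3 * i - 2):(3 * i)
  xj <- (3 * j - 2):(3 * j)
  tmp <- x[xi]; x[xi] <- x[xj]; x[xj] <- tmp
  x
}

# apply a permutation to one spin block of a configuration
# (slot j of the result <- electron perm[j] of the block)
permute_block <- function(x, perm, offset = 0) {
  out <- x
  for (j in seq_along(perm)) {
    out[(3 * (offset + j) - 2):(3 * (offset + j))] <-
      x[(3 * (offset + perm[j]) - 2):(3 * (offset + perm[j]))]
  }
  out
}
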