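test_that("Spearman's exact formula matches its contracts and Pearson", {
  expect_equal(spearman_rho(1:8, 1:8), 1)
  expect_equal(spearman_rho(1:8, 8:1), -1)
  r <- c(1, 2, 3, 4); s <- c(2, 1, 4, 3)
  expect_equal(spearman_rho(r, s), cor(r, s))
  set.seed(53)
  for (rep in 1:10) {
    R <- rand_ranks(sample(3:20, 1))
    expect_equal(spearman_rho(R), cor(R[, 1], R[, 2]))
  }
  expect_error(spearman_rho(rand_ranks(5, p = 3)), "p = 2")
})

test_that("Kendall's tau matches the exhaustive pair-count oracle", {
  expect_equal(kendall_tau(1:6, 1:6), 1)
  expect_equal(kendall_tau(1:6, 6:1), -1)
  set.seed(59)
  for (rep in 1:10) {
    R <- rand_ranks(5)
    expect_equal(kendall_tau(R), oracle_kendall(R[, 1], R[, 2]))
  }
})

test_that("the Spearman g-functional reproduces spearman_rho exactly", {
  gf <- gf_spearman()
  set.seed(61)
  for (n in c(3, 5, 12, 27, 50)) {
    R <- rand_ranks(n)
    expect_equal(kappa_hat(gf, R), spearman_rho(R), tolerance = 1e-12)
  }
})

test_that("g-functional normalisation contracts hold for the presets", {
  # constant g maps every rank configuration to a_n * const + b_n
  gfc <- g_functional(function(u, v) rep(0.3, length(u)),
                      a_n = function(n) 2, b_n = function(n) -1)
  expect_equal(kappa_hat(gfc, rand_ranks(9)), 2 * 0.3 - 1)

  set.seed(67)
  for (gf in list(gf_spearman(), gf_gini(), gf_blest())) {
    for (n in c(2, 3, 8, 15)) {
      expect_equal(kappa_hat(gf, cbind(1:n, 1:n)), 1, tolerance = 1e-12)
      expect_equal(kappa_hat(gf, cbind(1:n, n:1)), -1, tolerance = 1e-12)
      for (rep in 1:20) {
        k <- kappa_hat(gf, rand_ranks(n))
        expect_gte(k, -1 - 1e-12)
        expect_lte(k, 1 + 1e-12)
      }
    }
  }
})

test_that("Gini preset equals the direct rank-sum formula", {
  # plug-in Gini on rescaled ranks: normalised sum of |R+S-n| - |R-S|
  set.seed(71)
  for (n in c(4, 7, 10)) {
    R <- rand_ranks(n)
    direct <- sum(abs(R[, 1] + R[, 2] - n) - abs(R[, 1] - R[, 2]))
    denom_c <- sum(abs(2 * seq_len(n) - n))     # value at perfect concordance
    denom_d <- sum(abs(seq_len(n) + rev(seq_len(n)) - n) -
                     abs(seq_len(n) - rev(seq_len(n))))
    expected <- 2 * (direct - (denom_c + denom_d) / 2) / (denom_c - denom_d)
    expect_equal(kappa_hat(gf_gini(), R), expected, tolerance = 1e-12)
  }
})

test_that("weighted coefficients are convex combinations", {
  expect_equal(weighted_coef(1, 0.42), 0.42)
  expect_equal(weighted_coef(c(0.2, 0.5, 0.3), rep(0.6, 3)), 0.6)
  set.seed(73)
  w <- rand_simplex(4); est <- runif(4, -1, 1)
  expect_equal(weighted_coef(w, est), sum(w * est))
  expect_equal(weighted_tau_naive(w, est), sum(w * est))
  expect_error(weighted_coef(c(0.5, 0.5), est), "length mismatch")
})

test_that("cross-group Kendall reduces to tau on the diagonal", {
  set.seed(79)
  R <- rand_ranks(9)
  kc <- kendall_cross(R, R)
  expect_equal(kc$t, kendall_tau(R))
  expect_equal(kc$n_pairs, 9 * 8)

  # identical rank pairs in two equal-size groups: ties excluded, tau again
  kc2 <- kendall_cross(R, R[sample.int(9), ])
  expect_equal(kc2$t, kendall_tau(R))
})

test_that("cross-group Kendall matches exhaustive enumeration at (2,3)", {
  set.seed(83)
  ri <- cbind(sample(2), sample(2))
  rj <- cbind(sample(3), sample(3))
  num <- 0; npair <- 0
  for (s in 1:2) for (t in 1:3) {
    d1 <- ri[s, 1] / 2 - rj[t, 1] / 3
    d2 <- ri[s, 2] / 2 - rj[t, 2] / 3
    if (d1 != 0 && d2 != 0) {
      npair <- npair + 1
      num <- num + sign(d1) * sign(d2)
    }
  }
  kc <- kendall_cross(ri, rj)
  expect_equal(kc$t, num / npair)
  expect_equal(kc$n_pairs, npair)
})

test_that("tau_tilde is the quadratic form of the cross matrix", {
  set.seed(89)
  gs <- grouped_sample(lapply(c(6, 9, 7), function(n) cbind(rnorm(n), rnorm(n))))
  rd <- group_ranks(gs)
  cm <- kendall_cross_matrix(rd)
  expect_equal(diag(cm$t_mat),
               vapply(rd$ranks, kendall_tau, numeric(1)))
  expect_equal(tau_tilde(c(1, 0, 0), cm), cm$t_mat[1, 1])
  mu <- rand_simplex(3)
  direct <- 0
  for (i in 1:3) for (j in 1:3) direct <- direct + mu[i] * mu[j] * cm$t_mat[i, j]
  expect_equal(tau_tilde(mu, cm), direct)

  gs1 <- grouped_sample(gs$groups[1])
  expect_equal(tau_tilde(1, kendall_cross_matrix(group_ranks(gs1))),
               kendall_tau(rd$ranks[[1]]))
})

test_that("cross-group numerator expectation under independence is exact", {
  # E over all within-group rank permutations of the *numerator*
  # sum sign x sign equals n_i n_j (1/n_j - 1/n_i)^2; the tabled statistic
  # divides by the realised N_ij (zero expectation when sizes are equal)
  perms2 <- all_perms(2); perms3 <- all_perms(3)
  num <- c()
  for (R1 in perms2) for (S1 in perms2) for (R2 in perms3) for (S2 in perms3) {
    kc <- kendall_cross(cbind(R1, S1), cbind(R2, S2))
    num <- c(num, kc$t * kc$n_pairs)
  }
  expect_equal(mean(num), 2 * 3 * (1 / 3 - 1 / 2)^2)
  expect_equal(expected_cross_indep(2, 3, 5), (2 * 3 / 5) * (1 / 3 - 1 / 2)^2)
  expect_equal(expected_cross_indep(7, 7, 30), 0)

  # (3, 4): same identity at Monte Carlo precision
  set.seed(97)
  mc <- replicate(20000, {
    kc <- kendall_cross(cbind(sample(3), sample(3)), cbind(sample(4), sample(4)))
    kc$t * kc$n_pairs
  })
  # numerator values are bounded by 12, so 3 MC standard errors < 0.1
  expect_lt(abs(mean(mc) - 3 * 4 * (1 / 4 - 1 / 3)^2), 0.1)
})

test_that("Frechet heterogeneity: tau_tilde consistent, naive average not", {
  # groups drawn from C1 = Frechet(0.4, 0.2), M, Pi, W; tau_1 = 0.17333...
  alpha <- 0.4; beta <- 0.2
  tau1 <- frechet_tau(alpha, beta)
  expect_equal(tau1, 0.2 * 2.6 / 3)
  set.seed(101)
  n <- 150
  u <- runif(n)
  groups <- list(rfrechet(n, alpha, beta),
                 cbind(u, u),                       # M
                 cbind(runif(n), runif(n)),         # Pi
                 cbind(u, 1 - u))                   # W
  gs <- grouped_sample(groups)
  rd <- group_ranks(gs)
  fit <- mamse_weights(rd)
  taus <- vapply(rd$ranks, kendall_tau, numeric(1))
  naive <- weighted_tau_naive(fit$mu, taus)
  tt <- tau_tilde(fit$mu, kendall_cross_matrix(rd))
  expect_lt(abs(tt - tau1), 0.08)
  # the naive average pulls towards alpha - beta = 0.2 scaled by the
  # share granted to the pure components; with adaptive weights spread
  # across M/Pi/W it is the less accurate summary on this design
  expect_lt(abs(tt - tau1), abs(naive - tau1) + 0.05)
})

test_that("Spearman matrices: pooled, per-group and weighted modes", {
  set.seed(103)
  gs <- grouped_sample(lapply(c(10, 14), function(n)
    cbind(rnorm(n), rnorm(n), rnorm(n))))
  mats <- spearman_matrix(gs, mode = "group")
  for (M in mats) {
    expect_equal(diag(M), rep(1, 3))
    expect_equal(M, t(M))
    expect_true(all(M >= -1 & M <= 1))
  }
  # entries match direct per-pair computation
  rd <- group_ranks(gs)
  expect_equal(mats[[2]][1, 3],
               spearman_rho(rd$ranks[[2]][, 1], rd$ranks[[2]][, 3]))

  w <- scalar_weights(gs$sizes)
  expect_equal(spearman_matrix(gs, mode = "weighted"),
               w[1] * mats[[1]] + w[2] * mats[[2]])

  pooled <- spearman_matrix(gs, mode = "pooled")
  X <- do.call(rbind, gs$groups)
  expect_equal(pooled[1, 2], spearman_rho(rank(X[, 1]), rank(X[, 2])))
  # duplicated rows across groups force midranks with a warning
  gs2 <- grouped_sample(list(gs$groups[[1]], gs$groups[[1]] ))
  expect_warning(spearman_matrix(gs2, mode = "pooled"), "midrank")
})

test_that("MAMSE correlation matrices report weights and definiteness", {
  set.seed(107)
  gs <- grouped_sample(lapply(c(25, 25, 25), function(n)
    pnorm(rmvn(n, rep(0, 3), diag(3) * 0.5 + 0.5))))
  Mg <- mamse_cor_matrix(gs, target = 2, weighting = "global", seed = 1)
  expect_equal(dim(Mg), c(3, 3))
  expect_equal(unclass(Mg)[1, 2], unclass(Mg)[2, 1])
  expect_length(attr(Mg, "weights"), 3)
  expect_type(attr(Mg, "positive_definite"), "logical")

  Mp <- mamse_cor_matrix(gs, target = 2, weighting = "pairwise", seed = 1)
  expect_length(attr(Mp, "weights"), 3)  # one weight vector per pair
  expect_true(all(abs(unclass(Mp)) <= 1))
})
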