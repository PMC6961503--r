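test_that("Clayton sampler hits its Kendall tau and uniform margins", {
  u <- rclayton(5000, theta = 2, seed = 151)
  expect_equal(dim(u), c(5000, 2))
  expect_true(all(u > 0 & u <= 1))
  # tau = theta / (theta + 2) = 0.5; MC se of tau-hat ~ 0.01
  expect_lt(abs(cor(u[, 1], u[, 2], method = "kendall") - 0.5), 0.04)

  near0 <- rclayton(5000, theta = 1e-9, seed = 3)
  expect_lt(abs(cor(near0[, 1], near0[, 2], method = "kendall")), 0.04)

  neg <- rclayton(5000, theta = -0.6, seed = 5)
  expect_lt(cor(neg[, 1], neg[, 2], method = "kendall"), -0.2)

  expect_gt(suppressWarnings(ks.test(u[, 2], "punif")$p.value), 0.001)

  set.seed(157)
  a <- rclayton(10, 1.3, seed = 7); b <- rclayton(10, 1.3, seed = 7)
  expect_identical(a, b)
})

test_that("Clayton CDF and Spearman calibration are mutually consistent", {
  U <- cbind(c(0.3, 0.5, 1), c(0.4, 0.5, 1))
  expect_equal(clayton_cdf(U, 1e-15), U[, 1] * U[, 2])
  expect_equal(clayton_cdf(cbind(1, 0.37), 3), 0.37)
  # theta -> 0 as rho -> 0
  expect_lt(abs(clayton_theta(0.01)), 0.1)
  expect_error(clayton_theta(0), "nonzero")

  # round trip: empirical Spearman of a large calibrated sample
  th <- clayton_theta(0.5)
  u <- rclayton(50000, th, seed = 163)
  expect_lt(abs(cor(u[, 1], u[, 2], method = "spearman") - 0.5), 0.02)

  thn <- clayton_theta(-0.4)
  expect_true(thn > -1 && thn < 0)
  un <- rclayton(50000, thn, seed = 167)
  expect_lt(abs(cor(un[, 1], un[, 2], method = "spearman") + 0.4), 0.02)
})

test_that("Frechet-family sampler matches its closed-form tau", {
  expect_equal(kendall_tau(apply(rfrechet(100, 1, 0, seed = 1), 2, rank)), 1)
  expect_equal(kendall_tau(apply(rfrechet(100, 0, 1, seed = 2), 2, rank)), -1)
  u <- rfrechet(20000, 0.4, 0.2, seed = 173)
  expect_lt(abs(cor(u[, 1], u[, 2], method = "kendall") -
                  frechet_tau(0.4, 0.2)), 0.025)
  expect_gt(suppressWarnings(ks.test(u[, 1], "punif")$p.value), 0.001)
  expect_error(rfrechet(10, 0.8, 0.5), "alpha")

  # CDF mixes the three Frechet bounds
  U <- cbind(c(0.2, 0.7), c(0.9, 0.6))
  expect_equal(frechet_cdf(U, 0.4, 0.2),
               0.4 * pmin(U[, 1], U[, 2]) + 0.4 * U[, 1] * U[, 2] +
                 0.2 * pmax(U[, 1] + U[, 2] - 1, 0))
})

test_that("MVN sampler recovers moments and Gaussian-copula Spearman", {
  x <- rmvn(50000, c(2, -1), diag(2), seed = 179)
  expect_lt(max(abs(colMeans(x) - c(2, -1))), 0.03)
  expect_lt(abs(cor(x[, 1], x[, 2])), 0.02)

  r <- 0.6
  y <- rmvn(50000, c(0, 0), matrix(c(1, r, r, 1), 2), seed = 181)
  expect_lt(abs(cor(y[, 1], y[, 2], method = "spearman") - gauss_spearman(r)),
            0.01)
})

test_that("piecewise-uniform sampler interpolates the tabulated quantiles", {
  lev <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  val <- c(400, 545, 819, 1220, 1685)
  x <- rpiecewise_unif(40000, lev, val, seed = 191)
  expect_true(all(x >= 0 & x <= 2 * 1685))
  q <- quantile(x, lev)
  expect_lt(max(abs(q - val) / val), 0.03)
  # mean equals the trapezoid integral of the inverse CDF
  knots <- c(0, val, 2 * 1685); probs <- c(0, lev, 1)
  tru <- sum(diff(probs) * (head(knots, -1) + tail(knots, -1)) / 2)
  expect_lt(abs(mean(x) - tru) / tru, 0.01)
  expect_error(rpiecewise_unif(5, lev, rev(val)), "increasing")
})

test_that("confounded scenarios produce spurious pooled correlation", {
  sc <- scenario_salary_height()
  set.seed(193)
  gs <- generate_scenario(sc)
  expect_equal(gs$sizes, c(150, 150), ignore_attr = TRUE)
  stats <- replicate(25, {
    g <- generate_scenario(sc)
    rd <- group_ranks(g)
    c(max(abs(vapply(rd$ranks, spearman_rho, numeric(1)))),
      spearman_rho(apply(do.call(rbind, g$groups), 2, rank)))
  })
  # within-group independence, but group-shifted marginals push the pooled
  # coefficient up on average
  expect_lt(mean(stats[1, ]), 0.2)
  expect_gt(mean(stats[2, ]), 0.05)

  a <- generate_scenario(sc, seed = 3)
  b <- generate_scenario(sc, seed = 3)
  expect_identical(a$groups, b$groups)
})

test_that("scenario copula families drive within-group dependence", {
  sc <- confounded_scenario(list(
    list(n = 4000, copula = list(family = "clayton", rho = 0.5),
         margins = list(list(type = "uniform"), list(type = "uniform"))),
    list(n = 4000, copula = list(family = "gaussian", r = -0.5),
         margins = list(list(type = "normal", mean = 3, sd = 2),
                        list(type = "uniform")))))
  gs <- generate_scenario(sc, seed = 197)
  rd <- group_ranks(gs)
  expect_lt(abs(spearman_rho(rd$ranks[[1]]) - 0.5), 0.05)
  expect_lt(abs(spearman_rho(rd$ranks[[2]]) - gauss_spearman(-0.5)), 0.05)
})

test_that("iris MVN parameters match per-species moments", {
  pr <- iris_mvn_params()
  expect_named(pr, c("setosa", "versicolor", "virginica"))
  ir <- datasets::iris
  expect_equal(unname(pr$versicolor$mean),
               unname(colMeans(ir[ir$Species == "versicolor", 1:4])))
  gs <- riris_mvn(c(30, 30, 30), seed = 199)
  expect_equal(gs$sizes, c(30, 30, 30), ignore_attr = TRUE)
  expect_equal(gs$p, 4)
})
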