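test_that("within-group ranks follow the definition and reject ties", {
  gs <- grouped_sample(list(cbind(c(3.1, 1.2, 2.0))))
  expect_equal(group_ranks(gs)$ranks[[1]][, 1], c(3, 1, 2))

  # sorted columns rank 1..n in every group
  gs2 <- grouped_sample(list(cbind(sort(rnorm(6))), cbind(sort(rnorm(9)))))
  rd <- group_ranks(gs2)
  expect_equal(rd$ranks[[1]][, 1], 1:6)
  expect_equal(rd$ranks[[2]][, 1], 1:9)

  gs3 <- grouped_sample(list(cbind(c(1, 2, 2), c(1, 2, 3))),
                        labels = "dup")
  expect_error(group_ranks(gs3), "ties in group 'dup', column 1")
  expect_silent(rd3 <- group_ranks(gs3, ties = "midrank"))
  expect_equal(rd3$ranks[[1]][, 1], c(1, 2.5, 2.5))
})

test_that("grouped_sample validates its invariants", {
  expect_error(grouped_sample(list(cbind(1))), "fewer than 2")
  expect_error(grouped_sample(list(cbind(1:3), cbind(1:3, 4:6))),
               "same number of columns")
  expect_error(grouped_sample(list(cbind(c(1, NA, 3)))), "missing")
  expect_error(grouped_sample(data.frame(x = 1:4)), "group")
})

test_that("empirical copula evaluation matches the indicator definition", {
  ec <- empirical_copula(cbind(1:2, 1:2))
  expect_equal(cop_eval(ec, c(1, 1)), 1)
  expect_equal(cop_eval(ec, c(0.5, 0.5)), 0.5)
  expect_equal(cop_eval(ec, c(0.49, 1)), 0)
  expect_error(cop_eval(ec, c(1.2, 0.5)), "\\[0,1\\]")

  # n = 4 random ranks vs the exhaustive indicator-count oracle
  set.seed(101)
  for (rep in 1:5) {
    R <- rand_ranks(4)
    ec4 <- empirical_copula(R)
    U <- matrix(runif(20), 10, 2)
    expect_equal(cop_eval(ec4, U),
                 apply(U, 1, function(u) oracle_ecop(R, 4, u)))
  }
})

test_that("vectorised evaluation equals pointwise evaluation", {
  set.seed(7)
  ec <- empirical_copula(rand_ranks(9, p = 3L))
  U <- matrix(runif(30), 10, 3)
  expect_identical(cop_eval(ec, U),
                   vapply(seq_len(10), function(i) cop_eval(ec, U[i, ]),
                          numeric(1)))
})

test_that("exact margins: C(a/n, 1) = a/n by rank construction", {
  set.seed(11)
  n <- 17
  ec <- empirical_copula(rand_ranks(n))
  for (a in seq_len(n)) {
    expect_identical(cop_eval(ec, c(a / n, 1)), a / n)
    expect_identical(cop_eval(ec, c(1, a / n)), a / n)
  }
})

test_that("monotonicity increments obey the rank-increment bound", {
  # 0 <= C(u) - C(v) <= sum ceil(n (u_l - v_l)) / n for u >= v
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    p <- sample(2:3, 1)
    ec <- empirical_copula(rand_ranks(n, p))
    v <- runif(p)
    u <- pmin(v + runif(p, 0, 1 - v * 0), 1)
    u <- pmax(u, v)
    d <- cop_eval(ec, u) - cop_eval(ec, v)
    expect_gte(d, 0)
    expect_lte(d, sum(ceiling(n * (u - v))) / n + 1e-12)
  }
})

test_that("mixtures are convex combinations bounded by their components", {
  set.seed(17)
  comps <- lapply(1:3, function(i) empirical_copula(rand_ranks(8)))
  w <- rand_simplex(3)
  mx <- mixture_copula(comps, w)
  U <- matrix(runif(20), 10, 2)
  vals <- vapply(comps, function(cc) cop_eval(cc, U), numeric(10))
  expect_equal(cop_eval(mx, U), drop(vals %*% w))
  expect_true(all(cop_eval(mx, U) >= apply(vals, 1, min) - 1e-12))
  expect_true(all(cop_eval(mx, U) <= apply(vals, 1, max) + 1e-12))

  # single component with weight 1 reduces to the component
  expect_equal(cop_eval(mixture_copula(comps[1], 1), U),
               cop_eval(comps[[1]], U))
  # identical components: any weights give the component value
  same <- mixture_copula(comps[c(2, 2, 2)], c(0.6, 0.3, 0.1))
  expect_equal(cop_eval(same, U), cop_eval(comps[[2]], U))
  expect_error(mixture_copula(comps, c(0.5, 0.5)), "length mismatch")
})

test_that("evaluation point schemes follow their contracts", {
  g22 <- make_eval_points("grid", 2, p = 2)
  expect_equal(nrow(g22$points), 4)
  expect_equal(sort(apply(g22$points, 1, paste, collapse = ",")),
               sort(c("0.5,0.5", "0.5,1", "1,0.5", "1,1")))

  n1 <- 13
  expect_equal(nrow(make_eval_points("grid", n1, p = 2)$points), n1^2)

  mc1 <- make_eval_points("mc", 50, p = 3, seed = 42)
  mc2 <- make_eval_points("mc", 50, p = 3, seed = 42)
  expect_identical(mc1$points, mc2$points)

  expect_error(make_eval_points("grid", 1000, p = 5), "Monte Carlo")
})

test_that("integrated absolute error and sup distance behave as averages", {
  set.seed(19)
  ec <- empirical_copula(rand_ranks(6))
  pts <- make_eval_points("mc", 40, p = 2, seed = 3)
  self <- function(U) cop_eval(ec, U)
  expect_equal(integral_abs_error(ec, self, pts), 0)
  expect_equal(integral_abs_error(ec, function(U) self(U) - 0.07, pts), 0.07)
  expect_equal(sup_distance(ec, self, pts), 0)

  other <- empirical_copula(rand_ranks(6))
  U <- pts$points
  expect_equal(sup_distance(ec, other, pts),
               max(abs(cop_eval(ec, U) - cop_eval(other, U))))
  expect_equal(sup_distance(ec, other, U[3, , drop = FALSE]),
               abs(cop_eval(ec, U[3, ]) - cop_eval(other, U[3, ])))
})

test_that("coarse-grid integral error agrees with a refined grid", {
  # Lipschitz bound: both the empirical and the true copula move by at most
  # p/g (+ rank granularity p/n) across one grid cell
  set.seed(23)
  n <- 12
  ec <- empirical_copula(rand_ranks(n))
  truth <- function(U) U[, 1] * U[, 2]
  coarse <- integral_abs_error(ec, truth, make_eval_points("grid", 10, 2))
  fine <- integral_abs_error(ec, truth, make_eval_points("grid", 80, 2))
  bound <- 2 * (2 / 10 + 1 / n) + 2 * (2 / 80 + 1 / n)
  expect_lt(abs(coarse - fine), bound)
})

test_that("empirical copulas converge to the truth as n grows", {
  set.seed(29)
  theta <- 2
  truth <- clayton_copula(theta)
  pts <- make_eval_points("mc", 200, p = 2, seed = 5)
  med <- vapply(c(25, 100, 400), function(n) {
    median(replicate(15, {
      ec <- empirical_copula(apply(rclayton(n, theta), 2, rank))
      sup_distance(ec, truth, pts)
    }))
  }, numeric(1))
  expect_true(med[2] < med[1])
  expect_true(med[3] < med[2])
})

test_that("delimited input round-trips and rejects missing values", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_grouped_fixture(path)
  gs <- read_grouped(path, group = "g")
  expect_equal(gs$labels, c("a", "b"))
  expect_equal(gs$sizes, c(a = 12L, b = 12L), ignore_attr = TRUE)
  expect_equal(gs$groups[[1]][, 1], df$x[df$g == "a"])

  df$x[3] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_grouped(path, group = "g"), "missing")
})
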