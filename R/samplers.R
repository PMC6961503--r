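#' Clayton copula: sampling, CDF, Spearman calibration
#'
#' The bivariate Clayton copula
#' \eqn{C_\theta(u, v) = \max(u^{-\theta} + v^{-\theta} - 1, 0)^{-1/\theta}}
#' for \eqn{\theta \in (-1, \infty) \setminus \{0\}}, with Kendall's
#' \eqn{\tau = \theta / (\theta + 2)}. Negative dependence is obtained with
#' \eqn{\theta \in (-1, 0)} (the family reaches the lower Frechet bound at
#' \eqn{\theta = -1}). Sampling uses conditional inversion of
#' \eqn{C_{2|1}}.
#'
#' @param n number of pairs.
#' @param theta dependence parameter (0 is treated as independence).
#' @param seed optional RNG seed.
#' @return `rclayton`: an `n x 2` matrix of uniforms.
#' @examples
#' u <- rclayton(500, theta = 2, seed = 1)
#' @export
rclayton <- function(n, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  w <- runif(n)
  if (abs(theta) < 1e-12) return(cbind(u, w, deparse.level = 0))
  inner <- (w^(-theta / (1 + theta)) - 1) * u^(-theta) + 1
  v <- pmax(inner, 1e-300)^(-1 / theta)
  cbind(u, pmin(pmax(v, 0), 1), deparse.level = 0)
}

#' @rdname rclayton
#' @param U a `G x 2` matrix of points.
#' @return `clayton_cdf`: copula values at the rows of `U`.
#' @export
clayton_cdf <- function(U, theta) {
  U <- as.matrix(U)
  if (abs(theta) < 1e-12) return(U[, 1] * U[, 2])
  pmax(U[, 1]^(-theta) + U[, 2]^(-theta) - 1, 0)^(-1 / theta)
}

#' @rdname rclayton
#' @return `clayton_copula`: a function of a point matrix, suitable as the
#'   `truth` argument of [integral_abs_error()].
#' @export
clayton_copula <- function(theta) function(U) clayton_cdf(U, theta)

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch)
gauss_legendre_01 <- function(k) {
  j <- seq_len(k - 1)
  b <- j / sqrt(4 * j^2 - 1)
  A <- matrix(0, k, k)
  A[cbind(j, j + 1)] <- b
  A[cbind(j + 1, j)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(nodes = (e$values + 1) / 2, weights = e$vectors[1, ]^2)
}

#' @rdname rclayton
#' @return `clayton_spearman`: the population Spearman correlation
#'   \eqn{12 \int C_\theta(u, v)\,du\,dv - 3}, computed by tensor
#'   Gauss-Legendre quadrature.
#' @export
clayton_spearman <- function(theta) {
  gl <- gauss_legendre_01(48L)
  U <- as.matrix(expand.grid(gl$nodes, gl$nodes))
  w <- as.vector(outer(gl$weights, gl$weights))
  12 * sum(w * clayton_cdf(U, theta)) - 3
}

#' @rdname rclayton
#' @param rho_target desired Spearman correlation in `(-1, 1)`, nonzero.
#' @return `clayton_theta`: the parameter whose population Spearman equals
#'   `rho_target` (bisection to 1e-6).
#' @export
clayton_theta <- function(rho_target) {
  if (rho_target <= -1 || rho_target >= 1 || rho_target == 0)
    stop("target Spearman correlation must lie in (-1, 1) and be nonzero")
  f <- function(th) clayton_spearman(th) - rho_target
  iv <- if (rho_target > 0) c(1e-6, 100) else c(-1 + 1e-6, -1e-6)
  if (f(iv[1]) * f(iv[2]) > 0)
    stop("target Spearman correlation ", rho_target,
         " unattainable within the Clayton family")
  uniroot(f, interval = iv, tol = 1e-6)$root
}

#' Frechet-family copula sampler
#'
#' Mixture \eqn{C_{\alpha,\beta} = \alpha M + (1-\alpha-\beta)\Pi + \beta W}
#' of perfect concordance (M), independence (Pi) and perfect discordance
#' (W), with \eqn{\alpha, \beta \ge 0}, \eqn{\alpha + \beta \le 1}. Its
#' Kendall tau is \eqn{(\alpha - \beta)(\alpha + \beta + 2)/3}. Sampling
#' picks a latent component per pair.
#'
#' @param n number of pairs.
#' @param alpha,beta mixture weights of M and W.
#' @param seed optional RNG seed.
#' @return An `n x 2` matrix of uniforms.
#' @export
rfrechet <- function(n, alpha, beta, seed = NULL) {
  if (alpha < 0 || beta < 0 || alpha + beta > 1)
    stop("need alpha, beta >= 0 with alpha + beta <= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  pick <- runif(n)
  v <- runif(n)
  v[pick < alpha] <- u[pick < alpha]
  sel <- pick >= alpha & pick < alpha + beta
  v[sel] <- 1 - u[sel]
  cbind(u, v, deparse.level = 0)
}

#' @rdname rfrechet
#' @param U point matrix.
#' @export
frechet_cdf <- function(U, alpha, beta) {
  U <- as.matrix(U)
  alpha * pmin(U[, 1], U[, 2]) + (1 - alpha - beta) * U[, 1] * U[, 2] +
    beta * pmax(U[, 1] + U[, 2] - 1, 0)
}

#' @rdname rfrechet
#' @export
frechet_tau <- function(alpha, beta) (alpha - beta) * (alpha + beta + 2) / 3

#' Multivariate normal sampler
#'
#' Standard Cholesky-based sampling; the Gaussian copula of `sigma` has
#' population Spearman correlation \eqn{(6/\pi) \arcsin(r/2)} for pairwise
#' correlation r.
#'
#' @param n sample size.
#' @param mean mean vector.
#' @param sigma covariance matrix.
#' @param seed optional RNG seed.
#' @return An `n x p` matrix.
#' @export
rmvn <- function(n, mean, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(mean)
  L <- chol(sigma)
  matrix(rnorm(n * p), n, p) %*% L + matrix(mean, n, p, byrow = TRUE)
}

#' Population Spearman correlation of a Gaussian copula
#'
#' @param r Pearson correlation (matrix or scalar).
#' @return \eqn{(6/\pi)\arcsin(r/2)}, elementwise.
#' @export
gauss_spearman <- function(r) 6 / pi * asin(r / 2)

#' Piecewise-uniform sampler from tabulated quantiles
#'
#' Inverse-CDF sampling of the distribution whose CDF linearly interpolates
#' the knots `(min, 0), (q_l, l), ..., (max, 1)` — i.e. the variable is
#' uniform between consecutive tabulated quantiles, including the two
#' boundary cells.
#'
#' @param n sample size.
#' @param levels quantile levels in `(0, 1)`, strictly increasing.
#' @param values quantile values, strictly increasing.
#' @param minimum,maximum support bounds; `maximum` defaults to twice the
#'   last tabulated quantile.
#' @param seed optional RNG seed.
#' @return Numeric vector of length `n`.
#' @export
rpiecewise_unif <- function(n, levels, values, minimum = 0,
                            maximum = 2 * values[length(values)],
                            seed = NULL) {
  if (length(levels) != length(values)) stop("levels/values length mismatch")
  probs <- c(0, levels, 1)
  knots <- c(minimum, values, maximum)
  if (any(diff(probs) <= 0) || any(diff(knots) <= 0))
    stop("quantile levels and values must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  approx(probs, knots, xout = runif(n))$y
}

piecewise_unif_quantile <- function(u, levels, values, minimum, maximum) {
  approx(c(0, levels, 1), c(minimum, values, maximum), xout = u)$y
}

#' Confounded-scenario specification and sampler
#'
#' A scenario is a list of groups, each with a size, a copula family and
#' per-coordinate marginal specifications. The sampler draws the copula
#' first, then transforms each coordinate by the marginal quantile function,
#' so within-group dependence and marginals are controlled separately — the
#' mechanism by which group-specific marginals manufacture spurious pooled
#' correlation between within-group-independent variables.
#'
#' Supported copulas: `list(family = "independence")`,
#' `list(family = "clayton", theta = )` (or `rho = ` to calibrate),
#' `list(family = "frechet", alpha = , beta = )`,
#' `list(family = "gaussian", r = )`.
#' Supported margins: `list(type = "uniform")`,
#' `list(type = "normal", mean = , sd = )`,
#' `list(type = "piecewise", levels = , values = , minimum = , maximum = )`.
#'
#' @param groups list of group specs: `list(n = , copula = , margins =
#'   list(<one spec per coordinate>), label = )`.
#' @return An object of class `confounded_scenario`.
#' @export
confounded_scenario <- function(groups) {
  for (g in groups) {
    stopifnot(is.numeric(g$n), g$n >= 2, !is.null(g$copula$family))
    if (identical(g$copula$family, "clayton") && is.null(g$copula$theta) &&
        is.null(g$copula$rho))
      stop("clayton copula spec needs theta or rho")
  }
  p <- unique(vapply(groups, function(g) length(g$margins), integer(1)))
  if (length(p) != 1L) stop("all groups must share the marginal dimension")
  structure(list(groups = groups, p = p), class = "confounded_scenario")
}

sample_copula <- function(spec, n) {
  switch(spec$family,
    independence = matrix(runif(2 * n), n, 2L),
    clayton = {
      th <- if (!is.null(spec$theta)) spec$theta else clayton_theta(spec$rho)
      rclayton(n, th)
    },
    frechet = rfrechet(n, spec$alpha, spec$beta),
    gaussian = {
      z <- rmvn(n, c(0, 0), matrix(c(1, spec$r, spec$r, 1), 2))
      pnorm(z)
    },
    stop("unknown copula family: ", spec$family))
}

apply_margin <- function(u, spec) {
  switch(spec$type,
    uniform = u,
    normal = qnorm(u, spec$mean, spec$sd),
    piecewise = piecewise_unif_quantile(
      u, spec$levels, spec$values,
      if (is.null(spec$minimum)) 0 else spec$minimum,
      if (is.null(spec$maximum)) 2 * spec$values[length(spec$values)]
      else spec$maximum),
    stop("unknown margin type: ", spec$type))
}

#' @rdname confounded_scenario
#' @param scenario a `confounded_scenario`.
#' @param seed optional RNG seed.
#' @return `generate_scenario`: a [grouped_sample()].
#' @export
generate_scenario <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "confounded_scenario"))
  if (!is.null(seed)) set.seed(seed)
  groups <- lapply(scenario$groups, function(g) {
    U <- sample_copula(g$copula, g$n)
    vapply(seq_along(g$margins),
           function(l) apply_margin(U[, l], g$margins[[l]]),
           numeric(g$n))
  })
  labels <- vapply(seq_along(scenario$groups), function(i) {
    lb <- scenario$groups[[i]]$label
    if (is.null(lb)) as.character(i) else lb
  }, character(1))
  grouped_sample(groups, labels = labels)
}

#' Salary-vs-height confounding scenario
#'
#' Two groups (men / women) with independent height and weekly salary
#' inside each group but gender-specific marginals: heights are normal
#' (176.3 / 11.38 cm for men, 162.2 / 11.15 cm for women, from published
#' anthropometric tables) and salaries are piecewise-uniform between
#' tabulated weekly-earnings quantiles (10/25/50/75/90 percent), with
#' minimum 0 and maximum twice the 90th percentile.
#'
#' The earnings quantiles bundled here are *illustrative synthetic
#' placeholders* of plausible 2009 magnitude — the source tables are not
#' redistributed — so only results that are distribution-free under
#' independence (e.g. the level of the scalar-weighted rank test) are
#' quantitatively reproducible from this scenario.
#'
#' @param n per-group sample sizes (men, women).
#' @return A [confounded_scenario()].
#' @export
scenario_salary_height <- function(n = c(150, 150)) {
  lev <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  confounded_scenario(list(
    list(n = n[1], label = "men",
         copula = list(family = "independence"),
         margins = list(
           list(type = "normal", mean = 176.3, sd = 11.38),
           list(type = "piecewise", levels = lev,
                values = c(400, 545, 819, 1220, 1685)))),
    list(n = n[2], label = "women",
         copula = list(family = "independence"),
         margins = list(
           list(type = "normal", mean = 162.2, sd = 11.15),
           list(type = "piecewise", levels = lev,
                values = c(345, 455, 657, 940, 1290))))))
}

#' Multivariate-normal parameters of the iris species
#'
#' Per-species mean vectors and covariance matrices of the four iris
#' measurements, used as the "true model" of the simulation studies.
#'
#' @return Named list (one element per species) of `list(mean, cov)`.
#' @export
iris_mvn_params <- function() {
  ir <- datasets::iris
  out <- lapply(split(ir[, 1:4], ir$Species), function(d)
    list(mean = colMeans(d), cov = cov(d)))
  out
}

#' Sample simulated iris-like grouped data
#'
#' Draws each group from a multivariate normal with the given parameters.
#'
#' @param sizes group sizes.
#' @param params list of `list(mean, cov)` per group, e.g.
#'   [iris_mvn_params()] (recycled if a single element).
#' @param seed optional RNG seed.
#' @return A [grouped_sample()].
#' @export
riris_mvn <- function(sizes = c(50, 50, 50), params = iris_mvn_params(),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(params) == 1L) params <- rep(params, length(sizes))
  groups <- Map(function(n, pr) rmvn(n, pr$mean, pr$cov), sizes, params)
  grouped_sample(groups, labels = names(params))
}
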