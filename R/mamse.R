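#' Variance proxy of an empirical copula
#'
#' The crude plug-in \eqn{\hat C(u)\{1 - \hat C(u)\}/n}, the binomial part of
#' the asymptotic variance of the empirical copula (the only term that does
#' not involve derivatives of the true copula). It is bounded by 1/(4n).
#'
#' @param x an [empirical_copula()].
#' @param u evaluation point(s).
#' @return Nonnegative values, one per point.
#' @export
variance_proxy <- function(x, u) {
  v <- cop_eval(x, u)
  v * (1 - v) / x$n
}

#' Discretised MAMSE objective
#'
#' Builds the quadratic form of the MAMSE criterion
#' \deqn{P(\lambda) = \int \left[\{\hat C_t(u) - \hat C_\lambda(u)\}^2 +
#'   \sum_i \lambda_i^2 \widetilde{var}\{\hat C_i(u)\}\right] du}
#' discretised over a point set: `P(lambda) = lambda' (M + diag(d)) lambda -
#' 2 v' lambda + c0`, where `M` is the Gram matrix of copula values over the
#' points, `v` its target row, and `d` the averaged variance proxies.
#'
#' @param copulas list of [empirical_copula()] objects, one per group.
#' @param pts an [make_eval_points()] object (or point matrix).
#' @param target index of the group of interest (default 1).
#' @return An object of class `mamse_objective`.
#' @export
mamse_objective <- function(copulas, pts, target = 1L) {
  if (inherits(copulas, "empirical_copula")) copulas <- list(copulas)
  m <- length(copulas)
  if (m < 1L) stop("need at least one copula")
  if (target < 1L || target > m) stop("invalid target index")
  U <- if (inherits(pts, "eval_points")) pts$points else as.matrix(pts)
  G <- nrow(U)
  if (G == 0L) stop("empty evaluation point set")
  E <- vapply(copulas, function(cc) cop_eval(cc, U), numeric(G))
  if (G == 1L) E <- matrix(E, nrow = 1L)
  ns <- vapply(copulas, function(cc) cc$n, numeric(1))
  M <- crossprod(E) / G
  d <- colMeans(E * (1 - E)) / ns
  structure(list(M = M, v = M[target, ], d = d, c0 = M[target, target],
                 sizes = ns, target = target, G = G, m = m),
            class = "mamse_objective")
}

#' Evaluate the MAMSE objective at a weight vector
#'
#' @param obj a [mamse_objective()].
#' @param lambda weight vector on the simplex.
#' @return The value of the discretised objective.
#' @export
objective_value <- function(obj, lambda) {
  lambda <- check_weights(lambda, obj$m)
  Q <- obj$M + diag(obj$d, obj$m)
  drop(t(lambda) %*% Q %*% lambda - 2 * sum(obj$v * lambda) + obj$c0)
}

#' Minimise the MAMSE objective over the probability simplex
#'
#' Active-set quadratic programming: the equality-constrained KKT system is
#' solved on the current free set, negative coordinates are clamped one at a
#' time, and bound coordinates whose multiplier is negative are released
#' until the KKT conditions hold. The form is strictly convex whenever the
#' variance penalties `d` are positive, which holds as soon as one
#' integration point takes an interior copula value.
#'
#' @param obj a [mamse_objective()].
#' @param tol KKT residual tolerance.
#' @return An object of class `mamse_fit`: `mu` (the MAMSE weights),
#'   `objective` (its value), `iterations`, `active` (clamped coordinates),
#'   `min_eigen` (smallest eigenvalue of the quadratic form, a near-zero
#'   value flags near-flat directions / non-unique weights).
#' @export
solve_mamse <- function(obj, tol = 1e-10) {
  stopifnot(inherits(obj, "mamse_objective"))
  m <- obj$m
  Q <- obj$M + diag(obj$d, m)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("quadratic form is not positive semidefinite (min eigenvalue ",
         format(min(ev)), "); integration points may be degenerate")
  if (m == 1L)
    return(structure(list(mu = 1, objective = objective_value(obj, 1),
                          iterations = 0L, active = integer(0),
                          min_eigen = ev[1]), class = "mamse_fit"))
  kkt_solve <- function(idx) {
    k <- length(idx)
    A <- rbind(cbind(2 * Q[idx, idx, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    b <- c(2 * obj$v[idx], 1)
    tryCatch(solve(A, b), error = function(e)
      solve(A + diag(1e-10, k + 1L), b))
  }
  free <- rep(TRUE, m)
  best <- NULL
  for (iter in seq_len(4L * m + 16L)) {
    idx <- which(free)
    k <- length(idx)
    sol <- kkt_solve(idx)
    lf <- sol[seq_len(k)]
    nu <- sol[k + 1L]
    if (any(lf < -1e-10)) {
      free[idx[which.min(lf)]] <- FALSE     # clamp the most negative coord
      next
    }
    lam <- numeric(m)
    lam[idx] <- pmax(lf, 0)
    lam <- lam / sum(lam)
    val <- objective_value(obj, lam)
    if (is.null(best) || val < best$val - 1e-15)
      best <- list(lam = lam, val = val, iter = iter, free = free)
    s <- drop(2 * (Q %*% lam - obj$v)) - nu  # multipliers of the bounds
    viol <- which(!free & s < -tol)
    if (!length(viol))
      return(structure(list(mu = lam, objective = val,
                            iterations = iter, active = which(!free),
                            min_eigen = min(ev)),
                       class = "mamse_fit"))
    free[viol[which.min(s[viol])]] <- TRUE   # release the worst bound
  }
  # cycling safeguard: enumerate support sets exhaustively for small m
  if (m <= 14L) {
    for (code in seq_len(2L^m - 1L)) {
      idx <- which(bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
      sol <- kkt_solve(idx)
      lf <- sol[seq_along(idx)]
      if (any(lf < -1e-10)) next
      lam <- numeric(m)
      lam[idx] <- pmax(lf, 0)
      lam <- lam / sum(lam)
      val <- objective_value(obj, lam)
      if (is.null(best) || val < best$val - 1e-15)
        best <- list(lam = lam, val = val, iter = NA_integer_, free = idx)
    }
  }
  if (!is.null(best))
    return(structure(list(mu = best$lam, objective = best$val,
                          iterations = best$iter,
                          active = which(best$lam == 0),
                          min_eigen = min(ev)),
                     class = "mamse_fit"))
  stop("simplex QP solver failed to converge; m = ", m)
}

#' @export
print.mamse_fit <- function(x, ...) {
  cat("MAMSE weights:", paste(sprintf("%.4f", x$mu), collapse = " "), "\n")
  cat("  objective:", format(x$objective), " iterations:", x$iterations, "\n")
  invisible(x)
}

default_mamse_points <- function(n1, p, seed = NULL) {
  # grid g = n1 when the problem is bivariate and small, else Monte Carlo
  if (p == 2L && n1 <= 100L) make_eval_points("grid", n1, p)
  else make_eval_points("mc", 2000L, p, seed = seed)
}

#' MAMSE weights for a grouped sample
#'
#' Convenience wrapper: computes within-group ranks, empirical copulas, the
#' discretised objective on a default point set (full grid with `g = n_1`
#' when `p = 2` and `n_1 <= 100`, otherwise 2000 Monte Carlo points), and
#' minimises it over the simplex.
#'
#' @param x a [grouped_sample()] or [group_ranks()] object.
#' @param target index of the group of interest.
#' @param pts optional [make_eval_points()] overriding the default.
#' @param ties tie handling passed to [group_ranks()].
#' @param seed seed for the Monte Carlo default point set.
#' @return A `mamse_fit` (see [solve_mamse()]) with the point set attached
#'   as attribute `pts`.
#' @examples
#' gs <- grouped_sample(iris, group = "Species")
#' fit <- mamse_weights(gs, target = 2, ties = "midrank", seed = 1)
#' fit$mu
#' @export
mamse_weights <- function(x, target = 1L, pts = NULL,
                          ties = c("error", "midrank"), seed = NULL) {
  rd <- if (inherits(x, "rank_data")) x else group_ranks(x, match.arg(ties))
  cops <- empirical_copula(rd)
  if (is.null(pts))
    pts <- default_mamse_points(cops[[target]]$n, rd$p, seed = seed)
  fit <- solve_mamse(mamse_objective(cops, pts, target = target))
  attr(fit, "pts") <- pts
  fit
}

#' Size-proportional scalar weights
#'
#' `n_i / N`, the scalar weights minimising the variance-inflation factor
#' [a_k()] (which they bring to its lower bound 1).
#'
#' @param sizes positive group sizes.
#' @return Numeric weight vector summing to 1.
#' @export
scalar_weights <- function(sizes) {
  if (any(sizes <= 0)) stop("sizes must be positive")
  sizes / sum(sizes)
}

#' Variance-inflation factor of a weight vector
#'
#' \eqn{A = \sum_i w_i^2 N / n_i \ge 1}, with equality exactly at the
#' size-proportional weights. Its limit is also the asymptotic relative
#' efficiency of the pooled test versus the scalar-weighted test.
#'
#' @param w weights on the simplex.
#' @param sizes group sizes.
#' @return Scalar `>= 1`.
#' @export
a_k <- function(w, sizes) {
  w <- check_weights(w, length(sizes))
  if (any(sizes <= 0)) stop("sizes must be positive")
  sum(w^2 * sum(sizes) / sizes)
}
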