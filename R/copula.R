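#' Empirical copula
#'
#' The empirical copula of one group places mass 1/n at each rescaled rank
#' point R_j / n and is evaluated as
#' \deqn{\hat C(u) = \frac{1}{n}\sum_{j=1}^n \prod_{\ell=1}^p
#'   1\!\left(R_{j\ell}/n \le u_\ell\right).}
#' Rescaling uses R/n (not the R/(n+1) convention of several libraries), so
#' rescaled ranks live in (0, 1] and the copula attains 1 at u = (1, ..., 1).
#'
#' @param ranks an `n x p` rank matrix (integer ranks, or midranks for
#'   resampled data), or a `rank_data` object from [group_ranks()] (then a
#'   list of empirical copulas is returned).
#' @param n sample size; defaults to `nrow(ranks)`.
#' @return An object of class `empirical_copula` (or a list of them).
#' @examples
#' ec <- empirical_copula(cbind(1:4, c(2, 1, 4, 3)))
#' cop_eval(ec, c(0.5, 0.5))
#' @export
empirical_copula <- function(ranks, n = NULL) {
  if (inherits(ranks, "rank_data"))
    return(lapply(ranks$ranks, empirical_copula))
  ranks <- as.matrix(ranks)
  if (is.null(n)) n <- nrow(ranks)
  if (n < 1L) stop("empty rank matrix")
  if (any(ranks < 1 - 1e-9) || any(ranks > n + 1e-9))
    stop("ranks must lie in [1, n]")
  structure(list(ranks = ranks, resc = ranks / n, n = n, p = ncol(ranks)),
            class = "empirical_copula")
}

#' @export
print.empirical_copula <- function(x, ...) {
  cat("Empirical copula: n =", x$n, ", p =", x$p, "\n")
  invisible(x)
}

#' Weighted mixture of empirical copulas
#'
#' \eqn{\hat C_\lambda(u) = \sum_i \lambda_i \hat C_i(u)} for nonnegative
#' weights summing to one over the m groups.
#'
#' @param components list of [empirical_copula()] objects.
#' @param weights nonnegative numeric vector summing to 1, one per component.
#' @return An object of class `mixture_copula`.
#' @export
mixture_copula <- function(components, weights) {
  if (inherits(components, "empirical_copula")) components <- list(components)
  weights <- check_weights(weights, length(components))
  p <- unique(vapply(components, function(cc) cc$p, numeric(1)))
  if (length(p) != 1L) stop("components differ in dimension")
  structure(list(components = components, weights = weights, p = p),
            class = "mixture_copula")
}

check_weights <- function(w, m, tol = 1e-12) {
  if (length(w) != m)
    stop("length mismatch: ", length(w), " weights for ", m, " components")
  if (any(w < -tol)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  pmax(w, 0) / sum(pmax(w, 0))
}

as_points <- function(u, p) {
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1L)
  if (inherits(u, "eval_points")) U <- u$points
  if (ncol(U) != p) stop("points have dimension ", ncol(U), ", expected ", p)
  if (any(U < 0) || any(U > 1)) stop("evaluation points must lie in [0,1]^p")
  U
}

#' Evaluate a copula estimate at points of the unit hypercube
#'
#' @param x an `empirical_copula` or `mixture_copula`.
#' @param u a point (numeric vector), a `G x p` matrix of points, or an
#'   [make_eval_points()] object.
#' @return Numeric vector of values in `[0, 1]`, one per point. Vectorised
#'   evaluation is exactly equal to pointwise evaluation.
#' @export
cop_eval <- function(x, u) UseMethod("cop_eval")

#' @export
cop_eval.empirical_copula <- function(x, u) {
  U <- as_points(u, x$p)
  ecop_eval_cpp(U, x$resc)
}

#' @export
cop_eval.mixture_copula <- function(x, u) {
  U <- as_points(u, x$p)
  vals <- vapply(x$components, function(cc) ecop_eval_cpp(U, cc$resc),
                 numeric(nrow(U)))
  if (nrow(U) == 1L) vals <- matrix(vals, nrow = 1L)
  drop(vals %*% x$weights)
}

#' Evaluation points for integrals over the unit hypercube
#'
#' Either the evenly spaced grid \{(j1/g, ..., jp/g) : j in \{1..g\}^p\}
#' (excluding coordinate 0, including 1, where the empirical copula carries
#' mass) or `G` i.i.d. uniform Monte Carlo points reproducible from a seed.
#'
#' @param scheme `"grid"` or `"mc"`.
#' @param g_or_G per-axis resolution `g` (grid) or number of points `G`
#'   (Monte Carlo).
#' @param p dimension.
#' @param seed RNG seed for the Monte Carlo scheme.
#' @return An object of class `eval_points` with a `G x p` matrix `points`.
#' @examples
#' make_eval_points("grid", 2, p = 2)$points
#' @export
make_eval_points <- function(scheme = c("grid", "mc"), g_or_G, p, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(g_or_G >= 1, p >= 1)
  if (scheme == "grid") {
    g <- as.integer(g_or_G)
    if (p * log(g) > log(2e6))
      stop("grid of g^p = ", g, "^", p,
           " points is too large; use the Monte Carlo scheme instead")
    pts <- as.matrix(expand.grid(rep(list(seq_len(g) / g), p)))
    dimnames(pts) <- NULL
    structure(list(points = pts, scheme = "grid", g = g, p = p, seed = NULL),
              class = "eval_points")
  } else {
    G <- as.integer(g_or_G)
    if (!is.null(seed)) set.seed(seed)
    pts <- matrix(runif(G * p), G, p)
    structure(list(points = pts, scheme = "mc", G = G, p = p, seed = seed),
              class = "eval_points")
  }
}

#' @export
print.eval_points <- function(x, ...) {
  cat("Evaluation points:", nrow(x$points), "points in dimension", x$p,
      sprintf("(%s)\n", x$scheme))
  invisible(x)
}

#' Average absolute error against a reference copula
#'
#' Approximates \eqn{\int |\hat C(u) - C(u)| du} by the average over the
#' evaluation points (the unit cube has volume 1, so the average is the
#' Monte Carlo / Riemann value of the integral).
#'
#' @param x an `empirical_copula` or `mixture_copula`.
#' @param truth a function mapping a `G x p` matrix of points to copula
#'   values (see e.g. [clayton_copula()]).
#' @param pts an [make_eval_points()] object or a point matrix.
#' @return Nonnegative scalar.
#' @export
integral_abs_error <- function(x, truth, pts) {
  U <- as_points(pts, if (inherits(pts, "eval_points")) pts$p else x$p)
  mean(abs(cop_eval(x, U) - truth(U)))
}

#' Supremum distance between two copula estimates over a point set
#'
#' @param a,b `empirical_copula`/`mixture_copula` objects or functions of a
#'   point matrix.
#' @param pts evaluation points.
#' @return Maximum absolute difference over the points.
#' @export
sup_distance <- function(a, b, pts) {
  U <- if (inherits(pts, "eval_points")) pts$points else as.matrix(pts)
  fa <- if (is.function(a)) a(U) else cop_eval(a, U)
  fb <- if (is.function(b)) b(U) else cop_eval(b, U)
  max(abs(fa - fb))
}

#' Write copula evaluations to CSV
#'
#' Emits a table with the u-coordinates and one value column per estimate.
#'
#' @param path output file.
#' @param pts evaluation points.
#' @param ... named copula estimates to evaluate.
#' @return The data frame, invisibly.
#' @export
write_eval_table <- function(path, pts, ...) {
  U <- if (inherits(pts, "eval_points")) pts$points else as.matrix(pts)
  ests <- list(...)
  out <- as.data.frame(U)
  names(out) <- paste0("u", seq_len(ncol(U)))
  for (nm in names(ests)) out[[nm]] <- cop_eval(ests[[nm]], U)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
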