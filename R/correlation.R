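#' Spearman's rank correlation (exact finite-sample formula)
#'
#' \deqn{\hat\rho_n = -3\frac{n+1}{n-1} +
#'   \frac{12}{n(n+1)(n-1)}\sum_j R_j S_j,}
#' the normalisation that reaches exactly +1 / -1 at perfect concordance /
#' discordance of untied ranks.
#'
#' @param r,s rank vectors of one bivariate group, or `r` an `n x 2` rank
#'   matrix with `s` missing.
#' @return Value in `[-1, 1]`.
#' @export
spearman_rho <- function(r, s = NULL) {
  if (is.null(s)) {
    if (ncol(as.matrix(r)) != 2L) stop("expected bivariate ranks (p = 2)")
    s <- r[, 2L]; r <- r[, 1L]
  }
  n <- length(r)
  if (n < 2L || length(s) != n) stop("need two rank vectors of equal length >= 2")
  -3 * (n + 1) / (n - 1) + 12 / (n * (n + 1) * (n - 1)) * sum(r * s)
}

#' Kendall's rank correlation
#'
#' \eqn{\hat\tau_n = \frac{2}{n(n-1)}\sum_{i<j}
#'   \mathrm{sign}(R_i - R_j)\,\mathrm{sign}(S_i - S_j)} by a full pair scan.
#' The scan materialises the n x n sign matrices, so it is meant for
#' group-sized samples (thousands, not tens of thousands).
#'
#' @inheritParams spearman_rho
#' @return Value in `[-1, 1]`.
#' @export
kendall_tau <- function(r, s = NULL) {
  if (is.null(s)) {
    if (ncol(as.matrix(r)) != 2L) stop("expected bivariate ranks (p = 2)")
    s <- r[, 2L]; r <- r[, 1L]
  }
  n <- length(r)
  if (n < 2L || length(s) != n) stop("need two rank vectors of equal length >= 2")
  sum(sign(outer(r, r, "-")) * sign(outer(s, s, "-"))) / (n * (n - 1))
}

#' General rank-correlation functionals
#'
#' Coefficients of the form
#' \eqn{\hat\kappa = a_n \int g(u)\, d\hat C(u) + b_n =
#'   a_n \frac{1}{n}\sum_j g(R_j/n, S_j/n) + b_n}
#' for a bounded `g` on the unit square, with size-dependent normalisers
#' `a_n`, `b_n` chosen so that the coefficient lies in `[-1, 1]` with the
#' endpoints attained exactly at perfect concordance / discordance. When
#' `a_n`/`b_n` are omitted they are calibrated from that contract at each
#' sample size: `a_n = 2 / (K_c - K_d)`, `b_n = 1 - a_n K_c`, where `K_c`
#' and `K_d` are the plug-in averages under perfectly concordant and
#' discordant ranks.
#'
#' @param g function of two numeric vectors (u, v), vectorised.
#' @param a_n,b_n optional functions of `n` giving exact normalisers.
#' @param name label used in printing.
#' @return An object of class `g_functional`.
#' @seealso [gf_spearman()], [gf_gini()], [gf_blest()]
#' @export
g_functional <- function(g, a_n = NULL, b_n = NULL, name = "custom") {
  stopifnot(is.function(g))
  structure(list(g = g, a_n = a_n, b_n = b_n, name = name),
            class = "g_functional")
}

#' @export
print.g_functional <- function(x, ...) {
  cat("g-functional coefficient:", x$name, "\n")
  invisible(x)
}

#' @rdname g_functional
#' @details `gf_spearman()` uses `g(u, v) = uv` with the exact normalisers
#'   `a_n = 12 n^2 / ((n+1)(n-1))`, `b_n = -3(n+1)/(n-1)`, and reproduces
#'   [spearman_rho()] exactly.
#' @export
gf_spearman <- function() {
  g_functional(function(u, v) u * v,
               a_n = function(n) 12 * n^2 / ((n + 1) * (n - 1)),
               b_n = function(n) -3 * (n + 1) / (n - 1),
               name = "spearman")
}

#' @rdname g_functional
#' @details `gf_gini()` is Gini's cograduation coefficient,
#'   `g(u, v) = 2(|u + v - 1| - |u - v|)`, with parity-dependent exact
#'   normalisers.
#' @export
gf_gini <- function() {
  g_functional(function(u, v) 2 * (abs(u + v - 1) - abs(u - v)),
               a_n = function(n) n / (n - 1),
               b_n = function(n)
                 if (n %% 2 == 0) -1 / (n - 1) else -(n + 1) / (n * (n - 1)),
               name = "gini")
}

#' @rdname g_functional
#' @details `gf_blest()` is Blest's asymmetric coefficient based on
#'   `g(u, v) = (1 - u)^2 v` (penalising disagreement among the small
#'   ranks), with contract-calibrated normalisers.
#' @export
gf_blest <- function() {
  g_functional(function(u, v) (1 - u)^2 * v, name = "blest")
}

gf_normalizers <- function(gf, n) {
  if (!is.null(gf$a_n))
    return(c(a = gf$a_n(n), b = gf$b_n(n)))
  j <- seq_len(n) / n
  kc <- mean(gf$g(j, j))
  kd <- mean(gf$g(j, rev(j)))
  if (abs(kc - kd) < 1e-14)
    stop("g-functional is degenerate: identical plug-in value at perfect ",
         "concordance and discordance")
  a <- 2 / (kc - kd)
  c(a = a, b = 1 - a * kc)
}

#' Evaluate a g-functional coefficient on one group's bivariate ranks
#'
#' @param gf a [g_functional()].
#' @inheritParams spearman_rho
#' @return Value in `[-1, 1]`.
#' @examples
#' kappa_hat(gf_spearman(), 1:5, c(2, 1, 3, 5, 4))
#' @export
kappa_hat <- function(gf, r, s = NULL) {
  if (is.null(s)) { s <- r[, 2L]; r <- r[, 1L] }
  n <- length(r)
  ab <- gf_normalizers(gf, n)
  unname(ab["a"] * mean(gf$g(r / n, s / n)) + ab["b"])
}

#' Weighted sum of per-group coefficients
#'
#' \eqn{\hat\kappa_w = \sum_i w_i \hat\kappa_i}. This is the weighted
#' coefficient obtained by substituting the weighted empirical copula into a
#' linear (g-functional) coefficient.
#'
#' @param w weights on the simplex.
#' @param estimates per-group coefficient estimates.
#' @return Scalar in `[-1, 1]`.
#' @export
weighted_coef <- function(w, estimates) {
  w <- check_weights(w, length(estimates))
  sum(w * estimates)
}

#' Naive weighted Kendall's tau
#'
#' \eqn{\hat\tau_w = \sum_i w_i \hat\tau_i}. Consistent under homogeneous
#' copulas; with adaptive (MAMSE) weights under heterogeneity it need not
#' converge to the target group's tau because tau is not linear in the
#' copula — the quadratic-form statistic [tau_tilde()] is the consistent
#' alternative.
#'
#' @inheritParams weighted_coef
#' @param taus per-group Kendall tau estimates.
#' @export
weighted_tau_naive <- function(w, taus) weighted_coef(w, taus)

#' Cross-group Kendall statistic for one pair of groups
#'
#' \deqn{[\tilde T]_{ij} = \frac{1}{N_{ij}} \sum_{s,t}
#'  \mathrm{sign}(R_{is}/n_i - R_{jt}/n_j)\,
#'  \mathrm{sign}(S_{is}/n_i - S_{jt}/n_j)}
#' over all cross pairs, where cross pairs tied on either rescaled
#' coordinate contribute 0 and are excluded from the denominator
#' \eqn{N_{ij}}. Rescaled ranks (not raw ranks) are compared because group
#' sizes may differ. With `i = j` this reduces exactly to [kendall_tau()].
#'
#' @param ri,rj `n_i x 2` and `n_j x 2` bivariate rank matrices.
#' @return List with elements `t` (the statistic) and `n_pairs`
#'   (\eqn{N_{ij}}).
#' @export
kendall_cross <- function(ri, rj) {
  ri <- as.matrix(ri); rj <- as.matrix(rj)
  if (ncol(ri) != 2L || ncol(rj) != 2L)
    stop("cross-group Kendall requires bivariate ranks")
  res <- kendall_cross_cpp(ri, rj)
  if (res[2] == 0)
    stop("degenerate cross pair: every cross pair is tied (N_ij = 0)")
  list(t = res[1] / res[2], n_pairs = res[2])
}

#' Full cross-group Kendall matrix
#'
#' The `m x m` matrix powering [tau_tilde()]; its diagonal equals the
#' standard within-group Kendall tau.
#'
#' @param rd a [group_ranks()] object with `p = 2`.
#' @return An object of class `kendall_cross_matrix`: list with the matrix
#'   `t_mat` and the pair-count matrix `n_pairs`.
#' @export
kendall_cross_matrix <- function(rd) {
  stopifnot(inherits(rd, "rank_data"))
  if (rd$p != 2L) stop("cross-group Kendall requires bivariate data")
  m <- length(rd$ranks)
  Tm <- matrix(0, m, m); Nm <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    kc <- kendall_cross(rd$ranks[[i]], rd$ranks[[j]])
    Tm[i, j] <- Tm[j, i] <- kc$t
    Nm[i, j] <- Nm[j, i] <- kc$n_pairs
  }
  structure(list(t_mat = Tm, n_pairs = Nm, sizes = rd$sizes),
            class = "kendall_cross_matrix")
}

#' Quadratic-form weighted Kendall statistic
#'
#' \eqn{\tilde\tau_\mu = \mu' \tilde T \mu}, the weighted Kendall statistic
#' that substitutes the weighted empirical copula on *both* sides of the
#' population functional \eqn{4\int C\,dC - 1}. Unlike the naive weighted
#' average it remains consistent for the target group's tau under
#' heterogeneous copulas.
#'
#' @param mu weights on the simplex.
#' @param cross a [kendall_cross_matrix()] (or plain matrix).
#' @return Scalar.
#' @export
tau_tilde <- function(mu, cross) {
  Tm <- if (inherits(cross, "kendall_cross_matrix")) cross$t_mat else cross
  mu <- check_weights(mu, nrow(Tm))
  drop(t(mu) %*% Tm %*% mu)
}

#' Expectation of the cross-group Kendall entry under independence
#'
#' Closed form \eqn{(n_i n_j / N_{ij}) (1/n_j - 1/n_i)^2}; zero when the two
#' group sizes are equal, so the off-diagonal entries are not centred at 0
#' for unequal sizes.
#'
#' @param n_i,n_j group sizes.
#' @param n_pairs the untied cross-pair count \eqn{N_{ij}}.
#' @return Scalar.
#' @export
expected_cross_indep <- function(n_i, n_j, n_pairs) {
  (n_i * n_j / n_pairs) * (1 / n_j - 1 / n_i)^2
}

#' Spearman correlation matrices under a categorical confounder
#'
#' @param gs a [grouped_sample()] with `p >= 2`.
#' @param mode `"group"` returns one matrix per group; `"pooled"` ranks the
#'   concatenated sample, deliberately reproducing the confounded estimate;
#'   `"weighted"` combines the per-group matrices entrywise with `weights`.
#' @param weights weight vector for `mode = "weighted"` (defaults to
#'   size-proportional scalar weights).
#' @param ties within-group tie handling (see [group_ranks()]); ties in the
#'   pooled ranking are always resolved by midranks with a warning, since
#'   real data routinely tie across groups.
#' @return A `p x p` matrix, or a named list of them for `mode = "group"`.
#' @examples
#' gs <- grouped_sample(iris, group = "Species")
#' spearman_matrix(gs, mode = "group", ties = "midrank")$setosa
#' @export
spearman_matrix <- function(gs, mode = c("group", "pooled", "weighted"),
                            weights = NULL, ties = c("error", "midrank")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gs, "grouped_sample"))
  if (gs$p < 2L) stop("need at least two numeric columns")
  cn <- colnames(gs$groups[[1L]])
  if (mode == "pooled") {
    X <- do.call(rbind, gs$groups)
    tied <- any(apply(X, 2, anyDuplicated) > 0)
    if (tied)
      warning("ties in the pooled ranking resolved by midranks")
    R <- apply(X, 2, rank, ties.method = "average")
    out <- pair_spearman_matrix(R)
    dimnames(out) <- list(cn, cn)
    return(out)
  }
  rd <- group_ranks(gs, match.arg(ties))
  mats <- lapply(rd$ranks, function(R) {
    out <- pair_spearman_matrix(R)
    dimnames(out) <- list(cn, cn)
    out
  })
  names(mats) <- gs$labels
  if (mode == "group") return(mats)
  if (is.null(weights)) weights <- scalar_weights(gs$sizes)
  weights <- check_weights(weights, length(mats))
  Reduce(`+`, Map(`*`, mats, weights))
}

pair_spearman_matrix <- function(R) {
  p <- ncol(R)
  out <- diag(p)
  for (a in seq_len(p - 1L)) for (b in (a + 1L):p)
    out[a, b] <- out[b, a] <- spearman_rho(R[, a], R[, b])
  out
}

#' MAMSE-weighted correlation matrix
#'
#' Combines per-group correlation matrices with adaptive weights targeting
#' one group. `weighting = "global"` computes one weight vector from the
#' p-dimensional empirical copulas; `weighting = "pairwise"` recomputes
#' bivariate MAMSE weights on the 2-D margins of each variable pair,
#' adapting better to pair-specific similarity at the price of a combined
#' matrix that is no longer guaranteed positive definite (the result carries
#' an attribute `positive_definite`, checked but not enforced).
#'
#' @param gs a [grouped_sample()].
#' @param target index of the group of interest.
#' @param weighting `"global"` or `"pairwise"`.
#' @param coef `"spearman"`, `"kendall"` (naive weighted average) or
#'   `"tau_tilde"` (quadratic form per pair).
#' @param ties tie handling for [group_ranks()].
#' @param seed seed for Monte Carlo integration points (global weighting in
#'   dimension > 2).
#' @return The combined `p x p` matrix with attributes `weights` (vector, or
#'   list per pair) and `positive_definite`.
#' @export
mamse_cor_matrix <- function(gs, target = 1L,
                             weighting = c("global", "pairwise"),
                             coef = c("spearman", "kendall", "tau_tilde"),
                             ties = c("error", "midrank"), seed = NULL) {
  weighting <- match.arg(weighting)
  coef <- match.arg(coef)
  rd <- group_ranks(gs, match.arg(ties))
  p <- rd$p
  m <- length(rd$ranks)
  cn <- colnames(gs$groups[[1L]])
  out <- diag(p)
  pair_coef <- function(R, a, b) switch(coef,
    spearman = spearman_rho(R[, a], R[, b]),
    kendall = kendall_tau(R[, a], R[, b]),
    tau_tilde = kendall_tau(R[, a], R[, b]))
  if (weighting == "global") {
    fit <- mamse_weights(rd, target = target, seed = seed)
    w <- fit$mu
    for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
      if (coef == "tau_tilde") {
        sub <- structure(list(ranks = lapply(rd$ranks, function(R) R[, c(a, b)]),
                              sizes = rd$sizes, p = 2L, labels = rd$labels),
                         class = "rank_data")
        out[a, b] <- out[b, a] <- tau_tilde(w, kendall_cross_matrix(sub))
      } else {
        ests <- vapply(rd$ranks, pair_coef, numeric(1), a = a, b = b)
        out[a, b] <- out[b, a] <- weighted_coef(w, ests)
      }
    }
    weights <- w
  } else {
    weights <- list()
    for (a in seq_len(p - 1L)) for (b in (a + 1L):p) {
      sub <- structure(list(ranks = lapply(rd$ranks, function(R) R[, c(a, b)]),
                            sizes = rd$sizes, p = 2L, labels = rd$labels),
                       class = "rank_data")
      fit <- mamse_weights(sub, target = target, seed = seed)
      w <- fit$mu
      if (coef == "tau_tilde") {
        val <- tau_tilde(w, kendall_cross_matrix(sub))
      } else {
        ests <- vapply(rd$ranks, pair_coef, numeric(1), a = a, b = b)
        val <- weighted_coef(w, ests)
      }
      out[a, b] <- out[b, a] <- val
      weights[[paste0(a, ":", b)]] <- w
    }
  }
  dimnames(out) <- list(cn, cn)
  attr(out, "weights") <- weights
  attr(out, "positive_definite") <-
    min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) > 0
  out
}
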