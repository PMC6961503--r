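#' Cramer-von Mises statistic for copula homogeneity
#'
#' \deqn{T = \frac{1}{m}\sum_i \int \{\hat C_i(u) - \hat C_{-i}(u)\}^2 du}
#' where \eqn{\hat C_{-i}} is the leave-one-out size-weighted mixture of the
#' other groups' empirical copulas. The integral is approximated by the
#' average over the supplied points.
#'
#' @param rd a [group_ranks()] object (or list of rank matrices).
#' @param pts an [make_eval_points()] object or point matrix.
#' @param sizes group sizes when `rd` is a plain list.
#' @return Nonnegative scalar.
#' @export
cvm_statistic <- function(rd, pts, sizes = NULL) {
  if (inherits(rd, "rank_data")) {
    ranks <- rd$ranks
    sizes <- rd$sizes
  } else {
    ranks <- rd
    if (is.null(sizes)) sizes <- vapply(ranks, nrow, numeric(1))
  }
  m <- length(ranks)
  if (m < 2L) stop("homogeneity statistic requires at least two groups")
  U <- if (inherits(pts, "eval_points")) pts$points else as.matrix(pts)
  resc <- Map(function(R, n) as.matrix(R) / n, ranks, sizes)
  cvm_stat_cpp(resc, as.numeric(sizes), U)
}

#' Pool rescaled ranks across groups
#'
#' Concatenates the within-group rescaled ranks `R_ij / n_i` into a single
#' `N x p` matrix. Under the null of a common copula these rows are
#' (approximately) draws from that copula, free of the group-specific
#' marginals.
#'
#' @param rd a [group_ranks()] object.
#' @return An `N x p` numeric matrix with values in `(0, 1]`.
#' @export
pooled_rescaled_ranks <- function(rd) {
  stopifnot(inherits(rd, "rank_data"))
  do.call(rbind, Map(function(R, n) R / n, rd$ranks, rd$sizes))
}

#' Permutation split of pooled rows into bootstrap groups
#'
#' Draws without replacement from the pooled rows: a uniformly random
#' permutation is split into consecutive blocks of the required sizes, which
#' must exhaust the pool exactly.
#'
#' @param pool an `N x p` matrix (typically from [pooled_rescaled_ranks()]).
#' @param sizes target group sizes summing to `nrow(pool)`.
#' @return List of matrices with `sizes[i]` rows each.
#' @export
resample_null <- function(pool, sizes) {
  pool <- as.matrix(pool)
  if (sum(sizes) != nrow(pool))
    stop("group sizes must sum to the number of pooled rows")
  perm <- sample.int(nrow(pool))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(function(a, b) pool[perm[a:b], , drop = FALSE], starts, ends)
}

#' Resampling test of copula homogeneity across groups
#'
#' Tests whether the m groups share a common copula. The observed
#' Cramer-von Mises statistic is compared with statistics recomputed on B
#' bootstrap pseudo-samples obtained by pooling the rescaled within-group
#' ranks and redistributing them into groups without replacement. Bootstrap
#' pseudo-samples are re-ranked within groups before computing the
#' statistic; the redistribution creates ties, which are resolved by
#' midranks (a known source of mild conservatism of the test). The same
#' Monte Carlo integration points are reused for the observed and every
#' bootstrap statistic so that integration noise cancels from the
#' comparison.
#'
#' @param x a [grouped_sample()], or a data frame with `group`.
#' @param group grouping column name when `x` is a data frame.
#' @param B number of bootstrap samples.
#' @param G number of Monte Carlo integration points.
#' @param seed RNG seed governing both the integration points and the
#'   resampling.
#' @param alpha nominal level used for the reported rejection decision.
#' @param ties tie handling for the *original* data (resampled ties always
#'   use midranks).
#' @return An object of class `copconf_homtest`: `statistic`,
#'   `boot_statistics`, `p_value = #\{boot >= observed\}/B`, `reject`, `B`,
#'   `G`, `seed`, plus the Monte Carlo standard error of the observed
#'   statistic as diagnostic `mc_se`.
#' @examples
#' gs <- grouped_sample(iris[c(1:20, 51:70), ], group = "Species")
#' homogeneity_test(gs, B = 50, G = 500, seed = 1, ties = "midrank")
#' @export
homogeneity_test <- function(x, group = NULL, B = 1000L, G = 2000L,
                             seed = NULL, alpha = 0.05,
                             ties = c("error", "midrank")) {
  gs <- if (inherits(x, "grouped_sample")) x else grouped_sample(x, group)
  if (length(gs$groups) < 2L) stop("homogeneity test requires m >= 2 groups")
  if (B < 1L) stop("B must be >= 1")
  rd <- group_ranks(gs, match.arg(ties))
  if (!is.null(seed)) set.seed(seed)
  pts <- make_eval_points("mc", G, p = gs$p)
  obs <- cvm_statistic(rd, pts)
  pool <- pooled_rescaled_ranks(rd)
  sizes <- gs$sizes
  boot <- numeric(B)
  for (b in seq_len(B)) {
    parts <- resample_null(pool, sizes)
    branks <- lapply(parts, function(P)
      apply(P, 2, rank, ties.method = "average"))
    boot[b] <- cvm_statistic(branks, pts, sizes = sizes)
  }
  # dispersion of the per-point squared deviations as an MC-error diagnostic
  U <- pts$points
  E <- vapply(Map(function(R, n) R / n, rd$ranks, sizes),
              function(V) ecop_eval_cpp(U, as.matrix(V)), numeric(G))
  N <- sum(sizes)
  dev <- vapply(seq_along(sizes), function(i) {
    wts <- sizes[-i] / (N - sizes[i])
    (E[, i] - drop(E[, -i, drop = FALSE] %*% wts))^2
  }, numeric(G))
  mc_se <- sd(rowMeans(dev)) / sqrt(G)
  structure(list(statistic = obs, boot_statistics = boot,
                 p_value = mean(boot >= obs),
                 reject = mean(boot >= obs) < alpha,
                 B = B, G = G, seed = seed, alpha = alpha, mc_se = mc_se,
                 labels = gs$labels),
            class = "copconf_homtest")
}

#' @export
print.copconf_homtest <- function(x, ...) {
  cat("Resampling test of copula homogeneity (Cramer-von Mises)\n")
  cat(sprintf("  groups: %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  statistic = %.6g (MC se %.2g), B = %d, G = %d\n",
              x$statistic, x$mc_se, x$B, x$G))
  cat(sprintf("  p-value = %.4g  =>  %s homogeneity at level %.2g\n",
              x$p_value, if (x$reject) "reject" else "do not reject",
              x$alpha))
  invisible(x)
}
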