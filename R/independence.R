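#' Asymptotic tests of independence from rank correlations
#'
#' Under independence, Spearman's rho is compared to a centred normal with
#' variance 1/(n-1) and Kendall's tau to a centred normal with variance
#' (4n+10)/\{9n(n-1)\}. All tests are two-sided.
#'
#' @param rho_hat,tau_hat observed coefficient.
#' @param n sample size.
#' @param alpha nominal level.
#' @return List with `z`, `p_value`, `reject`.
#' @export
spearman_indep_test <- function(rho_hat, n, alpha = 0.05) {
  z <- rho_hat * sqrt(n - 1)
  p <- 2 * pnorm(-abs(z))
  list(z = z, p_value = p, reject = p < alpha)
}

#' @rdname spearman_indep_test
#' @export
kendall_indep_test <- function(tau_hat, n, alpha = 0.05) {
  z <- tau_hat / sqrt((4 * n + 10) / (9 * n * (n - 1)))
  p <- 2 * pnorm(-abs(z))
  list(z = z, p_value = p, reject = p < alpha)
}

#' Independence test from a scalar-weighted coefficient
#'
#' For coefficients combined across groups with size-proportional scalar
#' weights, the same normal approximations apply with the total sample size
#' N in place of n. Under independence the within-group ranks are
#' distribution-free, so the level does not depend on the (possibly
#' group-specific) continuous marginals.
#'
#' @param coef the weighted coefficient.
#' @param total_n total sample size N.
#' @param kind `"spearman"` or `"kendall"`.
#' @param alpha nominal level.
#' @return List with `z`, `p_value`, `reject`.
#' @export
weighted_indep_test <- function(coef, total_n, kind = c("spearman", "kendall"),
                                alpha = 0.05) {
  kind <- match.arg(kind)
  switch(kind,
         spearman = spearman_indep_test(coef, total_n, alpha),
         kendall = kendall_indep_test(coef, total_n, alpha))
}

#' Bootstrap Wald test of independence for MAMSE-weighted coefficients
#'
#' The MAMSE weights depend on all groups, including data not covered by the
#' null H0: group `target` is independent, so no closed-form null variance
#' is available. Each bootstrap replicate regenerates the target group from
#' the independence copula (i.i.d. uniform pairs) while resampling the other
#' groups' observations with replacement, then recomputes ranks, MAMSE
#' weights and the weighted coefficient. The standard deviation of the B
#' replicate coefficients is the standard error of a two-sided Wald
#' statistic `z = observed / se`.
#'
#' @param gs a [grouped_sample()] with `p = 2`.
#' @param target index of the group whose independence is tested.
#' @param coef `"spearman"`, `"kendall"` (naive weighted average) or
#'   `"tau_tilde"`.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param alpha nominal level.
#' @param ties tie handling for the observed-data ranks.
#' @return List with `statistic` (observed coefficient), `se`, `z`,
#'   `p_value`, `reject`, `boot_coefs`, `B`, `seed`.
#' @export
mamse_wald_test <- function(gs, target = 1L,
                            coef = c("spearman", "kendall", "tau_tilde"),
                            B = 400L, seed = NULL, alpha = 0.05,
                            ties = c("error", "midrank")) {
  coef <- match.arg(coef)
  stopifnot(inherits(gs, "grouped_sample"))
  if (gs$p != 2L) stop("Wald test implemented for bivariate data")
  if (length(gs$groups) < 2L) stop("need m >= 2 groups")
  if (B < 2L) stop("B must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  observed <- mamse_coef(group_ranks(gs, match.arg(ties)), target, coef)
  n_t <- gs$sizes[target]
  boot <- numeric(B)
  for (b in seq_len(B)) {
    groups <- gs$groups
    groups[[target]] <- matrix(runif(2 * n_t), n_t, 2L)
    for (i in seq_along(groups)) {
      if (i == target) next
      groups[[i]] <- groups[[i]][sample.int(nrow(groups[[i]]), replace = TRUE),
                                 , drop = FALSE]
    }
    bgs <- grouped_sample(groups, labels = gs$labels)
    boot[b] <- mamse_coef(group_ranks(bgs, ties = "midrank"), target, coef)
  }
  se <- sd(boot)
  if (se == 0) stop("bootstrap standard error is zero; cannot form Wald statistic")
  z <- observed / se
  p <- 2 * pnorm(-abs(z))
  list(statistic = observed, se = se, z = z, p_value = p, reject = p < alpha,
       boot_coefs = boot, B = B, seed = seed)
}

# weighted coefficient of one kind, recomputing MAMSE weights from the ranks
mamse_coef <- function(rd, target, coef) {
  fit <- mamse_weights(rd, target = target)
  switch(coef,
    spearman = weighted_coef(fit$mu, vapply(rd$ranks, spearman_rho, numeric(1))),
    kendall = weighted_coef(fit$mu, vapply(rd$ranks, kendall_tau, numeric(1))),
    tau_tilde = tau_tilde(fit$mu, kendall_cross_matrix(rd)))
}
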