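# shared fixtures and independent oracles, built in code

# random untied bivariate rank matrix
rand_ranks <- function(n, p = 2L) {
  vapply(seq_len(p), function(l) sample.int(n), integer(n))
}

# random point on the probability simplex
rand_simplex <- function(m) {
  e <- -log(runif(m))
  e / sum(e)
}

# brute-force empirical copula: direct indicator count, one point at a time
oracle_ecop <- function(ranks, n, u) {
  mean(apply(ranks, 1, function(rj) all(rj / n <= u)))
}

# all permutations of 1..n (tiny n only)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) out <- c(out, list(c(i, p + (p >= i))))
  }
  out
}

# direct pair-count Kendall oracle
oracle_kendall <- function(r, s) {
  n <- length(r)
  conc <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    conc <- conc + sign(r[i] - r[j]) * sign(s[i] - s[j])
  }
  2 * conc / (n * (n - 1))
}

# a small grouped CSV fixture on disk
write_grouped_fixture <- function(path, seed = 1) {
  set.seed(seed)
  df <- data.frame(g = rep(c("a", "b"), each = 12),
                   x = rnorm(24), y = rnorm(24))
  utils::write.csv(df, path, row.names = FALSE)
  df
}
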