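---
title: "Weighted rank correlation under categorical confounding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rank correlation under categorical confounding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copconf)
```

## The problem

Rank correlations are invariant to monotone marginal transformations, but
they are not immune to confounding. When a categorical variable (sex,
species, batch, study site) shifts the marginal distributions of two
otherwise independent measurements, the *pooled* Spearman or Kendall
coefficient picks up the between-group marginal structure and reports a
spurious association — a rank-based cousin of the ecological fallacy.
Ranking *within* each level of the confounder removes the nuisance
marginals, at the cost of splitting the data into m smaller samples whose
coefficients must then be recombined.

`copconf` implements that recombination at the level of the *empirical
copula*. For group $i$ with $n_i$ observations and within-group ranks
$R_{ij\ell}$, the empirical copula is

$$\hat C_i(u) = \frac{1}{n_i}\sum_{j=1}^{n_i}\prod_{\ell=1}^p
  \mathbf 1\!\left(R_{ij\ell}/n_i \le u_\ell\right),$$

and weighted estimators take the form $\hat C_w(u) = \sum_i w_i \hat
C_i(u)$ for nonnegative weights summing to one. Because most rank
correlations are linear functionals of the copula, weighting copulas is
equivalent to weighting the per-group coefficients (Kendall's tau is the
exception, treated below).

Two weighting regimes are supported:

* **Scalar weights** under the assumption of a common copula across
  groups: any simplex weights give a consistent estimator, and the
  size-proportional choice $w_i = n_i/N$ minimises the variance-inflation
  factor $A = \sum_i w_i^2 N/n_i \ge 1$ (`scalar_weights()`, `a_k()`).
  $\lim A$ is also the asymptotic relative efficiency of the pooled test
  against the weighted test, so at proportional weights nothing is lost
  asymptotically by stratifying.
* **Adaptive (MAMSE) weights** when the copulas may differ: weights
  minimise a squared-bias-plus-variance-proxy criterion targeting one
  group, borrowing strength from similar groups while remaining consistent
  for the target.

## The MAMSE objective and its minimisation

With group 1 as target, the criterion is

$$P(\lambda) = \int_{[0,1]^p}\Big[\{\hat C_1(u)-\hat C_\lambda(u)\}^2
  + \sum_i \lambda_i^2\,\frac{\hat C_i(u)\{1-\hat C_i(u)\}}{n_i}\Big]\,du ,$$

where the penalty is the binomial part of the empirical copula's variance —
the only part that does not involve derivatives of the unknown copula.
Discretised over a point set the criterion is the quadratic form
$\lambda'(M + \mathrm{diag}(d))\lambda - 2v'\lambda + c_0$
(`mamse_objective()`), strictly convex whenever some integration point
takes an interior copula value, so the simplex minimiser is unique.

`solve_mamse()` uses an active-set method: solve the equality-constrained
KKT system on the free coordinates, clamp the most negative coordinate,
release bound coordinates with negative multipliers, repeat. m is the
number of confounder levels — rarely more than a dozen — so the KKT
systems are tiny; a safeguard enumerates all support sets exhaustively
(for m up to 14) in the unlikely event of cycling. Tolerances: simplex
feasibility 1e-12, KKT residual 1e-10. Degenerate near-flat directions
(e.g. when a mixture of the other groups replicates the target copula, in
which case the weights are known to stay random even asymptotically) are
not canonicalised; the smallest eigenvalue of the quadratic form is
reported in the fit object so callers can detect them.

Solved instances always satisfy the chain
$\int(\hat C_1-\hat C_\mu)^2 \le P(\mu) \le P(e_1) \le 1/(4n_1)$, which is
asserted by the test suite on randomized instances.

**Integration points.** The criterion is integrated either on the evenly
spaced grid $\{j/g\}^p$ with $g = n_1$ (used by default when $p = 2$ and
$n_1 \le 100$) or with 2000 uniform Monte Carlo points (logged seed)
otherwise. The grid includes coordinate 1 and excludes 0, matching where
the empirical copula carries mass. Sensitivity checks during development
(2000 vs 20 000 Monte Carlo points vs a $7^4$ grid in the
four-dimensional case) moved the resulting weights and downstream MSEs
only marginally.

## Correlation estimators

* `spearman_rho()` / `kendall_tau()` implement the exact finite-sample
  normalisations that reach $\pm 1$ at perfect concordance/discordance of
  untied ranks.
* `kappa_hat()` evaluates general coefficients
  $a_n\int g\,d\hat C + b_n$ for a bounded $g$. `gf_spearman()` uses
  $g(u,v) = uv$ with the exact normalisers and reproduces `spearman_rho()`
  to machine precision (a tested identity). `gf_gini()` and `gf_blest()`
  are provided as presets; where the literature's finite-sample
  normalisers depend on parity or are awkward, they are *calibrated from
  the endpoint contract* ($+1$ at perfect concordance, $-1$ at perfect
  discordance), which fixes $a_n, b_n$ uniquely and preserves the
  asymptotic functional. The presets are validated only against the
  $[-1,1]$ and concordance contracts.
* Kendall's tau is not linear in the copula, so the naive weighted average
  $\sum_i \mu_i\hat\tau_i$ is inconsistent under heterogeneous copulas
  (`weighted_tau_naive()` documents this caveat). The consistent
  alternative substitutes the weighted copula on *both* sides of
  $4\int C\,dC-1$, giving the quadratic form
  $\tilde\tau_\mu = \mu'\tilde T\mu$ where $\tilde T$ compares rescaled
  ranks *across* groups (`kendall_cross_matrix()`, `tau_tilde()`).
  Cross-pairs are compared through $R_{is}/n_i$ versus $R_{jt}/n_j$
  because group sizes may differ; ties in rescaled ranks contribute zero
  and are excluded from the denominator $N_{ij}$. The diagonal reduces
  exactly to the within-group tau. Under independence the *numerator* of
  an off-diagonal entry has exact expectation
  $n_i n_j (1/n_j - 1/n_i)^2$ — zero only for equal sizes — which the
  suite verifies by exhaustive permutation enumeration at sizes (2, 3);
  the tabled entry divides by the realised $N_{ij}$, which is itself
  random, so the ratio form
  $(n_in_j/N_{ij})(1/n_j-1/n_i)^2$ should be read with $N_{ij}$ as the
  realised denominator rather than as an unconditional mean of the
  statistic.
* `spearman_matrix()` returns pooled (deliberately confounded), per-group
  and weighted matrices; `mamse_cor_matrix()` combines per-group matrices
  with global (p-dimensional) or pairwise (per-2-D-margin) adaptive
  weights. Pairwise weighting adapts better to pair-specific similarity
  but the combined matrix need not be positive definite; definiteness is
  checked and reported as an attribute, never enforced.

## Homogeneity test

`homogeneity_test()` implements a resampling test of equal copulas across
groups with the Cramér–von Mises statistic

$$T = \frac1m \sum_{i=1}^m \int \{\hat C_i(u) - \hat C_{-i}(u)\}^2\,du,
\qquad \hat C_{-i} = \sum_{j\ne i}\frac{n_j}{N-n_i}\hat C_j .$$

Within-group rescaled ranks are pooled, redistributed into groups by
drawing without replacement (sizes must exhaust the pool exactly), each
pseudo-group is re-ranked — redistribution inevitably creates ties, which
are resolved by midranks — and the statistic is recomputed; the p-value is
the proportion of bootstrap statistics at least as large as the observed
one. Integrals use 2000 Monte Carlo points; the same point set is used
for the observed and all bootstrap statistics so that integration noise
cancels from the comparison (a variance-reduction choice; drawing fresh
points per statistic shifted the level from about 0.03–0.04 to about
0.05 in our experiments and is not exposed as an option).

A caveat established during development and reflected in a deliberately
failing acceptance test: on three simulated iris-like groups of 50 the
procedure as literally stated is *conservative-to-nominal* (empirical
level ≈ 0.04 at the 5% level, power ≈ 0.60 against the heterogeneous
three-species alternative), whereas the reference experiment reports a
liberal level of 0.120 and power 0.757. No faithful variant we tried
(shared vs fresh integration points; midrank, min, max or random
re-ranking; skipping re-ranking altogether, which destroys the test)
reproduces those operating characteristics. Two opposite forces are at
play — drawing without replacement shrinks bootstrap group differences by
the finite-population factor, while re-ranking ties inflates them — and
their net effect in this implementation calibrates the test rather than
inflating it.

## Independence tests

Under independence, $\hat\rho\sqrt{n-1}$ is standard normal and
$\hat\tau$ has variance $(4n+10)/\{9n(n-1)\}$; weighted coefficients with
size-proportional weights reuse the same formulas with the total sample
size (`weighted_indep_test()`). Because only within-group ranks enter,
the level of the weighted test is distribution-free over continuous
group-specific marginals — the suite verifies this *realisation-wise* by
pushing common latent uniforms through different monotone quantile maps.

For MAMSE-weighted coefficients the weights depend on data outside the
null hypothesis, so `mamse_wald_test()` uses a bootstrap: each replicate
regenerates the target group from the independence copula, resamples the
other groups with replacement, and recomputes ranks, weights and the
coefficient (the weights are deliberately *inside* the resampling loop —
they are data-dependent); the Wald statistic divides the observed
coefficient by the bootstrap standard deviation, with 400 replicates by
default.

## Synthetic data

The samplers module states the worlds the experiments run in:

* `rclayton()` — conditional-inversion Clayton sampling;
  `clayton_theta()` calibrates the parameter to a target Spearman
  correlation by Gauss–Legendre quadrature of $12\int C_\theta - 3$ and
  bisection to 1e-6. Negative dependence uses $\theta \in (-1, 0)$,
  staying inside the named family.
* `rfrechet()` — the mixture $\alpha M + (1-\alpha-\beta)\Pi + \beta W$
  of the comonotone, independence and countermonotone copulas, with
  $\tau = (\alpha-\beta)(\alpha+\beta+2)/3$.
* `rmvn()` / `riris_mvn()` — multivariate normal groups; true Spearman
  correlations follow from the Gaussian copula as $(6/\pi)\arcsin(r/2)$,
  which is what the relative-MSE experiments use as ground truth.
* `rpiecewise_unif()` — inverse-CDF sampling of a distribution uniform
  between tabulated quantiles, linearly interpolated over *all* cells
  including the two boundary cells (support $[\text{min}, 2q_{90}]$).
* `scenario_salary_height()` — two groups, independent height and weekly
  salary within each, gender-specific marginals. The height parameters
  (176.3/11.38 cm and 162.2/11.15 cm) are published anthropometric
  values; the earnings quantiles are **illustrative synthetic
  placeholders** of plausible 2009 magnitude, because the source tables
  are not redistributable. Consequently the pooled rejection rate of this
  scenario is *not* quantitatively reproducible (only its qualitative
  inflation above the nominal level is asserted), whereas the level of
  the scalar-weighted test is distribution-free under independence and
  does not depend on the placeholders at all.

What a green test on synthetic data does establish: correctness of the
estimators, weights and tests under exactly stated dependence structures
and marginals. What it does not: robustness to ties and measurement
granularity in real data (the iris case study shows how heavily tie
handling matters), discrete or ordinal margins, or confounders with many
small levels (the asymptotics require a fixed number of groups with
growing sizes — a mixture of infinitely many size-10 samples never
converges below resolution 1/10).

## Numerical choices

* Rescaling is $R/n$ exactly, not $R/(n+1)$ — many libraries default to
  the latter; values at $(a/n, 1)$ are then *exactly* $a/n$.
* Evaluation of empirical copulas is vectorised in C++ over point sets,
  with the contract (tested) that vectorised and pointwise evaluation
  agree bit-for-bit. Comparisons are plain `<=`; grid coordinates and
  rescaled ranks built from the same `j/n` arithmetic compare exactly,
  and Monte Carlo points are off-lattice almost surely.
* Error integrals for the efficiency experiments (`run_table3()`) are
  evaluated by default on the rank-aligned grid with per-axis resolution
  n, where the $R/n$ empirical copula has no discretisation bias. At
  off-lattice Monte Carlo points every group copula carries an $O(1/n)$
  negative bias that the pooled benchmark (resolution $1/N$) largely
  avoids, which mechanically deflates the efficiency ratio — the `"mc"`
  scheme is retained for illustration of exactly that effect.
* Ties abort by default everywhere (the model assumes continuous data);
  midrank handling must be opted into (`ties = "midrank"`) and is always
  used for bootstrap resamples, which tie by construction.
* Weights are validated to the simplex within 1e-12 and renormalised
  after clamping negative round-off.

## Known limitations

* Strong-dependence, small-sample copula mixtures genuinely lose
  integrated-absolute-error efficiency against the pooled benchmark
  (ratios in the low 80s–90s at $n = 10$–20 under Spearman 0.9 rather
  than 100); the acceptance suite keeps the reference expectation and
  fails visibly there, with the bias/variance decomposition recorded in
  the project notes.
* The adaptive weights trade bias for variance through one global
  compromise; when one group's dependence differs sharply on a single
  variable pair, global weighting spreads that bias over the whole
  matrix. Pairwise weighting mitigates but does not remove this, and
  sacrifices guaranteed positive definiteness.
* No confidence statements are provided for the MAMSE weights themselves;
  their asymptotic distribution is unknown and they can remain random in
  degenerate configurations.
* The power-curve grid spans Spearman $\rho_1 \in [-0.9, 0.9]$ (51
  points); the reference range is unstated and this choice is ours.
* p = 1 and smoothed/checkerboard copula estimators are out of scope.
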