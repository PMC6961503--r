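# copconf

Weighted rank correlation and empirical-copula estimation under a
**categorical confounder**, for R.

Rank correlations are invariant to monotone marginal transformations but
not to confounding: when a discrete variable (sex, species, batch, site)
shifts the marginal distributions of two otherwise independent
measurements, the pooled Spearman or Kendall coefficient reports a
spurious association. The fix is to rank *within* each confounder level —
which removes the nuisance marginals but splits the sample into m small
groups — and then to recombine the group estimates. `copconf` does that
recombination at the level of the empirical copula

$$\hat C_i(u) = \frac{1}{n_i}\sum_{j=1}^{n_i}\prod_{\ell=1}^p
  \mathbf 1\!\left(R_{ij\ell}/n_i \le u_\ell\right),$$

with two weighting regimes over $\hat C_w = \sum_i w_i \hat C_i$:

* **scalar weights** $w_i = n_i/N$ when the groups share one copula —
  optimal among fixed weights, with variance-inflation factor
  $A = \sum_i w_i^2 N/n_i = 1$ and no asymptotic loss of power against
  the (unreachable) pooled benchmark;
* **adaptive MAMSE weights** when dependence may differ across groups —
  the simplex minimiser of the squared-bias-plus-variance criterion
  $P(\lambda)=\int\{\hat C_t-\hat C_\lambda\}^2
  +\sum_i\lambda_i^2\,\hat C_i(1-\hat C_i)/n_i\,du$,
  which borrows strength from similar groups while staying consistent
  for the target group.

On top of these sit weighted Spearman/Kendall/g-functional coefficients,
the cross-group Kendall statistic $\tilde\tau_\mu = \mu'\tilde T\mu$
(consistent under heterogeneity where the naive weighted tau is not), a
Cramér–von Mises resampling test of copula homogeneity, asymptotic and
bootstrap-Wald independence tests, copula samplers (Clayton, Fréchet
family, Gaussian) with confounded-marginal scenarios, and a simulation
harness that reproduces the reference numerical studies at configurable
scale. See `vignettes/methods.Rmd` for the model, assumptions, numerical
choices and known limitations.

## Worked example: the iris species as a confounder

```r
library(copconf)
gs <- grouped_sample(iris, group = "Species")
#> Grouped sample: 3 groups, p = 4
#>   sizes: setosa=50, versicolor=50, virginica=50

round(spearman_matrix(gs, mode = "pooled"), 2)   # the confounded analysis
#>              Sepal.Length Sepal.Width Petal.Length Petal.Width
#> Sepal.Length         1.00       -0.17         0.88        0.83
#> Sepal.Width         -0.17        1.00        -0.31       -0.29
#> Petal.Length         0.88       -0.31         1.00        0.93
#> Petal.Width          0.83       -0.29         0.93        1.00
```

Pooling the three species manufactures *negative* sepal-width
correlations that no single species exhibits. A homogeneity test shows
the species do not share one copula, so scalar weighting would be biased
and adaptive weights are called for:

```r
homogeneity_test(gs, B = 200, G = 2000, seed = 2, ties = "midrank")
#> Resampling test of copula homogeneity (Cramer-von Mises)
#>   groups: setosa, versicolor, virginica
#>   statistic = 0.0028993 (MC se 9.8e-05), B = 200, G = 2000
#>   p-value = 0  =>  reject homogeneity at level 0.05

fit <- mamse_weights(gs, target = 2, ties = "midrank", seed = 1)
#> MAMSE weights: 0.1044 0.6271 0.2685
#>   objective: 0.001318284  iterations: 1
```

Targeting versicolor, the adaptive weights keep 63% on versicolor
itself, borrow 27% from virginica (similar dependence) and 10% from
setosa (dissimilar). The weighted Spearman matrix for versicolor and the
variance-inflation of the weights:

```r
round(mamse_cor_matrix(gs, target = 2, weighting = "global",
                       ties = "midrank", seed = 1), 2)
#>              Sepal.Length Sepal.Width Petal.Length Petal.Width
#> Sepal.Length         1.00        0.51         0.71        0.45
#> Sepal.Width          0.51        1.00         0.48        0.57
#> Petal.Length         0.71        0.48         1.00        0.60
#> Petal.Width          0.45        0.57         0.60        1.00
a_k(fit$mu, gs$sizes)
#> [1] 1.429
```

`A = 1.43` means the weighted estimate behaves like one based on
$N/1.43 \approx 105$ i.i.d. observations — more than twice the 50
versicolor flowers alone, at the price of the (controlled) borrowing
bias. All diagonal-1, symmetric entries are weighted combinations of the
per-species rank correlations; the pooled artefacts are gone.

## Command-line interface

A thin wrapper (`inst/cli/copconf`) exposes subcommands on delimited
tables with a group column:

```sh
copconf weights          --input data.csv --group Species --target 2 --mc 2000 --seed 1
copconf corr             --input data.csv --group Species --weights mamse --target 2
copconf test-homogeneity --input data.csv --group Species --B 1000 --G 2000 --seed 1
copconf test-independence --input data.csv --group g --method scalar-weighted
copconf simulate         --config scenario.json --seed 1 --out sim.csv
copconf reproduce table3 --reps 1000 --seed 1 --out results/
```

JSON goes to stdout (or `--out`); matrices and tables are CSV.

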