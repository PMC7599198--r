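# parafacov

Confirmatory factor analysis of variables-by-occasions covariance matrices
with Khatri–Rao structured loadings — the **structural Parafac model**.

When the same `J` manifest variables are measured at `K` occasions (times,
raters, batteries, methods) on the same units, ordinary factor analysis of
the `JK` stacked variables ignores the replication structure. The
structural Parafac model constrains the `JK × S` loading matrix to the
Khatri–Rao (column-wise Kronecker) product of a `J × S` variable loading
matrix `B` and a `K × S` occasion loading matrix `C`:

    Σ(θ) = D [ (C • B) Φ (C • B)' + Ψ ] D

with common-factor covariance `Φ` (diagonal or oblique), specific-factor
covariance `Ψ` (diagonal, block-diagonal within occasions, or banded
within variables), and a positive diagonal `D` that makes the model scale
invariant (identified either through a unit-diagonal core — a correlation
structure — or through a unit `Ψ` diagonal with free `D`).

The package provides

* the model algebra (`khatri_rao()`, `implied_covariance()`,
  `psi_support()`, `count_parameters()`, `rescale()`),
* **runnable factor-uniqueness checkers** (`k_rank()`,
  `kruskal_condition()`, `row_deletion_condition()`,
  `occasion_rank_condition()`, `uniqueness_report()`),
* **estimation** by normal-theory maximum likelihood, GLS or OLS
  discrepancy minimization with analytic gradients, a seeded multi-start
  protocol and delta-method standard errors (`parafac_fit()`),
* **model comparison**: χ² test of overall fit, AIC/BIC, and a 12-model
  scan with the warm-start protocol for correlated-specific-factor models
  (`chi_square_test()`, `information_criteria()`, `parafac_scan()`),
* **synthetic studies**: seeded generation of identifiable true models,
  normal sampling and permutation/sign alignment for recovery experiments
  (`draw_identifiable_params()`, `simulate_sample_cov()`,
  `parafac_study()`, `align_solutions()`),
* the classic **Bentler–McClain multitrait–multimethod correlation
  matrix** (4 traits × 3 methods, I = 68) as a worked example
  (`bentler_mcclain()`), and a command-line interface
  (`inst/cli/parafac.R`: `fit`, `scan`, `simulate`).

## Worked example

Fit the comparison grid to the multitrait–multimethod data — traits
E(xtraversion), A(nxiety), I(mpulsivity), M(otivation) rated by Peer,
Teacher and Self — varying the factor count (2 or 3), the common-factor
structure and the specific-factor structure:

```r
library(parafacov)
bm <- bentler_mcclain()
scan <- parafac_scan(bm$R, bm$sample_size, bm$layout, model_grid(),
                     fit_options(n_starts = 30, seed = 2020,
                                 compute_se = FALSE))
scan
#>     S        phi                    psi  q  F_hat chi_square df  p_value    aic    bic
#>  1  2 orthogonal               diagonal 24 1.8475     123.78 54 2.12e-07 171.78 225.05
#>  2  2    oblique               diagonal 25 1.8076     121.11 53 3.01e-07 171.11 226.60
#>  3  2 orthogonal banded_within_variable 36 1.0633      71.24 42 3.22e-03 143.24 223.14
#>  ...
#>  9  3 orthogonal banded_within_variable 42 0.7399      49.58 36 6.55e-02 133.58 226.80
#> 10  3    oblique banded_within_variable 45 0.6745      45.19 33 7.67e-02 135.19 235.07
#> 11  3 orthogonal  block_within_occasion 48 0.6353      42.56 30 6.40e-02 138.56 245.10
#> 12  3    oblique  block_within_occasion 51 0.5830      39.06 27 6.26e-02 141.06 254.25
sum(scan$not_rejected)
#> [1] 4
```

Only the four three-factor models with correlated specific factors
survive the χ² test at α = 0.05; the S = 3 orthogonal banded model (row 9)
has the lowest AIC. Its minimized ML discrepancy is F̂ = 0.7399, giving
χ² = 49.58 on 36 df (p = 0.066): each trait's unique factor is allowed to
correlate with itself across rating methods. Models with correlated
specific factors are fitted from a single warm start at the matching
diagonal-Ψ optimum (the protocol that avoids local optima here), while
diagonal models use the full multi-start (`n_at_global` counts starts
agreeing with the reported minimum to four decimals). The selected
model's loading matrices (first rows fixed to 1):

```r
sel <- scan_fit(scan, 9)
round(sel$params$B, 2)      # traits E, A, I, M
#>       [,1]  [,2]  [,3]
#> [1,]  1.00  1.00  1.00
#> [2,] -0.04 -1.26 -2.07
#> [3,]  0.42  2.64  0.36
#> [4,]  0.33 -6.20 -3.36
round(sel$params$C, 2)      # methods P, T, S
#>      [,1] [,2] [,3]
#> [1,] 1.00 1.00 1.00
#> [2,] 3.67 0.49 1.73
#> [3,] 1.77 0.41 0.39
```

Factor 1 is dominated by Teacher rating of Extraversion; factor 2 opposes
Impulsivity to Achievement motivation, measured mainly by Peer report;
factor 3 loads Anxiety and Motivation negatively with Teacher and Peer
weights. The second factor sits in an extremely flat direction of the
likelihood (its loading standard errors are of the same order as the
estimates), so the magnitudes of its largest entries are data-limited —
see the methods vignette (`vignettes/structural-parafac.Rmd`) on flat
optima.

The fitted solution also passes the uniqueness checks
(`sel$uniqueness`): k-rank(B) + k-rank(C) = 6 ≥ S + 2, and all four
per-variable blocks have full column rank, the condition relevant for the
banded structure.

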