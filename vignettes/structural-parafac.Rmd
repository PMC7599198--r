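---
title: "Structural Parafac models for variables-by-occasions covariance matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural Parafac models for variables-by-occasions covariance matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafacov)
```

## The model

When the same $J$ manifest variables are observed at $K$ occasions on the
same units -- repeated measurements, multiple raters, multiple batteries --
the $JK$-vector of scores has a three-way structure that ordinary factor
analysis ignores.  The structural Parafac model is a confirmatory factor
model for the $JK \times JK$ covariance matrix whose loading matrix is
constrained to the Khatri--Rao (column-wise Kronecker) product of a
$J \times S$ variable loading matrix $B$ and a $K \times S$ occasion
loading matrix $C$:

$$\Sigma(\theta) \;=\; D\,\bigl[(C \bullet B)\,\Phi\,(C \bullet B)' + \Psi\bigr]\,D ,$$

where $\Phi$ ($S \times S$) is the common-factor covariance, $\Psi$
($JK \times JK$) the specific-factor covariance, and $D$ a positive
diagonal scaling matrix.  Row $(k-1)J + j$ of the vectorized data refers to
variable $j$ at occasion $k$ (variable-fastest ordering, fixed by
`three_way_layout()` and `composite_index()`).  Within occasion $k$ the
model reads $x_k = \mu_k + B\,\mathrm{diag}(c_k)\,a + e_k$: every occasion
shares the same variable loadings $B$, while the common factors are
rescaled occasion-by-occasion through the rows of $C$.

Three structures are supported for the specific factors:

* **diagonal** -- classical uncorrelated unique factors;
* **block within occasion** -- unique factors of different variables may
  correlate when measured at the same occasion (correlations across
  occasions are attributed to common factors only);
* **banded within variable** -- the mirror-image structure: the unique
  factor of a variable is correlated with itself across occasions.

$\Phi$ is either diagonal (`"orthogonal"`) or an unstructured positive
definite matrix (`"oblique"`).

## Scale invariance

Without $D$ the Khatri--Rao constraint destroys scale invariance: a
rescaling $x \mapsto Lx$ with a general positive diagonal $L$ has no
counterpart in $(B, C)$ unless $L = L_O \otimes L_V$, i.e. unless every
variable is rescaled identically across occasions and vice versa (in that
special case the scaling is absorbed, $(L_O \otimes L_V)(C \bullet B) =
(L_O C) \bullet (L_V B)$, a property the test suite checks on random
draws).  Embedding the free diagonal $D$ restores invariance for arbitrary
$L$: the rescaled model simply has $D_L = LD$ with all other parameters
untouched, which `rescale()` implements and the estimation tests verify on
fitted solutions.

$D$ itself must be identified.  Two conventions are available:

* `invariance = "sigma_unit_diag"` (variant (a)): the bracketed core is
  constrained to unit diagonal, so the model is a reparameterization of a
  correlation matrix.  The package enforces this by construction, deriving
  $D = \mathrm{diag}(M)^{-1/2}$ from $M = (C\bullet B)\Phi(C\bullet B)' +
  \Psi$ rather than by a Lagrangian constraint -- a reparameterization
  that keeps the optimization unconstrained.
* `invariance = "psi_unit_diag"` (variant (b)): $\Psi$ has unit diagonal
  and $D$ is a free parameter block.  This is the variant used in the
  worked multitrait--multimethod example, and the only one for which
  parameter counting and fit statistics are defined in the package.

The loading scale must also be fixed: either unit column norms of $B$ and
$C$ (`"unit_column_norm"`, the natural convention for uniqueness theory)
or first rows of $B$ and $C$ fixed to one (`"first_row_unit"`, common in
confirmatory applications and used in the worked example).

## Factor uniqueness, as runnable checks

A Parafac decomposition is essentially unique -- identified up to a joint
column permutation of $B$ and $C$ (and sign conventions) -- under mild
rank conditions.  The package ships the conditions as numerical checkers
rather than as theory:

* `k_rank()` computes the Kruskal rank by exhaustive subset enumeration:
  the largest $k$ such that every $k$-subset of columns is independent.
  Because the model's first factor matrix is $\Phi^{1/2}$, which has
  k-rank $S$ whenever $\Phi$ is positive definite, the operative
  inequality is $k\text{-rank}(B) + k\text{-rank}(C) \ge S + 2$
  (`kruskal_condition()`).
* `row_deletion_condition()` checks the Anderson--Rubin-type requirement
  for diagonal $\Psi$: deleting any one row of the loading matrix leaves
  two disjoint row sets of full column rank.
* `occasion_rank_condition()` checks the multiple-battery requirement used
  for within-occasion blocks: at least three blocks
  $B\,\mathrm{diag}(c_k)$ of full column rank.  For the banded structure
  the same condition is applied with the roles of variables and occasions
  exchanged.

`uniqueness_report()` evaluates all of them on a parameter set, either on
$C \bullet B$ or on the scaled loadings $D(C\bullet B)\Phi^{1/2}$ (the
relevant matrix for the scale-invariant variants; for positive definite
$\Phi$ and positive $D$ the two have equal row spaces, so both entry
points are exposed rather than one declared canonical).  Rank decisions
use singular values with a relative tolerance (default `1e-8`) that is
surfaced as an argument because k-rank is a discontinuous quantity.
Enumeration is exhaustive with size guards (at most 30 rows / 6 columns in
the partition search); at the matrix orders this model class targets,
correctness is worth more than scale.

## Estimation

`parafac_fit()` minimizes a discrepancy between the sample covariance $S$
and $\Sigma(\theta)$:

* `"ml"`: the normal-theory discrepancy
  $F = \log|\Sigma| - \log|S| + \mathrm{tr}(S\Sigma^{-1}) - JK$, whose
  minimizer is the Gaussian maximum likelihood estimate and for which
  $(I-1)\hat F$ is the likelihood-ratio statistic against the saturated
  model;
* `"gls"` / `"ols"`: the quadratic family
  $\mathrm{tr}\{[(S-\Sigma)W^{-1}]^2\}/2$ with $W = S$ or $W = I$.  Near
  $\Sigma = S$ the ML discrepancy agrees with the $W = S$ quadratic form
  to second order (checked numerically in the tests); OLS is not scale
  invariant and is used mainly as a starting device.

**Parameterization.**  The optimizer works on an unconstrained vector:
$\log$ diagonal for $D$ and for free $\Psi$ diagonals, free entries of $B$
and $C$ (rows below the fixed first row under `"first_row_unit"`),
$\log$-diagonal or log-Cholesky parameterization of $\Phi$, and raw values
for the $\Psi$ off-diagonals on the declared support.  $\Phi$ and $D$ are
therefore positive (definite) by construction; $\Psi$ alone can push
$\Sigma$ out of the positive definite cone, which the objective handles
with a smooth eigenvalue barrier that steers the iterate back.  Under
`"unit_column_norm"` the internal loadings are deliberately unnormalized
(norms are absorbed into $\Phi$ on output); the resulting flat directions
are harmless for function minimization and are excluded from standard
errors, which such configurations do not report.

**Optimization.**  All three discrepancies have analytic gradients through
the entire parameterization (the gradient of $F$ with respect to $\Sigma$
is propagated through $D$, the Khatri--Rao structure, $\Phi$ and $\Psi$ in
closed form; agreement with numerical differentiation is part of the test
suite).  Minimization uses the PORT quasi-Newton routine (`nlminb`) with
box bounds only on the log-scale blocks (to prevent overflow), up to three
continuation restarts per run on very flat surfaces, and a run counts as
converged when the optimizer reports success or the gradient
infinity-norm falls below `conv_grad_tol` (default `1e-4`; the PORT
routine frequently labels a fully converged run "false convergence" under
tight relative tolerances).  A Newton--Raphson iteration with numerical
Hessian converges to the same optima but costs on the order of $q^2$
objective evaluations per step; the analytic-gradient quasi-Newton makes
the 100-start protocol routine.

**Multi-start protocol.**  Random starts draw every internal parameter
i.i.d. from a centered normal with scale 0.5.  By default each start first
minimizes the OLS discrepancy and then refines with the target method
(`start_strategy = "ols_then_ml"`).  The reported solution is the best
converged local minimum; `n_at_global` counts how many starts agree with
it on the first four decimal digits of $\hat F$, a useful fingerprint of
multimodality.  `parafac_scan()` adds the warm-start protocol that proved
necessary for models with correlated specific factors: those are started
from the best-fitting diagonal-$\Psi$ solution with the same $S$ and
$\Phi$ structure, with the new off-diagonal $\Psi$ entries at zero.

**A caution about flat optima.**  On small samples the ML surface of
richly parameterized variants can be extremely flat along directions that
trade loading magnitude against factor variance: the Hessian at the
optimum can be positive definite yet severely ill-conditioned.  On such
ridges different
software -- or the same software under a looser stopping rule -- can
report visibly different loadings whose discrepancies agree to two
decimals.  The package always iterates to gradient-level convergence and
reports the stationary point it reaches; when comparing against estimates
published from other implementations, expect the flattest loading entries
(they are also the ones with the largest standard errors) to differ even
when every fit statistic matches.

**Fit statistics.**  With $q$ free parameters (`count_parameters()`),
$\chi^2 = (I-1)\hat F$ on $df = JK(JK+1)/2 - q$ degrees of freedom, and
the information criteria follow the covariance-structure convention
$\mathrm{AIC} = \chi^2 + 2q$, $\mathrm{BIC} = \chi^2 + q\log I$ (these
order models identically to the likelihood-based definitions, differing
only by a per-sample constant).  Standard errors are delta-method:
$\mathrm{cov}(\hat\theta) = \tfrac{2}{I-1} H^{-1}$ with $H$ the numerical
Hessian of the discrepancy at the optimum, mapped through the Jacobian of
the internal-to-natural transform; an indefinite or singular $H$ yields a
warning and no standard errors rather than fabricated ones.  Exact
standard-error conventions differ across structural-equation software
(expected vs observed information, divisor choices), so cross-software
agreement should be expected to a few percent, not to the last digit.

## The synthetic-data generator

`draw_identifiable_params()` draws loading entries uniformly on $[-1, 1]$
(before applying the identification convention), $\Phi$ as a scaled
Wishart-type positive definite matrix (its diagonal under orthogonality),
moderate specific-factor correlations (uniform on $[-0.3, 0.3]$ in
correlation units) on the declared support, and free $D$ entries uniform
on $[0.5, 1.5]$ -- generic values at the scale of standardized test
scores.  Draws are rejection-sampled (budget 100) until the uniqueness
conditions relevant to the model hold; generic draws satisfy them almost
surely, so rejection merely converts "almost surely" into "certainly",
and dimensionally impossible requests fail with a message instead of
looping.  `simulate_sample_cov()` draws i.i.d. zero-mean multivariate
normal vectors with the implied covariance and returns their sample
covariance (divisor $n-1$).

The generator emulates exactly what the model assumes: multivariate
normality, independent units, a mean structure of no interest, and
second-moment information only.  It does not emulate non-normal or
heavy-tailed data (for which the quadratic discrepancy with
fourth-moment weights would be the appropriate estimator, out of scope
here), missingness, or occasion-specific measurement artifacts.  Passing
recovery tests therefore demonstrate correctness of the estimator under
the model's own assumptions -- not robustness to their violation.

Recovery experiments in the test suite fit the *population* covariance of
a drawn truth and require the aligned estimate (`align_solutions()`, an
exhaustive search over the $S!$ column permutations and, where the
convention allows, per-column sign flips with $\Phi$ compensated) to match
to `1e-4` in every parameter, for each of the three $\Psi$ structures --
the operational restatement of the uniqueness results.  Finite-sample
behavior is exercised at $n$ of a few hundred; the law-of-large-numbers
check uses one draw of $n = 10^6$.

## Numerical choices and problem sizes

Dense linear algebra throughout: the design envelope is $JK$ up to a few
hundred, and the shipped analyses use $JK = 12$.  Test and example runs
use 5--30 random starts (the estimator default is 100); on the worked
example the complete 12-model comparison with 30 starts per diagonal
model runs in well under a minute on one core, and every multi-start
fingerprint reported there is stable across seeds.  Tie-breaking in
`align_solutions()` is by total squared loading deviation; `k_rank()` and
the partition searches break as soon as a witness is found.  Degenerate
inputs are handled explicitly: singular sample covariances are flagged
(and rejected by the ML discrepancy with a clear error), saturated models
raise rather than report a nonpositive $df$, and non-finite intermediate
covariances trigger a coercive surrogate objective instead of crashing
the optimizer.

## Limitations

* The Tucker3 covariance structure (a core-array generalization of this
  model) is out of scope; so are mean structures, constrained loadings,
  fourth-moment (distribution-free) weighting and Bayesian estimation.
* Parameter counting and chi-square statistics are defined for the
  estimable configurations (`"psi_unit_diag"` with `"first_row_unit"`,
  and `"none"`); other invariance/identification combinations fit but
  report no $q$-dependent statistics rather than guessing a convention.
* Standard errors require a positive definite Hessian on the free
  parameter space; flat or unidentified configurations return none.
* The uniqueness checkers implement the classical sufficient conditions;
  sharper conditions exploiting the square structure of $\Phi^{1/2}$
  exist and could flag as "unverified" some models that are in fact
  unique.
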