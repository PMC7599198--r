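test_that("quadratic discrepancy matches the explicit trace oracle", {
  expect_equal(quadratic_discrepancy(diag(3), diag(3), diag(3)), 0)
  expect_equal(quadratic_discrepancy(matrix(2), matrix(1), matrix(1)), 0.5)
  set.seed(501)
  for (rep in 1:5) {
    A1 <- matrix(rnorm(16), 4); S_mat <- crossprod(A1) + diag(4)
    A2 <- matrix(rnorm(16), 4); Sigma <- crossprod(A2) + diag(4)
    A3 <- matrix(rnorm(16), 4); W <- crossprod(A3) + diag(4)
    Prod <- (S_mat - Sigma) %*% solve(W)
    oracle <- sum(diag(Prod %*% Prod)) / 2
    expect_equal(quadratic_discrepancy(S_mat, Sigma, W), oracle,
                 tolerance = 1e-10)
  }
  expect_error(quadratic_discrepancy(diag(2), diag(2), matrix(0, 2, 2)),
               "singular")
})

test_that("ml discrepancy has its closed form and second-order GLS limit", {
  expect_equal(ml_discrepancy(diag(4), diag(4)), 0)
  expect_equal(ml_discrepancy(matrix(1), matrix(2)), log(2) + 1 / 2 - 1)
  expect_error(ml_discrepancy(matrix(1), matrix(-1)), "positive definite")
  # near Sigma = S the ML discrepancy agrees with the W = S quadratic one
  # to second order: ratio -> 1 as the perturbation shrinks
  set.seed(502)
  A <- matrix(rnorm(16), 4); S_mat <- crossprod(A) + diag(4)
  E <- matrix(rnorm(16), 4); E <- (E + t(E)) / 2
  ratios <- sapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    Sigma <- S_mat + eps * E
    ml_discrepancy(S_mat, Sigma) / quadratic_discrepancy(S_mat, Sigma, S_mat)
  })
  expect_lt(abs(ratios[3] - 1), 1e-3)
  expect_true(all(diff(abs(ratios - 1)) < 0))
})

test_that("analytic gradients match numerical differentiation", {
  layout <- layout43()
  configs <- list(
    list(m = app_model(2, "orthogonal", "diagonal"), method = "ml"),
    list(m = app_model(3, "oblique", "banded_within_variable"),
         method = "ml"),
    list(m = app_model(2, "oblique", "block_within_occasion"),
         method = "gls"),
    list(m = parafac_model(2, "orthogonal", "diagonal",
                           invariance = "none",
                           identification = "unit_column_norm"),
         method = "ols"),
    list(m = parafac_model(2, "oblique", "diagonal",
                           invariance = "sigma_unit_diag",
                           identification = "first_row_unit"),
         method = "ml"))
  bm <- bentler_mcclain()
  set.seed(503)
  for (cfg in configs) {
    map <- parafacov:::par_map(cfg$m, layout)
    obj <- parafacov:::make_objective(bm$R, cfg$m, layout, cfg$method, map)
    th <- parafacov:::random_theta(map, 0.3)
    expect_equal(obj$gr(th), pracma::grad(obj$fn, th), tolerance = 1e-5)
  }
})

test_that("fitting a population covariance recovers the truth exactly", {
  layout <- layout43()
  m <- app_model(2, "orthogonal", "diagonal")
  truth <- draw_identifiable_params(m, layout, seed = 504)
  Sigma <- implied_covariance(truth, m, layout)
  fit <- parafac_fit(Sigma, 1000, m, layout,
                     fit_options(n_starts = 10, seed = 505,
                                 compute_se = FALSE))
  expect_lte(fit$F_hat, 1e-8)
  al <- align_solutions(fit$params, truth, m)
  expect_lt(max(abs(al$params$B - truth$B)), 1e-4)
  expect_lt(max(abs(al$params$C - truth$C)), 1e-4)
  expect_lt(max(abs(al$params$Phi - truth$Phi)), 1e-4)
  expect_lt(max(abs(al$params$d - truth$d)), 1e-4)
})

test_that("the discrepancy is invariant to variable/occasion rescaling", {
  # scale-invariant variant: fitting L S L changes only D-hat
  layout <- three_way_layout(3, 3)
  m <- parafac_model(2, "orthogonal", "diagonal",
                     invariance = "psi_unit_diag",
                     identification = "first_row_unit")
  truth <- draw_identifiable_params(m, layout, seed = 506)
  S0 <- simulate_sample_cov(truth, m, layout, n = 500, seed = 507)
  set.seed(508)
  lv <- runif(3, 0.5, 2); lo <- runif(3, 0.5, 2)
  l <- as.vector(outer(lv, lo))
  S1 <- S0 * tcrossprod(l)
  opts <- fit_options(n_starts = 8, seed = 509, compute_se = FALSE)
  f0 <- parafac_fit(S0, 500, m, layout, opts)
  f1 <- parafac_fit(S1, 500, m, layout, opts)
  expect_lt(abs(f0$F_hat - f1$F_hat), 1e-6)
  al <- align_solutions(f1$params, f0$params, m)
  expect_lt(max(abs(al$params$B - f0$params$B)), 1e-4)
  expect_lt(max(abs(al$params$C - f0$params$C)), 1e-4)
  expect_lt(max(abs(al$params$Phi - f0$params$Phi)), 1e-4)
  # D-hat absorbs the scaling (alignment leaves d untouched)
  expect_lt(max(abs(f1$params$d / f0$params$d - l)), 1e-4)
})

test_that("standard errors are deterministic and honest about failure", {
  layout <- three_way_layout(3, 3)
  m <- parafac_model(2, "orthogonal", "diagonal",
                     invariance = "psi_unit_diag",
                     identification = "first_row_unit")
  truth <- draw_identifiable_params(m, layout, seed = 510)
  S_mat <- simulate_sample_cov(truth, m, layout, n = 400, seed = 511)
  f1 <- parafac_fit(S_mat, 400, m, layout,
                    fit_options(n_starts = 5, seed = 1))
  f2 <- parafac_fit(S_mat, 400, m, layout,
                    fit_options(n_starts = 5, seed = 2))
  expect_false(is.null(f1$standard_errors))
  # different seeds, same optimum: identical estimates and SEs
  expect_equal(f1$F_hat, f2$F_hat, tolerance = 1e-8)
  expect_equal(f1$standard_errors, f2$standard_errors, tolerance = 1e-5)
  # dual route on the Hessian: finite differences of the analytic gradient
  obj <- parafacov:::make_objective(S_mat, m, layout, "ml", f1$map)
  H1 <- pracma::hessian(obj$fn, f1$theta)
  H2 <- pracma::jacobian(obj$gr, f1$theta)
  expect_equal((H1 + t(H1)) / 2, (H2 + t(H2)) / 2, tolerance = 1e-4)

  # an unidentified model (flat directions) must warn, not fabricate
  m_flat <- parafac_model(2, "orthogonal", "diagonal",
                          invariance = "none",
                          identification = "unit_column_norm")
  expect_warning(
    parafac_fit(S_mat, 400, m_flat, layout,
                fit_options(n_starts = 3, seed = 3)),
    "standard errors unavailable")
})

test_that("warm starts and convergence bookkeeping behave", {
  bm <- bentler_mcclain()
  m <- app_model(2, "orthogonal", "diagonal")
  f <- parafac_fit(bm$R, bm$sample_size, m, bm$layout,
                   fit_options(n_starts = 6, seed = 512, compute_se = FALSE))
  expect_gte(f$n_converged, 1)
  expect_lte(f$n_at_global, length(f$start_values))
  expect_equal(f$df, 78 - 24)
  # warm start at the optimum returns immediately to the same minimum
  f2 <- parafac_fit(bm$R, bm$sample_size, m, bm$layout,
                    fit_options(n_starts = 1, compute_se = FALSE),
                    init = f$params)
  expect_equal(f2$F_hat, f$F_hat, tolerance = 1e-7)
  # dimension mismatch is caught early
  expect_error(parafac_fit(bm$R[1:6, 1:6], 68, m, bm$layout,
                           fit_options(n_starts = 1)), "12 x 12")
})
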