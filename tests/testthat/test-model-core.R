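test_that("implied covariance matches hand computations in simple cases", {
  layout <- layout43()
  # one common factor with unit loadings everywhere, unit Phi, identity Psi
  m <- parafac_model(1, "orthogonal", "diagonal")
  p <- parafac_params(matrix(1, 4, 1), matrix(1, 3, 1), matrix(1), diag(12))
  Sigma <- implied_covariance(p, m, layout)
  expect_equal(unname(Sigma), matrix(1, 12, 12) + diag(12))

  # doubling every D entry scales Sigma by 4
  m2 <- parafac_model(2, "oblique", "diagonal", invariance = "psi_unit_diag")
  set.seed(5)
  B <- matrix(runif(8, -1, 1), 4, 2); C <- matrix(runif(6, -1, 1), 3, 2)
  Phi <- diag(2)
  p1 <- parafac_params(B, C, Phi, diag(12), D = rep(2, 12))
  Lambda <- khatri_rao(C, B)
  expect_equal(unname(implied_covariance(p1, m2, layout)),
               4 * (Lambda %*% t(Lambda) + diag(12)))
})

test_that("implied covariance equals the elementwise double-sum formula", {
  layout <- layout43()
  m <- parafac_model(2, "oblique", "block_within_occasion",
                     invariance = "psi_unit_diag")
  p <- random_params(layout, 2, "block_within_occasion", "psi_unit_diag",
                     seed = 11)
  Sigma <- implied_covariance(p, m, layout)
  oracle <- matrix(0, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    j <- (r - 1) %% 4 + 1; k <- (r - 1) %/% 4 + 1
    jp <- (c - 1) %% 4 + 1; kp <- (c - 1) %/% 4 + 1
    acc <- 0
    for (s in 1:2) for (t in 1:2)
      acc <- acc + p$B[j, s] * p$C[k, s] * p$Phi[s, t] * p$B[jp, t] * p$C[kp, t]
    oracle[r, c] <- p$d[r] * p$d[c] * (acc + p$Psi[r, c])
  }
  expect_equal(unname(Sigma), oracle, tolerance = 1e-12)
  # symmetric and positive definite
  expect_equal(Sigma, t(Sigma))
  expect_no_error(chol(Sigma))
})

test_that("psi_support enumerates the declared structures", {
  layout <- layout43()
  expect_equal(sum(psi_support("diagonal", layout)), 12)
  # K blocks of J variables: K * J(J-1)/2 = 18 free upper off-diagonals
  expect_equal(sum(psi_support("block_within_occasion", layout)), 12 + 2 * 18)
  expect_equal(nrow(parafacov:::psi_off_support_pairs("block_within_occasion",
                                                      layout)), 18)
  # J bands of K occasions: J * K(K-1)/2 = 12
  expect_equal(sum(psi_support("banded_within_variable", layout)), 12 + 2 * 12)
  expect_equal(nrow(parafacov:::psi_off_support_pairs("banded_within_variable",
                                                      layout)), 12)
  expect_true(isSymmetric(psi_support("block_within_occasion", layout)))
  expect_error(psi_support("bogus", layout))
})

test_that("count_parameters matches direct counting and rejects unsupported specs", {
  layout <- layout43()
  expect_identical(count_parameters(app_model(2), layout), 24L)
  expect_identical(count_parameters(app_model(3, "oblique",
                                              "block_within_occasion"),
                                    layout), 51L)
  expect_identical(count_parameters(app_model(2, "orthogonal",
                                              "banded_within_variable"),
                                    layout), 36L)
  # invariance "none": free Psi diagonal, column-norm constraints on loadings
  m <- parafac_model(2, "orthogonal", "diagonal", invariance = "none",
                     identification = "unit_column_norm")
  expect_identical(count_parameters(m, layout),
                   as.integer(4 * 2 - 2 + 3 * 2 - 2 + 2 + 12))
  expect_error(count_parameters(
    parafac_model(2, invariance = "sigma_unit_diag"), layout),
    "not defined")
})

test_that("rescale transforms parameters consistently with L Sigma L", {
  layout <- layout43()
  set.seed(31)
  lv <- runif(4, 0.5, 2); lo <- runif(3, 0.5, 2)
  l <- as.vector(outer(lv, lo))

  # identity scaling is a no-op
  m <- parafac_model(2, "oblique", "diagonal", invariance = "none")
  p <- random_params(layout, 2, seed = 7)
  p_id <- rescale(p, m, layout, rep(1, 4), rep(1, 3))
  expect_equal(p_id$B, p$B)
  expect_equal(p_id$Psi, p$Psi)

  # without D the loadings and Psi absorb the scaling
  p_l <- rescale(p, m, layout, lv, lo)
  expect_equal(unname(implied_covariance(p_l, m, layout)),
               unname(implied_covariance(p, m, layout)) * tcrossprod(l),
               tolerance = 1e-12)

  # with free D only D changes
  m2 <- parafac_model(2, "oblique", "diagonal", invariance = "psi_unit_diag")
  p2 <- random_params(layout, 2, invariance = "psi_unit_diag", seed = 8)
  p2_l <- rescale(p2, m2, layout, c(2, 1, 1, 1), rep(1, 3))
  expect_equal(p2_l$B, p2$B)
  expect_equal(p2_l$Psi, p2$Psi)
  affected <- composite_index(rep(1, 3), 1:3, layout)
  expect_equal(p2_l$d[affected], 2 * p2$d[affected])
  expect_equal(p2_l$d[-affected], p2$d[-affected])
  expect_equal(unname(implied_covariance(p2_l, m2, layout)),
               unname(implied_covariance(p2, m2, layout)) *
                 tcrossprod(as.vector(outer(c(2, 1, 1, 1), rep(1, 3)))),
               tolerance = 1e-12)
  expect_error(rescale(p2, m2, layout, c(-1, 1, 1, 1), rep(1, 3)),
               "positive")
})

test_that("unit-diagonal-core variant reparameterizes a correlation matrix", {
  layout <- layout43()
  m <- parafac_model(2, "oblique", "banded_within_variable",
                     invariance = "sigma_unit_diag")
  p <- random_params(layout, 2, "banded_within_variable", seed = 13)
  Sigma <- implied_covariance(p, m, layout)
  expect_equal(unname(diag(Sigma)), rep(1, 12), tolerance = 1e-12)
})

test_that("parameter validation flags structural violations", {
  layout <- layout43()
  m <- app_model(2, "oblique")
  p <- random_params(layout, 2, invariance = "psi_unit_diag", seed = 3)
  # B lacks unit first row under first_row_unit
  expect_error(parafacov:::validate_params(p, m, layout), "first")
  p$B[1, ] <- 1; p$C[1, ] <- 1
  expect_silent(parafacov:::validate_params(p, m, layout))
  p_bad <- p
  p_bad$Psi[1, 2] <- p_bad$Psi[2, 1] <- 0.5  # off the diagonal support
  expect_error(parafacov:::validate_params(p_bad, m, layout), "support")
})
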