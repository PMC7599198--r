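test_that("identifiable draws are deterministic and pass their checks", {
  layout <- layout43()
  for (psi in c("diagonal", "block_within_occasion",
                "banded_within_variable")) {
    m <- parafac_model(2, "oblique", psi, invariance = "psi_unit_diag",
                       identification = "first_row_unit")
    p1 <- draw_identifiable_params(m, layout, seed = 701)
    p2 <- draw_identifiable_params(m, layout, seed = 701)
    expect_identical(p1, p2)
    expect_true(uniqueness_report(p1, m, layout)$relevant_satisfied)
  }
  # dimensionally impossible request fails with a clear message
  expect_error(
    draw_identifiable_params(parafac_model(3), three_way_layout(2, 2)),
    "unattainable")
})

test_that("sample covariance converges to the population matrix", {
  layout <- three_way_layout(3, 2)
  m <- parafac_model(2, "orthogonal", "diagonal")
  truth <- draw_identifiable_params(m, layout, seed = 702)
  Sigma <- implied_covariance(truth, m, layout)
  S_big <- simulate_sample_cov(truth, m, layout, n = 1e6, seed = 703)
  expect_lt(max(abs(S_big - Sigma)), 0.01 * max(diag(Sigma)))
  # determinism
  S_a <- simulate_sample_cov(truth, m, layout, n = 50, seed = 704)
  S_b <- simulate_sample_cov(truth, m, layout, n = 50, seed = 704)
  expect_identical(S_a, S_b)
  # n <= JK: singular but still returned, flagged
  S_small <- simulate_sample_cov(truth, m, layout, n = 2, seed = 705)
  expect_true(isTRUE(attr(S_small, "singular")))
  expect_lt(abs(det(S_small)), 1e-10)
})

test_that("synthetic studies bundle a replayable truth and sample", {
  layout <- layout43()
  m <- app_model(2)
  st <- parafac_study(m, layout, n = 100, seed = 706)
  expect_s3_class(st, "parafac_study")
  st2 <- parafac_study(m, layout, n = 100, seed = 706)
  expect_identical(st$sample_cov, st2$sample_cov)
  expect_equal(st$population_cov,
               implied_covariance(st$true_params, m, layout))
})

test_that("align_solutions recovers planted permutations and signs", {
  layout <- layout43()
  m_fru <- parafac_model(3, "oblique", "diagonal",
                         identification = "first_row_unit")
  p <- random_params(layout, 3, seed = 707)
  # identity alignment
  al0 <- align_solutions(p, p, m_fru)
  expect_identical(al0$permutation, 1:3)
  expect_equal(al0$deviation, 0)
  # planted column swap
  perm <- c(2, 3, 1)
  p_swapped <- parafac_params(p$B[, perm], p$C[, perm], p$Phi[perm, perm],
                              p$Psi)
  al <- align_solutions(p_swapped, p, m_fru)
  expect_equal(al$params$B, p$B)
  expect_equal(al$params$Phi, p$Phi)
  # planted permutation plus sign flips under unit column norms
  m_ucn <- parafac_model(3, "oblique", "diagonal",
                         identification = "unit_column_norm")
  eB <- c(-1, 1, -1); eC <- c(1, -1, -1)
  p_flipped <- parafac_params(
    sweep(p$B[, perm], 2, eB, "*"),
    sweep(p$C[, perm], 2, eC, "*"),
    diag(eB * eC) %*% p$Phi[perm, perm] %*% diag(eB * eC),
    p$Psi)
  al2 <- align_solutions(p_flipped, p, m_ucn)
  expect_equal(al2$params$B, p$B, tolerance = 1e-12)
  expect_equal(al2$params$C, p$C, tolerance = 1e-12)
  expect_equal(al2$params$Phi, p$Phi, tolerance = 1e-12)
  expect_error(align_solutions(
    random_params(layout, 2, seed = 1), p, m_fru), "dimensions")
})

test_that("the packaged correlation matrix is a valid MTMM fixture", {
  bm <- bentler_mcclain()
  expect_identical(dim(bm$R), c(12L, 12L))
  expect_equal(unname(diag(bm$R)), rep(1, 12))
  expect_equal(bm$R, t(bm$R))
  expect_equal(bm$R["E@P", "A@P"], -0.38)
  expect_equal(bm$R["M@S", "I@S"], -0.37)
  expect_equal(bm$R["E@T", "E@P"], 0.64)
  expect_gt(min(eigen(bm$R, symmetric = TRUE)$values), 0)
  expect_identical(bm$sample_size, 68L)
  # the shipped CSV is the same matrix
  csv <- read_cov_matrix(system.file("extdata", "bentler_mcclain_cor.csv",
                                     package = "parafacov"))
  expect_equal(unname(csv), unname(bm$R), tolerance = 1e-12)
})
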