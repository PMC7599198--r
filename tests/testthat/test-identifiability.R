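# independent oracle: k-rank by enumerating all column subsets and testing
# rank with a QR factorization (the implementation uses singular values)
k_rank_oracle <- function(M, tol = 1e-8) {
  n <- ncol(M)
  for (k in seq_len(min(n, nrow(M)))) {
    ok <- all(apply(utils::combn(n, k), 2, function(cols)
      qr(M[, cols, drop = FALSE], tol = tol)$rank == k))
    if (!ok) return(k - 1L)
  }
  min(n, nrow(M))
}

test_that("k_rank handles canonical cases", {
  expect_identical(k_rank(diag(3)), 3L)
  expect_identical(k_rank(matrix(c(1, 2, 1, 2), 2)), 1L)  # duplicate direction
  expect_identical(k_rank(cbind(c(1, 0), c(0, 0))), 0L)   # a zero column
  expect_error(k_rank(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("k_rank agrees with the exhaustive QR oracle on random matrices", {
  set.seed(401)
  for (rep in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:4, 1)
    M <- matrix(rnorm(n * m), n, m)
    if (rep %% 5 == 0) M[, m] <- M[, 1]  # plant a dependency sometimes
    expect_identical(k_rank(M), k_rank_oracle(M))
  }
})

test_that("k_rank is bounded by rank and attains it generically", {
  set.seed(402)
  for (rep in 1:20) {
    M <- matrix(rnorm(6 * 3), 6, 3)
    kr <- k_rank(M)
    r <- qr(M)$rank
    expect_lte(kr, r)
    expect_identical(kr, r)  # generic matrices have k-rank == rank
  }
})

test_that("kruskal_condition evaluates the 2S+2 inequality", {
  expect_true(kruskal_condition(2, 2, 2, 2))    # 6 >= 6
  expect_false(kruskal_condition(2, 2, 1, 2))   # 5 < 6
  set.seed(403)
  B <- matrix(rnorm(12), 4, 3); C <- matrix(rnorm(9), 3, 3)
  expect_true(kruskal_condition(3, k_rank(B), k_rank(C), 3))
})

test_that("row_deletion_condition finds or refutes rank-S partitions", {
  I2 <- diag(2)
  expect_true(row_deletion_condition(rbind(I2, I2, I2)))  # 6 rows, S = 2
  short <- matrix(rnorm(4), 2, 2)  # only S rows
  expect_false(row_deletion_condition(short))
  expect_match(attr(row_deletion_condition(short), "reason"), "at least")
  expect_false(row_deletion_condition(rbind(I2, I2)))     # 4 rows < 2S+1
})

test_that("occasion_rank_condition counts full-rank occasion blocks", {
  set.seed(404)
  B <- matrix(rnorm(8), 4, 2)
  C_good <- matrix(runif(6, 0.5, 1), 3, 2)
  res <- occasion_rank_condition(B, C_good)
  expect_identical(res$count, 3L)
  expect_true(res$satisfied)
  # an occasion with a zero loading kills that block's rank
  C_bad <- C_good; C_bad[2, ] <- c(1, 0)
  res2 <- occasion_rank_condition(B, C_bad)
  expect_identical(res2$count, 2L)
  expect_false(res2$satisfied)
  # fewer than three occasions can never satisfy the condition
  expect_false(occasion_rank_condition(B, C_good[1:2, ])$satisfied)
})

test_that("generic draws satisfy the uniqueness conditions (they are mild)", {
  layout <- layout43()
  m <- parafac_model(3, "oblique", "diagonal")
  set.seed(405)
  for (rep in 1:10) {
    p <- random_params(layout, 3, seed = 405 + rep)
    rep_u <- uniqueness_report(p, m, layout)
    expect_true(rep_u$kruskal_satisfied)
    expect_true(rep_u$row_deletion_satisfied)
    expect_identical(rep_u$occasion_rank_count, 3L)
  }
})

test_that("uniqueness report is invariant under joint column permutation", {
  layout <- layout43()
  m <- parafac_model(3, "oblique", "block_within_occasion")
  p <- random_params(layout, 3, "block_within_occasion", seed = 406)
  perm <- c(3, 1, 2)
  p2 <- parafac_params(p$B[, perm], p$C[, perm], p$Phi[perm, perm], p$Psi)
  r1 <- uniqueness_report(p, m, layout)
  r2 <- uniqueness_report(p2, m, layout)
  for (field in c("k_rank_B", "k_rank_C", "kruskal_satisfied",
                  "row_deletion_satisfied", "occasion_rank_count",
                  "result2_satisfied", "variable_rank_count"))
    expect_identical(r1[[field]], r2[[field]])
})
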