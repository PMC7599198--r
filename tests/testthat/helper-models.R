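# shared builders for the test suite

layout43 <- function() three_way_layout(4, 3)

# the application's parameterization: scale-invariant (free D, unit Psi
# diagonal), first rows of B and C fixed to one
app_model <- function(S, phi = "orthogonal", psi = "diagonal") {
  parafac_model(S, phi, psi, invariance = "psi_unit_diag",
                identification = "first_row_unit")
}

# a generic valid parameter set at the given sizes (not necessarily
# satisfying identification conventions; for algebraic checks only)
random_params <- function(layout, S, psi_structure = "diagonal",
                          invariance = "none", seed = 1) {
  set.seed(seed)
  J <- layout$J; K <- layout$K; JK <- J * K
  B <- matrix(runif(J * S, -1, 1), J, S)
  C <- matrix(runif(K * S, -1, 1), K, S)
  A <- matrix(rnorm(S * S), S)
  Phi <- tcrossprod(A) / S + 0.5 * diag(S)
  supp <- psi_support(psi_structure, layout)
  Psi <- diag(JK)
  off <- which(supp & upper.tri(supp), arr.ind = TRUE)
  if (nrow(off)) {
    rho <- runif(nrow(off), -0.2, 0.2)
    Psi[off] <- rho
    Psi[off[, 2:1, drop = FALSE]] <- rho
  }
  d <- if (invariance == "psi_unit_diag") runif(JK, 0.5, 1.5) else NULL
  parafac_params(B, C, Phi, Psi, D = d)
}
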