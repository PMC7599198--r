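#' Quadratic (weighted least squares) discrepancy
#'
#' The generalized least squares family of discrepancy functions
#' `f = tr\{[(S - \Sigma) W^{-1}]^2\} / 2` between a sample covariance `S`
#' and a model-implied `\Sigma`, with weight matrix `W`.  `W = I` gives
#' ordinary least squares, `W = S` the best generalized least squares
#' discrepancy, and `W = \Sigma(\theta)` (iteratively reweighted)
#' approximates maximum likelihood for large samples.
#'
#' @param S_mat sample covariance matrix (symmetric).
#' @param Sigma model-implied covariance matrix (symmetric, same order).
#' @param W positive definite weight matrix; identity by default.
#' @return Nonnegative scalar; zero iff `S_mat == Sigma`.
#' @examples
#' quadratic_discrepancy(matrix(2), matrix(1), matrix(1))  # 0.5
#' @export
quadratic_discrepancy <- function(S_mat, Sigma, W = NULL) {
  S_mat <- as.matrix(S_mat); Sigma <- as.matrix(Sigma)
  stopifnot(nrow(S_mat) == ncol(S_mat), all(dim(S_mat) == dim(Sigma)))
  R <- S_mat - Sigma
  A <- if (is.null(W)) R else {
    W <- as.matrix(W)
    Winv <- tryCatch(chol2inv(chol(W)),
                     error = function(e) stop("weight matrix W is singular or not positive definite",
                                              call. = FALSE))
    R %*% Winv
  }
  sum(A * t(A)) / 2
}

#' Normal-theory maximum likelihood discrepancy
#'
#' `F_ML = log det \Sigma - log det S + tr(S \Sigma^{-1}) - JK`, the
#' discrepancy whose minimizer is the Gaussian maximum likelihood estimate
#' and for which `(I - 1) F_ML` at the optimum is the likelihood-ratio
#' chi-square statistic against the saturated model.  Nonnegative, zero iff
#' `S == \Sigma`.
#'
#' @param S_mat sample covariance matrix, positive definite.
#' @param Sigma model-implied covariance matrix, positive definite.
#' @return Scalar discrepancy value.
#' @examples
#' ml_discrepancy(matrix(1), matrix(2))  # log 2 + 1/2 - 1
#' @export
ml_discrepancy <- function(S_mat, Sigma) {
  S_mat <- as.matrix(S_mat); Sigma <- as.matrix(Sigma)
  stopifnot(nrow(S_mat) == ncol(S_mat), all(dim(S_mat) == dim(Sigma)))
  cS <- tryCatch(chol(S_mat),
                 error = function(e) stop("sample covariance is not positive definite",
                                          call. = FALSE))
  cSig <- tryCatch(chol(Sigma),
                   error = function(e) stop("implied covariance is not positive definite",
                                            call. = FALSE))
  p <- nrow(S_mat)
  2 * sum(log(diag(cSig))) - 2 * sum(log(diag(cS))) +
    sum(chol2inv(cSig) * S_mat) - p
}

# ---------------------------------------------------------------------------
# Objective/gradient builder on the internal theta scale.
#
# Sigma(theta) = D M D with M = Lambda Phi Lambda' + Psi, Lambda = C • B.
# For any discrepancy F with matrix gradient G = dF/dSigma (symmetric),
# dF/dtheta_i = <G, dSigma/dtheta_i>.  With D free, dSigma = D dM D for
# M-parameters, so their gradients use H = D G D; the log-D block has
# dF/dlogd_i = 2 d_i [G D M]_{ii}.  Under the unit-diagonal-core variant,
# D = diag(M)^{-1/2} depends on M and contributes diag(w) to H with
# w_i = -[G D M]_{ii} d_i^3.
#
# Non-PD Sigma (possible through the free Psi off-diagonals) is handled by
# a smooth barrier: F = penalty * (1 - lambda_min), G = -penalty * v v'
# with v the eigenvector of the smallest eigenvalue, which pushes the
# iterate back toward the PD cone.
# ---------------------------------------------------------------------------

make_objective <- function(S_mat, model, layout, method = c("ml", "gls", "ols"),
                           map = par_map(model, layout),
                           pd_penalty = 1e8) {
  method <- match.arg(method)
  S_mat <- as.matrix(S_mat)
  JK <- map$JK
  stopifnot(nrow(S_mat) == JK, ncol(S_mat) == JK)

  const_lds <- NULL
  Winv <- NULL
  if (method == "ml") {
    cS <- tryCatch(chol(S_mat),
                   error = function(e) stop("sample covariance is not positive definite",
                                            call. = FALSE))
    const_lds <- 2 * sum(log(diag(cS)))
  } else if (method == "gls") {
    cS <- tryCatch(chol(S_mat),
                   error = function(e) stop("sample covariance is not positive definite",
                                            call. = FALSE))
    Winv <- chol2inv(cS)
  } else {
    Winv <- diag(JK)
  }

  variant_a <- model$invariance == "sigma_unit_diag"
  has_logd <- length(map$idx$logd) > 0L

  # core evaluation shared by fn and gr
  evaluate <- function(theta, want_grad) {
    m <- theta_decode(theta, map)
    Lambda <- khatri_rao(m$C, m$B)
    U <- Lambda %*% m$Phi
    M <- U %*% t(Lambda) + m$Psi
    if (!all(is.finite(M))) {
      # numeric overflow far outside the feasible region: a coercive
      # quadratic surrogate pulls the iterate back
      fval <- pd_penalty * (1 + 0.5 * sum(theta^2))
      if (!want_grad) return(list(value = fval))
      return(list(value = fval, overflow = TRUE,
                  grad = pd_penalty * theta))
    }
    d <- if (variant_a) {
      dm <- diag(M)
      if (any(dm <= 0)) NULL else 1 / sqrt(dm)
    } else m$d
    if (is.null(d)) {
      # diag(M) <= 0: treat like a PD failure on M itself
      ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
      lmin <- ev$values[length(ev$values)]
      fval <- pd_penalty * (1 - lmin)
      if (!want_grad) return(list(value = fval))
      v <- ev$vectors[, length(ev$values)]
      return(list(value = fval, G = -pd_penalty * tcrossprod(v),
                  m = m, Lambda = Lambda, U = U, M = M,
                  d = rep(1, JK), barrier = TRUE))
    }
    Sigma <- M * tcrossprod(d)
    if (!all(is.finite(Sigma))) {
      fval <- pd_penalty * (1 + 0.5 * sum(theta^2))
      if (!want_grad) return(list(value = fval))
      return(list(value = fval, overflow = TRUE,
                  grad = pd_penalty * theta))
    }
    Sigma <- (Sigma + t(Sigma)) / 2
    cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cSig)) {
      ev <- eigen(Sigma, symmetric = TRUE)
      lmin <- ev$values[length(ev$values)]
      fval <- pd_penalty * (1 - lmin)
      if (!want_grad) return(list(value = fval))
      v <- ev$vectors[, length(ev$values)]
      return(list(value = fval, G = -pd_penalty * tcrossprod(v),
                  m = m, Lambda = Lambda, U = U, M = M, d = d))
    }
    if (method == "ml") {
      Siginv <- chol2inv(cSig)
      fval <- 2 * sum(log(diag(cSig))) - const_lds + sum(Siginv * S_mat) - JK
      if (!want_grad) return(list(value = fval))
      G <- Siginv - Siginv %*% S_mat %*% Siginv
    } else {
      R <- S_mat - Sigma
      A <- R %*% Winv
      fval <- sum(A * t(A)) / 2
      if (!want_grad) return(list(value = fval))
      G <- -(Winv %*% R %*% Winv)
    }
    G <- (G + t(G)) / 2
    list(value = fval, G = G, m = m, Lambda = Lambda, U = U, M = M, d = d)
  }

  fn <- function(theta) evaluate(theta, want_grad = FALSE)$value

  gr <- function(theta) {
    e <- evaluate(theta, want_grad = TRUE)
    if (isTRUE(e$overflow)) return(e$grad)
    G <- e$G; m <- e$m; d <- e$d
    M <- e$M; Lambda <- e$Lambda; U <- e$U
    idx <- map$idx
    grad <- numeric(map$n_theta)

    # [G D M]_{ii} (needed for logd and the variant-a chain term)
    GD <- sweep(G, 2, d, "*")
    gdm_diag <- rowSums(GD * M)  # M symmetric

    if (has_logd) grad[idx$logd] <- 2 * d * gdm_diag

    H <- G * tcrossprod(d)
    if (variant_a && !isTRUE(e$barrier)) {
      H <- H + diag(-gdm_diag * d^3, JK)
    }

    # loading blocks: V = H U; grad B[j,s] = 2 (V_s %*% c_s)[j]
    V <- H %*% U
    S <- map$S; J <- map$J; K <- map$K
    gB <- matrix(0, J, S); gC <- matrix(0, K, S)
    for (s in seq_len(S)) {
      Vs <- matrix(V[, s], J, K)
      gB[, s] <- 2 * (Vs %*% m$C[, s])
      gC[, s] <- 2 * crossprod(Vs, m$B[, s])
    }
    if (map$first_row_fixed) {
      grad[idx$B] <- as.vector(gB[-1, , drop = FALSE])
      grad[idx$C] <- as.vector(gC[-1, , drop = FALSE])
    } else {
      grad[idx$B] <- as.vector(gB)
      grad[idx$C] <- as.vector(gC)
    }

    # Phi block
    W2 <- crossprod(Lambda, H %*% Lambda)
    if (model$phi_structure == "orthogonal") {
      grad[idx$phi] <- diag(W2) * m$phi_diag
    } else {
      GL <- 2 * W2 %*% m$L
      GL[upper.tri(GL)] <- 0
      diag(GL) <- diag(GL) * diag(m$L)  # chain through log-diagonal
      grad[idx$phi] <- GL[lower_tri_pairs(S)]
    }

    # Psi blocks
    if (length(idx$logpsi)) grad[idx$logpsi] <- diag(H) * m$psi_diag
    if (nrow(map$off_pairs)) grad[idx$psioff] <- 2 * H[map$off_pairs]

    grad
  }

  list(fn = fn, gr = gr, map = map)
}
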