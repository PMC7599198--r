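# Internal unconstrained parameterization used by the optimizer.
#
# theta is a flat vector with blocks, in order:
#   logd     log diagonal of D            (invariance "psi_unit_diag" only)
#   B        free entries of B, column-major; under "first_row_unit" rows
#            2..J only (row 1 fixed at 1), otherwise all J rows
#   C        free entries of C, likewise
#   phi      orthogonal: log of diag(Phi); oblique: log-Cholesky factor of
#            Phi, lower triangle column-major with log-transformed diagonal
#   logpsi   log diagonal of Psi          (absent when fixed at 1)
#   psioff   free off-diagonal entries of Psi on the declared support
#            (upper triangle, raw scale)
#
# Positive-definiteness of Phi and positivity of D and diag(Psi) are built
# into the transform; Psi (and hence Sigma) can leave the PD cone through
# psioff, which the objective handles with a smooth eigenvalue barrier.
# Under "unit_column_norm" the internal B and C are deliberately
# unnormalized (the column norms are absorbed into Phi on extraction), so
# theta is overparameterized along scaling directions; this is harmless for
# function minimization and avoids constraints.

par_map <- function(model, layout) {
  J <- layout$J; K <- layout$K; S <- model$S
  JK <- J * K
  first_row_fixed <- model$identification == "first_row_unit"
  n_logd <- if (model$invariance == "psi_unit_diag") JK else 0L
  nB <- if (first_row_fixed) (J - 1L) * S else J * S
  nC <- if (first_row_fixed) (K - 1L) * S else K * S
  n_phi <- if (model$phi_structure == "orthogonal") S else S * (S + 1L) / 2L
  n_logpsi <- if (model$invariance == "psi_unit_diag") 0L else JK
  off_pairs <- psi_off_support_pairs(model$psi_structure, layout)
  n_off <- nrow(off_pairs)
  sizes <- c(logd = n_logd, B = nB, C = nC, phi = n_phi,
             logpsi = n_logpsi, psioff = n_off)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  idx <- Map(function(a, b) if (b < a) integer(0) else seq.int(a, b),
             starts, ends)
  names(idx) <- names(sizes)
  # box bounds for the optimizer: log-scale blocks capped to avoid overflow
  lower <- rep(-Inf, ends[["psioff"]])
  upper <- rep(Inf, ends[["psioff"]])
  for (blk in c("logd", "phi", "logpsi")) {
    lower[idx[[blk]]] <- -20
    upper[idx[[blk]]] <- 20
  }
  list(model = model, layout = layout, J = J, K = K, S = S, JK = JK,
       first_row_fixed = first_row_fixed, idx = idx,
       n_theta = unname(ends[["psioff"]]),
       off_pairs = off_pairs, lower = lower, upper = upper)
}

# lower-triangle (column-major, including diagonal) index pairs of an S x S
# matrix
lower_tri_pairs <- function(S) {
  idx <- which(lower.tri(diag(S), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

# decode theta into raw parameter matrices (no D resolution for variant a,
# which implied_covariance/objective handle)
theta_decode <- function(theta, map) {
  model <- map$model
  J <- map$J; K <- map$K; S <- map$S; JK <- map$JK
  idx <- map$idx

  d <- if (length(idx$logd)) exp(theta[idx$logd]) else rep(1, JK)

  decode_loading <- function(v, n) {
    if (map$first_row_fixed) rbind(1, matrix(v, n - 1L, S))
    else matrix(v, n, S)
  }
  B <- decode_loading(theta[idx$B], J)
  C <- decode_loading(theta[idx$C], K)

  if (model$phi_structure == "orthogonal") {
    phi_diag <- exp(theta[idx$phi])
    Phi <- diag(phi_diag, S)
    L <- NULL
  } else {
    L <- matrix(0, S, S)
    lt <- lower_tri_pairs(S)
    L[lt] <- theta[idx$phi]
    diag(L) <- exp(diag(L))
    Phi <- tcrossprod(L)
    phi_diag <- NULL
  }

  psi_diag <- if (length(idx$logpsi)) exp(theta[idx$logpsi]) else rep(1, JK)
  Psi <- diag(psi_diag, JK)
  if (nrow(map$off_pairs)) {
    Psi[map$off_pairs] <- theta[idx$psioff]
    Psi[map$off_pairs[, 2:1, drop = FALSE]] <- theta[idx$psioff]
  }
  list(B = B, C = C, Phi = Phi, L = L, phi_diag = phi_diag,
       Psi = Psi, psi_diag = psi_diag, d = d)
}

theta_to_params <- function(theta, map) {
  m <- theta_decode(theta, map)
  d <- m$d
  if (map$model$invariance == "sigma_unit_diag") {
    Lambda <- khatri_rao(m$C, m$B)
    M <- Lambda %*% m$Phi %*% t(Lambda) + m$Psi
    d <- 1 / sqrt(diag(M))
  }
  parafac_params(B = m$B, C = m$C, Phi = m$Phi, Psi = m$Psi, D = d)
}

# encode a parameter set into theta (inverse of theta_to_params for free
# blocks; variant-a D is dropped since it is derived)
params_to_theta <- function(params, map) {
  model <- map$model
  theta <- numeric(map$n_theta)
  idx <- map$idx
  if (length(idx$logd)) theta[idx$logd] <- log(params$d)
  strip_first <- function(M) {
    if (map$first_row_fixed) as.vector(M[-1, , drop = FALSE]) else as.vector(M)
  }
  theta[idx$B] <- strip_first(params$B)
  theta[idx$C] <- strip_first(params$C)
  if (model$phi_structure == "orthogonal") {
    theta[idx$phi] <- log(diag(params$Phi))
  } else {
    L <- t(chol(params$Phi))
    diag(L) <- log(diag(L))
    theta[idx$phi] <- L[lower_tri_pairs(map$S)]
  }
  if (length(idx$logpsi)) theta[idx$logpsi] <- log(diag(params$Psi))
  if (nrow(map$off_pairs)) theta[idx$psioff] <- params$Psi[map$off_pairs]
  theta
}

# natural-scale free parameters with names, for reporting and the delta
# method: D diagonal, free loading entries, Phi entries (diagonal or lower
# triangle), free Psi entries
natural_from_theta <- function(theta, map) {
  m <- theta_decode(theta, map)
  model <- map$model; layout <- map$layout
  lab <- composite_labels(layout)
  out <- numeric(0)
  if (length(map$idx$logd)) {
    d <- m$d
    names(d) <- paste0("d[", lab, "]")
    out <- c(out, d)
  }
  load_entries <- function(M, labels, what) {
    rows <- if (map$first_row_fixed) seq_len(nrow(M))[-1] else seq_len(nrow(M))
    v <- as.vector(M[rows, , drop = FALSE])
    nm <- as.vector(outer(labels[rows], seq_len(ncol(M)),
                          function(r, s) paste0(what, "[", r, ",", s, "]")))
    stats::setNames(v, nm)
  }
  out <- c(out, load_entries(m$B, layout$variable_labels, "B"))
  out <- c(out, load_entries(m$C, layout$occasion_labels, "C"))
  if (model$phi_structure == "orthogonal") {
    v <- diag(m$Phi)
    names(v) <- paste0("phi[", seq_len(map$S), ",", seq_len(map$S), "]")
    out <- c(out, v)
  } else {
    lt <- lower_tri_pairs(map$S)
    v <- m$Phi[lt]
    names(v) <- paste0("phi[", lt[, 1], ",", lt[, 2], "]")
    out <- c(out, v)
  }
  if (length(map$idx$logpsi)) {
    v <- m$psi_diag
    names(v) <- paste0("psi[", lab, ",", lab, "]")
    out <- c(out, v)
  }
  if (nrow(map$off_pairs)) {
    v <- m$Psi[map$off_pairs]
    names(v) <- paste0("psi[", lab[map$off_pairs[, 1]], ",",
                       lab[map$off_pairs[, 2]], "]")
    out <- c(out, v)
  }
  out
}

# random starting vector: i.i.d. centered draws at the given scale on the
# internal (unconstrained) parameter scale
random_theta <- function(map, scale = 0.5) {
  stats::rnorm(map$n_theta, mean = 0, sd = scale)
}

# report parameters under the model's identification convention: under
# unit_column_norm, normalize the columns of B and C and absorb the norms
# into Phi (Sigma is unchanged); fix signs so each column of B has a
# positive entry of largest magnitude
standardize_params <- function(params, model) {
  if (model$identification != "unit_column_norm") return(params)
  B <- params$B; C <- params$C; Phi <- params$Phi
  nb <- sqrt(colSums(B^2)); nc <- sqrt(colSums(C^2))
  if (any(nb == 0) || any(nc == 0))
    stop("cannot normalize a zero column of B or C", call. = FALSE)
  B <- sweep(B, 2, nb, "/")
  C <- sweep(C, 2, nc, "/")
  sb <- vapply(seq_len(ncol(B)), function(s) {
    v <- B[, s]; sign(v[which.max(abs(v))])
  }, numeric(1))
  sc <- vapply(seq_len(ncol(C)), function(s) {
    v <- C[, s]; sign(v[which.max(abs(v))])
  }, numeric(1))
  B <- sweep(B, 2, sb, "*")
  C <- sweep(C, 2, sc, "*")
  scl <- nb * nc * sb * sc
  Phi <- Phi * tcrossprod(scl)
  parafac_params(B = B, C = C, Phi = Phi, Psi = params$Psi, D = params$d)
}
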