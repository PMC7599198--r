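#' Specify a structural Parafac covariance model
#'
#' The structural Parafac model expresses the `JK x JK` covariance matrix of
#' `J` variables observed at `K` occasions as
#' \deqn{\Sigma = D[(C \bullet B)\Phi(C \bullet B)' + \Psi]D,}
#' where `B` (`J x S`) and `C` (`K x S`) are the variable and occasion
#' loading matrices, `\bullet` is the Khatri-Rao product, `\Phi` (`S x S`) is
#' the common-factor covariance, `\Psi` (`JK x JK`) the specific-factor
#' covariance, and `D` a positive diagonal scaling matrix that makes the
#' model scale invariant.
#'
#' @param n_factors number of common factors `S` (at least 1).
#' @param phi_structure `"orthogonal"` (diagonal `\Phi`) or `"oblique"`
#'   (unstructured positive definite `\Phi`).
#' @param psi_structure structure of the specific-factor covariance:
#'   `"diagonal"` (uncorrelated specific factors),
#'   `"block_within_occasion"` (specific factors of different variables may
#'   correlate within the same occasion; `\Psi` is block diagonal with `K`
#'   blocks of order `J`), or `"banded_within_variable"` (specific factors of
#'   the same variable may correlate across occasions).
#' @param invariance scale-invariance variant: `"none"` (no `D`, `D = I`),
#'   `"sigma_unit_diag"` (variant (a): `D` absorbs scale and the core matrix
#'   `(C • B)\Phi(C • B)' + \Psi` is constrained to unit diagonal, so the
#'   model reparameterizes a correlation matrix), or `"psi_unit_diag"`
#'   (variant (b): `D` is free and `\Psi` has unit diagonal).
#' @param identification convention fixing the column scaling of the
#'   loadings: `"unit_column_norm"` (columns of `B` and `C` have unit
#'   Euclidean norm) or `"first_row_unit"` (first row of `B` and of `C`
#'   fixed to ones, as in the multitrait-multimethod application).
#'
#' @return An object of class `"parafac_model"`.
#' @examples
#' parafac_model(3, "orthogonal", "banded_within_variable",
#'               invariance = "psi_unit_diag",
#'               identification = "first_row_unit")
#' @export
parafac_model <- function(n_factors,
                          phi_structure = c("orthogonal", "oblique"),
                          psi_structure = c("diagonal",
                                            "block_within_occasion",
                                            "banded_within_variable"),
                          invariance = c("none", "sigma_unit_diag",
                                         "psi_unit_diag"),
                          identification = c("unit_column_norm",
                                             "first_row_unit")) {
  S <- as.integer(n_factors)
  if (length(S) != 1L || is.na(S) || S < 1L)
    stop("`n_factors` must be a single integer >= 1", call. = FALSE)
  structure(
    list(S = S,
         phi_structure = match.arg(phi_structure),
         psi_structure = match.arg(psi_structure),
         invariance = match.arg(invariance),
         identification = match.arg(identification)),
    class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat("Structural Parafac model\n")
  cat("  factors:       S =", x$S, paste0("(", x$phi_structure, ")"), "\n")
  cat("  specific cov:  ", x$psi_structure, "\n")
  cat("  invariance:    ", x$invariance, "\n")
  cat("  identification:", x$identification, "\n")
  invisible(x)
}

#' Bundle the parameter matrices of a structural Parafac model
#'
#' @param B variable loading matrix, `J x S`.
#' @param C occasion loading matrix, `K x S`.
#' @param Phi common-factor covariance, `S x S` symmetric positive definite.
#' @param Psi specific-factor covariance, `JK x JK` symmetric positive
#'   definite with zeros off the support declared by the model's
#'   `psi_structure`.
#' @param D diagonal scaling: either a length-`JK` positive vector or `NULL`
#'   (identity; also the placeholder under invariance `"sigma_unit_diag"`,
#'   where `D` is determined by the unit-diagonal constraint).
#' @return An object of class `"parafac_params"` (a list with elements `B`,
#'   `C`, `Phi`, `Psi`, `d` where `d = diag(D)`).
#' @export
parafac_params <- function(B, C, Phi, Psi, D = NULL) {
  B <- as.matrix(B); C <- as.matrix(C)
  Phi <- as.matrix(Phi); Psi <- as.matrix(Psi)
  S <- ncol(B)
  if (ncol(C) != S || nrow(Phi) != S || ncol(Phi) != S)
    stop("inconsistent factor dimensions among B, C, Phi", call. = FALSE)
  JK <- nrow(B) * nrow(C)
  if (nrow(Psi) != JK || ncol(Psi) != JK)
    stop("Psi must be ", JK, " x ", JK, call. = FALSE)
  d <- if (is.null(D)) rep(1, JK) else {
    d <- if (is.matrix(D)) diag(D) else as.numeric(D)
    if (length(d) != JK) stop("D must have ", JK, " diagonal entries",
                              call. = FALSE)
    if (any(d <= 0)) stop("D must have strictly positive diagonal entries",
                          call. = FALSE)
    d
  }
  structure(list(B = B, C = C, Phi = Phi, Psi = Psi, d = d),
            class = "parafac_params")
}

#' @export
print.parafac_params <- function(x, digits = 3, ...) {
  cat("Parafac parameter set: J =", nrow(x$B), ", K =", nrow(x$C),
      ", S =", ncol(x$B), "\n")
  cat("B (variables):\n"); print(round(x$B, digits))
  cat("C (occasions):\n"); print(round(x$C, digits))
  cat("Phi:\n"); print(round(x$Phi, digits))
  cat("diag(D):", round(x$d, digits), "\n")
  invisible(x)
}

#' Support pattern of the specific-factor covariance
#'
#' Returns the set of entries of `\Psi` allowed to be nonzero under a given
#' structure, as a logical `JK x JK` matrix.  The diagonal is always in the
#' support.  `"block_within_occasion"` adds pairs of composite indices
#' sharing the occasion (`k == k'`, `j != j'`); `"banded_within_variable"`
#' adds pairs sharing the variable (`j == j'`, `k != k'`).  The support is
#' symmetric.
#'
#' @param psi_structure one of `"diagonal"`, `"block_within_occasion"`,
#'   `"banded_within_variable"`.
#' @param layout a [three_way_layout()].
#' @return Logical `JK x JK` matrix, `TRUE` where `\Psi` may be nonzero.
#' @export
psi_support <- function(psi_structure, layout) {
  stopifnot(inherits(layout, "three_way_layout"))
  psi_structure <- match.arg(psi_structure,
                             c("diagonal", "block_within_occasion",
                               "banded_within_variable"))
  g <- composite_grid(layout)
  JK <- layout$J * layout$K
  same_j <- outer(g[, "j"], g[, "j"], "==")
  same_k <- outer(g[, "k"], g[, "k"], "==")
  supp <- switch(psi_structure,
                 diagonal = same_j & same_k,
                 block_within_occasion = same_k,
                 banded_within_variable = same_j)
  dimnames(supp) <- list(composite_labels(layout), composite_labels(layout))
  supp
}

# indices (i, j), i < j, of the free off-diagonal entries of Psi
psi_off_support_pairs <- function(psi_structure, layout) {
  supp <- psi_support(psi_structure, layout)
  idx <- which(supp & upper.tri(supp), arr.ind = TRUE)
  idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
}

#' Model-implied covariance matrix
#'
#' Computes `\Sigma(\theta) = D[(C • B)\Phi(C • B)' + \Psi]D`.  Under
#' invariance `"sigma_unit_diag"`, `D` is not free but determined by the
#' constraint that the bracketed core matrix has unit diagonal, i.e.
#' `D = diag(M)^{-1/2}` with `M = (C • B)\Phi(C • B)' + \Psi`; any `D`
#' stored in `params` is ignored in that case.
#'
#' @param params a [parafac_params()] set.
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @return Symmetric `JK x JK` matrix with composite-label dimnames.
#' @export
implied_covariance <- function(params, model, layout) {
  stopifnot(inherits(params, "parafac_params"),
            inherits(model, "parafac_model"),
            inherits(layout, "three_way_layout"))
  if (nrow(params$B) != layout$J || nrow(params$C) != layout$K ||
      ncol(params$B) != model$S)
    stop("parameter dimensions do not match model/layout", call. = FALSE)
  Lambda <- khatri_rao(params$C, params$B)
  M <- Lambda %*% params$Phi %*% t(Lambda) + params$Psi
  d <- switch(model$invariance,
              none = rep(1, nrow(M)),
              sigma_unit_diag = 1 / sqrt(diag(M)),
              psi_unit_diag = params$d)
  Sigma <- M * tcrossprod(d)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(composite_labels(layout), composite_labels(layout))
  Sigma
}

#' Count the free parameters of a model
#'
#' Returns the number of free parameters `q` used for degrees of freedom
#' (`df = JK(JK+1)/2 - q`) and information criteria.  Defined for the
#' parameterizations the package estimates:
#' \itemize{
#'   \item `identification = "first_row_unit"`, `invariance =
#'     "psi_unit_diag"`: `JK` (diagonal of `D`) + `(J-1)S` + `(K-1)S`
#'     (loadings below the fixed first rows) + `S` (orthogonal) or
#'     `S(S+1)/2` (oblique) for `\Phi` + the free off-diagonal support of
#'     `\Psi` (its diagonal being fixed at 1).
#'   \item `invariance = "none"`: no `D`; the `\Psi` diagonal is free
#'     (`JK` more parameters); under `"unit_column_norm"` each loading
#'     matrix loses `S` parameters to the column-norm constraints.
#' }
#' Other combinations raise an error rather than return a guess.
#'
#' @inheritParams implied_covariance
#' @return Integer count of free parameters.
#' @examples
#' layout <- three_way_layout(4, 3)
#' count_parameters(parafac_model(2, "orthogonal", "diagonal",
#'   invariance = "psi_unit_diag", identification = "first_row_unit"),
#'   layout)  # 24
#' @export
count_parameters <- function(model, layout) {
  stopifnot(inherits(model, "parafac_model"),
            inherits(layout, "three_way_layout"))
  J <- layout$J; K <- layout$K; S <- model$S
  JK <- J * K
  n_phi <- if (model$phi_structure == "orthogonal") S else S * (S + 1L) / 2L
  n_psi_off <- nrow(psi_off_support_pairs(model$psi_structure, layout))
  if (model$invariance == "psi_unit_diag" &&
      model$identification == "first_row_unit") {
    return(as.integer(JK + (J - 1L) * S + (K - 1L) * S + n_phi + n_psi_off))
  }
  if (model$invariance == "none") {
    n_load <- switch(model$identification,
                     first_row_unit = (J - 1L) * S + (K - 1L) * S,
                     unit_column_norm = J * S - S + K * S - S)
    return(as.integer(n_load + n_phi + JK + n_psi_off))
  }
  stop("parameter counting is not defined for invariance '",
       model$invariance, "' with identification '", model$identification,
       "'", call. = FALSE)
}

#' Rescale the observed variables of a parameter set
#'
#' Applies the measurement-unit change `x -> (L_O %x% L_V) x`, where `L_V`
#' rescales the variables (same factor at every occasion) and `L_O` the
#' occasions.  Without a scaling matrix (`invariance = "none"`) the change
#' propagates into the loadings and the specific-factor covariance,
#' `B -> L_V B`, `C -> L_O C`, `\Psi -> L \Psi L`; under the scale-invariant
#' variants it is absorbed entirely by `D -> L D`.  In both cases the
#' implied covariance transforms as `\Sigma -> L \Sigma L`.
#'
#' @param params a [parafac_params()] set.
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @param l_v length-`J` vector of strictly positive variable scale factors.
#' @param l_o length-`K` vector of strictly positive occasion scale factors.
#' @return A rescaled [parafac_params()] set.
#' @export
rescale <- function(params, model, layout, l_v, l_o) {
  stopifnot(inherits(params, "parafac_params"),
            inherits(model, "parafac_model"),
            inherits(layout, "three_way_layout"))
  l_v <- as.numeric(l_v); l_o <- as.numeric(l_o)
  if (length(l_v) != layout$J || length(l_o) != layout$K)
    stop("scale vectors must have lengths J and K", call. = FALSE)
  if (any(l_v <= 0) || any(l_o <= 0))
    stop("scale factors must be strictly positive", call. = FALSE)
  l <- as.vector(outer(l_v, l_o))  # composite order, variable fastest
  if (model$invariance == "none") {
    parafac_params(B = params$B * l_v, C = params$C * l_o,
                   Phi = params$Phi,
                   Psi = params$Psi * tcrossprod(l),
                   D = NULL)
  } else {
    parafac_params(B = params$B, C = params$C, Phi = params$Phi,
                   Psi = params$Psi, D = params$d * l)
  }
}

# validate a parameter set against the model's structural constraints;
# returns invisibly or stops with the first violation found
validate_params <- function(params, model, layout, tol = 1e-8) {
  if (max(abs(params$Phi - t(params$Phi))) > tol)
    stop("Phi is not symmetric", call. = FALSE)
  if (inherits(try(chol(params$Phi), silent = TRUE), "try-error"))
    stop("Phi is not positive definite", call. = FALSE)
  if (model$phi_structure == "orthogonal" &&
      max(abs(params$Phi - diag(diag(params$Phi), nrow(params$Phi)))) > tol)
    stop("orthogonal model requires diagonal Phi", call. = FALSE)
  supp <- psi_support(model$psi_structure, layout)
  if (max(abs(params$Psi[!supp])) > tol)
    stop("Psi has entries off the declared support", call. = FALSE)
  if (inherits(try(chol(params$Psi), silent = TRUE), "try-error"))
    stop("Psi is not positive definite", call. = FALSE)
  if (model$invariance == "psi_unit_diag" &&
      max(abs(diag(params$Psi) - 1)) > tol)
    stop("invariance 'psi_unit_diag' requires diag(Psi) = 1", call. = FALSE)
  if (model$identification == "first_row_unit") {
    if (max(abs(params$B[1, ] - 1)) > tol || max(abs(params$C[1, ] - 1)) > tol)
      stop("first_row_unit identification requires unit first rows of B and C",
           call. = FALSE)
  }
  invisible(TRUE)
}
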