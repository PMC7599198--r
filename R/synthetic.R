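#' Draw a random parameter set satisfying the uniqueness conditions
#'
#' Generates a generic structural Parafac parameter set and
#' rejection-samples until the runnable uniqueness conditions relevant to
#' the model's specific-factor structure hold ([uniqueness_report()]):
#' the reduced Kruskal inequality together with the row-deletion condition
#' (diagonal `\Psi`), the three-full-rank-occasions condition
#' (within-occasion blocks) or its within-variable mirror image (banded).
#' Loading entries are drawn uniformly on `[-1, 1]` before the
#' identification convention is applied; `\Phi` is a scaled Wishart-type
#' positive definite draw (or its diagonal under orthogonality); free
#' `\Psi` off-diagonal correlations are drawn moderately and checked for
#' positive definiteness; free `D` entries are uniform on `[0.5, 1.5]`.
#'
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @param seed optional integer seed (`NULL` leaves the RNG state alone).
#' @param max_tries rejection-sampling budget.
#' @param tol rank tolerance forwarded to the condition checkers.
#' @return A [parafac_params()] set whose [uniqueness_report()] has
#'   `relevant_satisfied = TRUE`.
#' @export
draw_identifiable_params <- function(model, layout, seed = NULL,
                                     max_tries = 100L, tol = 1e-8) {
  stopifnot(inherits(model, "parafac_model"),
            inherits(layout, "three_way_layout"))
  if (!is.null(seed)) set.seed(seed)
  J <- layout$J; K <- layout$K; S <- model$S
  JK <- J * K
  # quick infeasibility screens before burning the retry budget
  if (k_rank_bound(J, S) + k_rank_bound(K, S) < S + 2)
    stop("uniqueness conditions unattainable: max attainable ",
         "k-rank(B) + k-rank(C) = ", k_rank_bound(J, S) + k_rank_bound(K, S),
         " < S + 2 = ", S + 2, call. = FALSE)
  if (model$psi_structure == "diagonal" && JK < 2 * S + 1)
    stop("uniqueness conditions unattainable: row-deletion condition needs ",
         "JK >= 2S + 1", call. = FALSE)
  if (model$psi_structure == "block_within_occasion" && K < 3)
    stop("uniqueness conditions unattainable: needs at least 3 occasions",
         call. = FALSE)
  if (model$psi_structure == "banded_within_variable" && J < 3)
    stop("uniqueness conditions unattainable: needs at least 3 variables",
         call. = FALSE)

  draw_loading <- function(n) {
    M <- matrix(stats::runif(n * S, -1, 1), n, S)
    if (model$identification == "first_row_unit") M[1, ] <- 1
    else M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    M
  }
  supp_off <- psi_off_support_pairs(model$psi_structure, layout)
  for (try in seq_len(max_tries)) {
    B <- draw_loading(J)
    C <- draw_loading(K)
    Phi <- {
      A <- matrix(stats::rnorm(S * S), S)
      P <- tcrossprod(A) / S + 0.5 * diag(S)
      if (model$phi_structure == "orthogonal") diag(diag(P), S) else P
    }
    psi_diag <- if (model$invariance == "psi_unit_diag") rep(1, JK)
                else stats::runif(JK, 0.5, 1.5)
    Psi <- diag(psi_diag, JK)
    if (nrow(supp_off)) {
      rho <- stats::runif(nrow(supp_off), -0.3, 0.3)
      scl <- sqrt(psi_diag[supp_off[, 1]] * psi_diag[supp_off[, 2]])
      Psi[supp_off] <- rho * scl
      Psi[supp_off[, 2:1, drop = FALSE]] <- rho * scl
    }
    if (inherits(try(chol(Psi), silent = TRUE), "try-error")) next
    d <- if (model$invariance == "psi_unit_diag")
      stats::runif(JK, 0.5, 1.5) else NULL
    params <- parafac_params(B, C, Phi, Psi, D = d)
    rep_ok <- uniqueness_report(params, model, layout, tol = tol)
    if (rep_ok$relevant_satisfied) return(params)
  }
  stop("could not draw parameters satisfying the uniqueness conditions in ",
       max_tries, " tries (last failing condition: see uniqueness_report)",
       call. = FALSE)
}

# largest k-rank a generic n x S matrix can have
k_rank_bound <- function(n, S) min(n, S)

#' Sample covariance of multivariate normal draws from the model
#'
#' Draws `n` independent zero-mean multivariate normal vectors with
#' covariance `implied_covariance(params)` and returns their sample
#' covariance matrix (divisor `n - 1`).  By the law of large numbers the
#' result converges to the population matrix as `n` grows.  For
#' `n <= JK` the sample covariance is singular; it is still returned, with
#' attribute `"singular" = TRUE`.
#'
#' @param params a [parafac_params()] set.
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @param n sample size (at least 2).
#' @param seed optional integer seed.
#' @param return_data also return the raw `n x JK` data matrix.
#' @return The `JK x JK` sample covariance matrix; if `return_data`, a list
#'   with elements `S` and `X`.
#' @export
simulate_sample_cov <- function(params, model, layout, n, seed = NULL,
                                return_data = FALSE) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- implied_covariance(params, model, layout)
  R <- chol(Sigma)
  JK <- nrow(Sigma)
  X <- matrix(stats::rnorm(n * JK), n, JK) %*% R
  colnames(X) <- colnames(Sigma)
  S_mat <- stats::cov(X)
  if (n <= JK) attr(S_mat, "singular") <- TRUE
  if (return_data) list(S = S_mat, X = X) else S_mat
}

#' Generate a complete synthetic study
#'
#' Draws an identifiable true parameter set and a normal sample covariance
#' from its implied population covariance, bundling everything needed to
#' replay a recovery experiment: the truth, the model, the seed and the
#' generated sample.
#'
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @param n sample size.
#' @param seed integer seed (required: studies are meant to be replayable).
#' @return An object of class `"parafac_study"`: list with `true_params`,
#'   `population_cov`, `sample_cov`, `model`, `layout`, `n`, `seed`.
#' @export
parafac_study <- function(model, layout, n, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  true_params <- draw_identifiable_params(model, layout, seed = seed)
  sample_cov <- simulate_sample_cov(true_params, model, layout, n,
                                    seed = seed + 1L)
  structure(
    list(true_params = true_params,
         population_cov = implied_covariance(true_params, model, layout),
         sample_cov = sample_cov,
         model = model, layout = layout, n = as.integer(n),
         seed = as.integer(seed)),
    class = "parafac_study")
}

#' @export
print.parafac_study <- function(x, ...) {
  cat("Synthetic structural Parafac study (seed", x$seed, ", n =", x$n, ")\n")
  print(x$model)
  invisible(x)
}

#' Align an estimated solution with a reference up to permutation and sign
#'
#' Structural Parafac solutions are essentially unique: identified only up
#' to a simultaneous column permutation of `B` and `C` (with `\Phi`
#' permuted congruently) and, under the unit-column-norm convention, joint
#' column sign flips.  This exhaustively searches permutations (and sign
#' patterns where applicable) minimizing the total squared deviation of the
#' loading matrices from the reference, and returns the aligned estimate.
#'
#' @param est estimated [parafac_params()].
#' @param reference reference [parafac_params()] with the same dimensions.
#' @param model a [parafac_model()] (decides whether sign flips are
#'   searched).
#' @return List with `params` (aligned estimate), `permutation` (integer
#'   vector `p` such that aligned column `s` is estimated column `p[s]`),
#'   `signs_B`, `signs_C`, and `deviation` (the minimized sum of squares).
#' @export
align_solutions <- function(est, reference, model) {
  stopifnot(inherits(est, "parafac_params"),
            inherits(reference, "parafac_params"))
  S <- ncol(est$B)
  if (S != ncol(reference$B) || nrow(est$B) != nrow(reference$B) ||
      nrow(est$C) != nrow(reference$C))
    stop("solutions have different dimensions", call. = FALSE)
  if (S > 8L) stop("exhaustive permutation search refused for S > 8",
                   call. = FALSE)
  perms <- permutations_of(S)
  use_signs <- model$identification == "unit_column_norm"
  # per matched column, the best sign for B and for C can be chosen
  # independently (the product of the two signs is compensated in Phi)
  best <- NULL
  for (pi in seq_len(nrow(perms))) {
    p <- perms[pi, ]
    Bp <- est$B[, p, drop = FALSE]
    Cp <- est$C[, p, drop = FALSE]
    if (use_signs) {
      dev_plus_B <- colSums((Bp - reference$B)^2)
      dev_minus_B <- colSums((Bp + reference$B)^2)
      dev_plus_C <- colSums((Cp - reference$C)^2)
      dev_minus_C <- colSums((Cp + reference$C)^2)
      eB <- ifelse(dev_minus_B < dev_plus_B, -1, 1)
      eC <- ifelse(dev_minus_C < dev_plus_C, -1, 1)
      dev <- sum(pmin(dev_plus_B, dev_minus_B)) +
             sum(pmin(dev_plus_C, dev_minus_C))
    } else {
      eB <- eC <- rep(1, S)
      dev <- sum((Bp - reference$B)^2) + sum((Cp - reference$C)^2)
    }
    if (is.null(best) || dev < best$deviation)
      best <- list(p = p, eB = eB, eC = eC, deviation = dev)
  }
  p <- best$p
  B <- sweep(est$B[, p, drop = FALSE], 2, best$eB, "*")
  C <- sweep(est$C[, p, drop = FALSE], 2, best$eC, "*")
  ePhi <- best$eB * best$eC
  Phi <- est$Phi[p, p, drop = FALSE] * tcrossprod(ePhi)
  aligned <- parafac_params(B, C, Phi, est$Psi, D = est$d)
  list(params = aligned, permutation = p, signs_B = best$eB,
       signs_C = best$eC, deviation = best$deviation)
}

permutations_of <- function(S) {
  if (S == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(S - 1L)
  out <- matrix(0L, 0, S)
  for (pos in seq_len(S)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], S,
                            sub[, seq.int(pos, length.out = S - pos),
                                drop = FALSE]))
  }
  unname(out)
}
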