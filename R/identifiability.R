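# Runnable checkers for the factor-uniqueness conditions of the structural
# Parafac model: Kruskal's k-rank inequality, the row-deletion condition of
# Anderson & Rubin type for diagonal specific-factor covariances, and the
# per-occasion full-rank condition (Browne's multiple-battery argument) for
# block-diagonal ones.

# numerical column rank via singular values, relative tolerance
num_rank <- function(M, tol = 1e-8) {
  if (length(M) == 0) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  if (d[1] <= 0) return(0L)
  sum(d > tol * d[1])
}

#' Kruskal rank (k-rank) of a matrix
#'
#' The k-rank of `M` is the largest `k` such that *every* subset of `k`
#' columns of `M` is linearly independent.  Computed by exhaustive subset
#' enumeration with numerical rank decided from singular values at relative
#' tolerance `tol` (k-rank is a discontinuous quantity, so the tolerance is
#' surfaced).  Returns 0 when some single column is numerically zero.
#' Intended for the small matrices of this model class; refuses more than
#' `max_cols` columns.
#'
#' @param M numeric matrix (nonempty).
#' @param tol relative singular-value tolerance, `> 0`.
#' @param max_cols guard on the exhaustive enumeration.
#' @return Integer k-rank, between 0 and `ncol(M)`.
#' @examples
#' k_rank(diag(3))                      # 3
#' k_rank(matrix(c(1, 2, 1, 2), 2))     # 1: duplicated column direction
#' @export
k_rank <- function(M, tol = 1e-8, max_cols = 12L) {
  M <- as.matrix(M)
  if (length(M) == 0) stop("`M` must be nonempty", call. = FALSE)
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  n <- ncol(M)
  if (n > max_cols)
    stop("exhaustive k-rank enumeration refused for more than ", max_cols,
         " columns", call. = FALSE)
  kr <- 0L
  for (k in seq_len(min(n, nrow(M)))) {
    subsets <- utils::combn(n, k)
    all_full <- all(apply(subsets, 2, function(cols)
      num_rank(M[, cols, drop = FALSE], tol) == k))
    if (!all_full) break
    kr <- k
  }
  kr
}

#' Kruskal's uniqueness condition
#'
#' Checks the inequality `kA + kB + kC >= 2S + 2` that guarantees essential
#' uniqueness of an `S`-component Parafac decomposition.  In the structural
#' model the first factor matrix is `Phi^{1/2}`, which has k-rank `S`
#' whenever `Phi` is positive definite; with `kA = S` the inequality reduces
#' to `k_rank(B) + k_rank(C) >= S + 2`.
#'
#' @param kA,kB,kC k-ranks of the three loading matrices (nonnegative).
#' @param S number of components.
#' @return Logical flag.
#' @export
kruskal_condition <- function(kA, kB, kC, S) {
  stopifnot(kA >= 0, kB >= 0, kC >= 0, S >= 1)
  (kA + kB + kC) >= (2 * S + 2)
}

#' Row-deletion uniqueness condition (diagonal specific factors)
#'
#' Checks the Anderson-Rubin-type condition for a `JK x S` factor loading
#' matrix: after deleting *any* single row, the remaining rows can be split
#' into two disjoint row sets each of full column rank `S`.  The search
#' enumerates `S`-subsets of the remaining rows; a subset of rank `S` whose
#' complementary rows also have rank `S` witnesses the partition.  Needs at
#' least `2S + 1` rows to be satisfiable.
#'
#' @param Lambda numeric loading matrix with `S = ncol(Lambda)` columns.
#' @param tol relative singular-value tolerance.
#' @return Logical flag; attribute `"reason"` explains a `FALSE` verdict.
#' @export
row_deletion_condition <- function(Lambda, tol = 1e-8) {
  Lambda <- as.matrix(Lambda)
  n <- nrow(Lambda); S <- ncol(Lambda)
  if (n < 2 * S + 1) {
    return(structure(FALSE,
      reason = sprintf("only %d rows; at least 2S+1 = %d needed", n,
                       2 * S + 1)))
  }
  if (n > 30L || S > 6L)
    stop("exhaustive row-deletion search refused beyond 30 rows / 6 columns",
         call. = FALSE)
  for (drop_row in seq_len(n)) {
    remaining <- setdiff(seq_len(n), drop_row)
    found <- FALSE
    for (cols in seq_len(ncol(sub <- utils::combn(remaining, S)))) {
      set1 <- sub[, cols]
      if (num_rank(Lambda[set1, , drop = FALSE], tol) < S) next
      set2 <- setdiff(remaining, set1)
      if (num_rank(Lambda[set2, , drop = FALSE], tol) == S) {
        found <- TRUE
        break
      }
    }
    if (!found) {
      return(structure(FALSE,
        reason = sprintf("no rank-%d partition after deleting row %d", S,
                         drop_row)))
    }
  }
  TRUE
}

#' Per-occasion full-rank condition (block-diagonal specific factors)
#'
#' For specific factors correlated within occasions, uniqueness follows from
#' the multiple-battery argument when at least three of the per-occasion
#' loading blocks `B diag(c_k)` have full column rank `S`.  Returns the
#' count of such occasions and the flag `count >= 3`.
#'
#' @param B variable loading matrix `J x S`.
#' @param C occasion loading matrix `K x S`; row `k` is `c_k`.
#' @param tol relative singular-value tolerance.
#' @return List with `count` and `satisfied`.
#' @export
occasion_rank_condition <- function(B, C, tol = 1e-8) {
  B <- as.matrix(B); C <- as.matrix(C)
  if (ncol(B) != ncol(C))
    stop("B and C must have the same number of columns", call. = FALSE)
  S <- ncol(B)
  count <- sum(vapply(seq_len(nrow(C)), function(k)
    num_rank(B %*% diag(C[k, ], S), tol) == S, logical(1)))
  list(count = as.integer(count), satisfied = count >= 3)
}

#' Uniqueness report for a structural Parafac parameter set
#'
#' Evaluates the runnable factor-uniqueness conditions on a parameter set:
#' the k-ranks of `B` and `C` and the reduced Kruskal inequality
#' `k_rank(B) + k_rank(C) >= S + 2` (condition (b) of both uniqueness
#' results); the row-deletion condition on the loading matrix (condition (c)
#' for diagonal `\Psi`); the per-occasion rank count (condition (c) for
#' within-occasion blocks); and, by the model's variable/occasion symmetry,
#' the per-variable rank count used for the within-variable banded
#' structure.  The loading matrix tested is `C • B` by default, or
#' `D (C • B) Phi^{1/2}` (`loadings = "scaled"`) for the scale-invariant
#' variants, whose uniqueness argument runs through the scaled loadings; for
#' full-rank `Phi` and positive `D` the two choices have equal row spaces.
#'
#' @param params a [parafac_params()] set.
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @param tol relative singular-value tolerance.
#' @param loadings which loading matrix the rank conditions are evaluated
#'   on: `"khatri_rao"` for `C • B`, `"scaled"` for `D (C • B) Phi^{1/2}`.
#' @return An object of class `"uniqueness_report"`: a list with fields
#'   `k_rank_B`, `k_rank_C`, `kruskal_lhs`, `kruskal_satisfied`,
#'   `row_deletion_satisfied`, `occasion_rank_count`, `result2_satisfied`,
#'   `variable_rank_count`, `banded_satisfied`, and `relevant_satisfied`
#'   (the conjunction of condition (b) with the condition (c) matching the
#'   model's `psi_structure`).
#' @export
uniqueness_report <- function(params, model, layout, tol = 1e-8,
                              loadings = c("khatri_rao", "scaled")) {
  stopifnot(inherits(params, "parafac_params"),
            inherits(model, "parafac_model"),
            inherits(layout, "three_way_layout"))
  loadings <- match.arg(loadings)
  S <- model$S
  kB <- k_rank(params$B, tol)
  kC <- k_rank(params$C, tol)
  kruskal_ok <- kruskal_condition(S, kB, kC, S)  # kA = k_rank(Phi^{1/2}) = S
  Lambda <- khatri_rao(params$C, params$B)
  if (loadings == "scaled") {
    e <- eigen(params$Phi, symmetric = TRUE)
    phi_half <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    Lambda <- params$d * (Lambda %*% phi_half)
  }
  rd <- row_deletion_condition(Lambda, tol)
  occ <- occasion_rank_condition(params$B, params$C, tol)
  # symmetric condition for the banded (within-variable) structure:
  # blocks indexed by variables, loadings C diag(b_j)
  var <- occasion_rank_condition(params$C, params$B, tol)
  relevant <- kruskal_ok && switch(model$psi_structure,
                                   diagonal = isTRUE(rd),
                                   block_within_occasion = occ$satisfied,
                                   banded_within_variable = var$satisfied)
  structure(
    list(k_rank_B = kB, k_rank_C = kC,
         kruskal_lhs = kB + kC,
         kruskal_satisfied = kruskal_ok,
         row_deletion_satisfied = isTRUE(rd),
         row_deletion_reason = attr(rd, "reason"),
         occasion_rank_count = occ$count,
         result2_satisfied = occ$satisfied,
         variable_rank_count = var$count,
         banded_satisfied = var$satisfied,
         relevant_satisfied = relevant,
         loadings = loadings, S = S),
    class = "uniqueness_report")
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat("Factor-uniqueness conditions (loadings:", x$loadings, ")\n")
  cat(sprintf("  k-rank(B) + k-rank(C) = %d + %d = %d (need >= S+2 = %d): %s\n",
              x$k_rank_B, x$k_rank_C, x$kruskal_lhs, x$S + 2,
              if (x$kruskal_satisfied) "satisfied" else "NOT satisfied"))
  cat(sprintf("  row-deletion condition (diagonal Psi): %s\n",
              if (x$row_deletion_satisfied) "satisfied"
              else paste("NOT satisfied -", x$row_deletion_reason)))
  cat(sprintf("  full-rank occasions (block Psi): %d (need >= 3): %s\n",
              x$occasion_rank_count,
              if (x$result2_satisfied) "satisfied" else "NOT satisfied"))
  cat(sprintf("  full-rank variables (banded Psi): %d (need >= 3): %s\n",
              x$variable_rank_count,
              if (x$banded_satisfied) "satisfied" else "NOT satisfied"))
  cat("  conditions relevant to this model:",
      if (x$relevant_satisfied) "satisfied" else "NOT satisfied", "\n")
  invisible(x)
}
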