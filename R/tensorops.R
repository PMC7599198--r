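#' Khatri-Rao (column-wise Kronecker) product
#'
#' For `C` of order `K x S` and `B` of order `J x S`, returns the `JK x S`
#' matrix whose column `s` is `C[, s] %x% B[, s]`.  Rows follow the
#' variable-fastest composite ordering of [composite_index()], i.e. row
#' `(k - 1) * J + j` holds `C[k, s] * B[j, s]`.
#'
#' @param C numeric matrix `K x S` (occasion loadings).
#' @param B numeric matrix `J x S` (variable loadings).
#' @return Numeric matrix of order `JK x S`.
#' @examples
#' khatri_rao(diag(2), matrix(c(1, 3, 2, 4), 2))
#' @export
khatri_rao <- function(C, B) {
  C <- as.matrix(C); B <- as.matrix(B)
  if (ncol(C) != ncol(B))
    stop("Khatri-Rao product needs equal column counts: ncol(C) = ", ncol(C),
         ", ncol(B) = ", ncol(B), call. = FALSE)
  K <- nrow(C); J <- nrow(B)
  C[rep(seq_len(K), each = J), , drop = FALSE] *
    B[rep(seq_len(J), times = K), , drop = FALSE]
}
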