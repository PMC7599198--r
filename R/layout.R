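#' Declare the layout of a variables-by-occasions data vector
#'
#' A three-way layout fixes the number of manifest variables `J`, the number
#' of occasions `K`, and the vectorization convention that binds row `r` of a
#' `JK x JK` covariance matrix to a (variable, occasion) pair.  The
#' convention used throughout the package is *variable-fastest*: the
#' composite row index of variable `j` observed at occasion `k` is
#' `(k - 1) * J + j`, so the `J` variables of occasion 1 come first, then the
#' `J` variables of occasion 2, and so on.  This matches the row ordering of
#' the Kronecker product `C %x% B` and of the Khatri-Rao product
#' [khatri_rao()], and makes the within-occasion blocks of a block-diagonal
#' specific-factor covariance contiguous.
#'
#' @param n_variables number of manifest variables `J` (at least 1).
#' @param n_occasions number of occasions `K` (at least 1).
#' @param variable_labels character vector of `J` unique labels.
#' @param occasion_labels character vector of `K` unique labels.
#'
#' @return An object of class `"three_way_layout"`: a list with elements
#'   `J`, `K`, `variable_labels`, `occasion_labels`.
#' @examples
#' layout <- three_way_layout(4, 3,
#'   variable_labels = c("E", "A", "I", "M"),
#'   occasion_labels = c("P", "T", "S"))
#' composite_labels(layout)
#' @export
three_way_layout <- function(n_variables, n_occasions,
                             variable_labels = paste0("V", seq_len(n_variables)),
                             occasion_labels = paste0("O", seq_len(n_occasions))) {
  J <- as.integer(n_variables)
  K <- as.integer(n_occasions)
  if (length(J) != 1L || is.na(J) || J < 1L)
    stop("`n_variables` must be a single integer >= 1", call. = FALSE)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("`n_occasions` must be a single integer >= 1", call. = FALSE)
  variable_labels <- as.character(variable_labels)
  occasion_labels <- as.character(occasion_labels)
  if (length(variable_labels) != J || anyDuplicated(variable_labels))
    stop("`variable_labels` must be ", J, " unique strings", call. = FALSE)
  if (length(occasion_labels) != K || anyDuplicated(occasion_labels))
    stop("`occasion_labels` must be ", K, " unique strings", call. = FALSE)
  structure(
    list(J = J, K = K,
         variable_labels = variable_labels,
         occasion_labels = occasion_labels),
    class = "three_way_layout")
}

#' @export
print.three_way_layout <- function(x, ...) {
  cat("Three-way layout: J =", x$J, "variables x K =", x$K, "occasions\n")
  cat("  variables:", paste(x$variable_labels, collapse = ", "), "\n")
  cat("  occasions:", paste(x$occasion_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Composite row index of a (variable, occasion) pair
#'
#' Maps 1-based variable index `j` and occasion index `k` to the 1-based row
#' index `(k - 1) * J + j` of the vectorized data (variable-fastest
#' ordering).  The map is a bijection from the `J x K` index grid onto
#' `1:(J*K)`.  Both arguments are vectorized and recycled.
#'
#' @param j variable index (or vector of indices) in `1:J`.
#' @param k occasion index (or vector of indices) in `1:K`.
#' @param layout a [three_way_layout()].
#' @return Integer row indices in `1:(J*K)`.
#' @examples
#' layout <- three_way_layout(4, 3)
#' composite_index(1, 1, layout)  # 1
#' composite_index(4, 3, layout)  # 12
#' @export
composite_index <- function(j, k, layout) {
  stopifnot(inherits(layout, "three_way_layout"))
  j <- as.integer(j); k <- as.integer(k)
  if (any(is.na(j)) || any(j < 1L) || any(j > layout$J))
    stop("variable index out of range 1:", layout$J, call. = FALSE)
  if (any(is.na(k)) || any(k < 1L) || any(k > layout$K))
    stop("occasion index out of range 1:", layout$K, call. = FALSE)
  (k - 1L) * layout$J + j
}

#' Labels of the composite rows, in composite-index order
#'
#' @param layout a [three_way_layout()].
#' @param sep separator between variable and occasion label.
#' @return Character vector of length `J*K`, entry `r` labelling composite
#'   row `r` as `"variable@occasion"`.
#' @export
composite_labels <- function(layout, sep = "@") {
  stopifnot(inherits(layout, "three_way_layout"))
  as.vector(outer(layout$variable_labels, layout$occasion_labels,
                  function(v, o) paste(v, o, sep = sep)))
}

# variable (j) and occasion (k) index of each composite row, as a JK x 2 matrix
composite_grid <- function(layout) {
  cbind(j = rep(seq_len(layout$J), times = layout$K),
        k = rep(seq_len(layout$K), each = layout$J))
}
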