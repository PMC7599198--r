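#' Bentler-McClain multitrait-multimethod correlation matrix
#'
#' The classic 12 x 12 correlation matrix of four personality traits of
#' I = 68 fifth-grade children -- Extraversion (E), Test anxiety (A),
#' Impulsivity (I) and Academic achievement motivation (M) -- each measured
#' by three methods: Peer report (P), Teacher rating (T) and Self-rating
#' (S).  Traits play the role of variables and methods the role of
#' occasions, so the composite ordering is trait-fastest within method.
#'
#' @return A list with elements `R` (the symmetric unit-diagonal correlation
#'   matrix with composite-label dimnames), `layout` (the corresponding
#'   [three_way_layout()]) and `sample_size` (68).
#' @examples
#' bm <- bentler_mcclain()
#' bm$R["E@P", "A@P"]  # -0.38
#' @export
bentler_mcclain <- function() {
  layout <- three_way_layout(
    4, 3,
    variable_labels = c("E", "A", "I", "M"),
    occasion_labels = c("P", "T", "S"))
  lower <- c(
    -0.38,
     0.42, -0.21,
    -0.25,  0.54, -0.54,
     0.64, -0.15,  0.26, -0.05,
    -0.29,  0.66, -0.19,  0.44, -0.25,
     0.38, -0.09,  0.56, -0.19,  0.59, -0.14,
    -0.22,  0.51, -0.33,  0.66,  0.06,  0.62, -0.05,
     0.45, -0.05,  0.12,  0.10,  0.50, -0.05,  0.36,  0.17,
     0.04,  0.38, -0.03,  0.14,  0.08,  0.30,  0.09,  0.16,  0.02,
     0.33, -0.13,  0.35, -0.18,  0.41, -0.14,  0.45, -0.13,  0.43,  0.16,
    -0.21,  0.37, -0.44,  0.58, -0.01,  0.41, -0.10,  0.62,  0.06,  0.04, -0.37)
  R <- diag(12)
  R[upper.tri(R)] <- lower   # column-major upper triangle = row-major lower
  R <- R + t(R) - diag(12)
  dimnames(R) <- list(composite_labels(layout), composite_labels(layout))
  list(R = R, layout = layout, sample_size = 68L)
}
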