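#' Read a square covariance/correlation matrix from CSV
#'
#' Expects a square numeric CSV with a header row of composite labels in
#' composite-index order (variable fastest within occasion, see
#' [composite_index()]); row names are optional.  Symmetry is enforced up
#' to rounding.
#'
#' @param path file path.
#' @return Numeric matrix with dimnames from the header.
#' @export
read_cov_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) == nrow(tab) + 1L &&
      !is.numeric(tab[[1L]])) {  # leading label column
    rn <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
    rownames(tab) <- rn
  }
  M <- as.matrix(tab)
  if (!is.numeric(M) || nrow(M) != ncol(M))
    stop("`", path, "` does not hold a square numeric matrix", call. = FALSE)
  if (max(abs(M - t(M))) > 1e-6 * max(1, max(abs(M))))
    stop("matrix in `", path, "` is not symmetric", call. = FALSE)
  rownames(M) <- colnames(M)
  (M + t(M)) / 2
}

#' Write a square matrix to CSV with composite-label header
#'
#' @param M square numeric matrix.
#' @param path output file path.
#' @param layout optional [three_way_layout()] supplying the header labels
#'   (defaults to existing column names).
#' @export
write_cov_matrix <- function(M, path, layout = NULL) {
  M <- as.matrix(M)
  if (!is.null(layout)) {
    dimnames(M) <- list(composite_labels(layout), composite_labels(layout))
  }
  utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  invisible(path)
}

#' Read a model + layout configuration from a YAML file
#'
#' Recognized keys: `n_factors`, `phi_structure`, `psi_structure`,
#' `invariance`, `identification` (see [parafac_model()]) and `J`, `K`,
#' `variable_labels`, `occasion_labels` (see [three_way_layout()]).
#' Missing optional keys fall back to the constructors' defaults.
#'
#' @param path YAML file path.
#' @return List with elements `model` and `layout`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config is missing `", key, "`",
                                  call. = FALSE)
    cfg[[key]]
  }
  layout <- three_way_layout(
    need("J"), need("K"),
    variable_labels = cfg$variable_labels %||% paste0("V", seq_len(cfg$J)),
    occasion_labels = cfg$occasion_labels %||% paste0("O", seq_len(cfg$K)))
  model <- parafac_model(
    need("n_factors"),
    phi_structure = cfg$phi_structure %||% "orthogonal",
    psi_structure = cfg$psi_structure %||% "diagonal",
    invariance = cfg$invariance %||% "none",
    identification = cfg$identification %||% "unit_column_norm")
  list(model = model, layout = layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic text report of a fit (no timestamps: identical runs must
# produce identical files)
write_fit_report <- function(fit, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  out <- function(...) writeLines(paste0(...), con)
  out("structural Parafac fit report")
  out("=============================")
  m <- fit$model
  out("model: S = ", m$S, ", phi = ", m$phi_structure, ", psi = ",
      m$psi_structure, ", invariance = ", m$invariance,
      ", identification = ", m$identification)
  lay <- fit$layout
  out("layout: J = ", lay$J, " (", paste(lay$variable_labels, collapse = ","),
      "), K = ", lay$K, " (", paste(lay$occasion_labels, collapse = ","), ")")
  out("sample size I = ", fit$sample_size)
  op <- fit$options
  out("method = ", op$method, ", n_starts = ", op$n_starts,
      ", start_strategy = ", op$start_strategy,
      ", seed = ", if (is.null(op$seed)) "NULL" else op$seed)
  out("")
  out(sprintf("F_hat = %.6f", fit$F_hat))
  if (!is.na(fit$chi_square)) {
    out(sprintf("chi_square = %.4f, df = %d, p_value = %.6f",
                fit$chi_square, fit$df, fit$p_value))
    out(sprintf("AIC = %.4f, BIC = %.4f, q = %d", fit$aic, fit$bic,
                fit$n_parameters))
  }
  out("starts converged = ", fit$n_converged, "/", length(fit$start_values),
      ", at reported minimum (4 decimals) = ", fit$n_at_global)
  out("")
  out("estimates (natural scale):")
  est <- fit$estimates
  se <- fit$standard_errors
  for (i in seq_along(est)) {
    line <- sprintf("  %-14s %10.4f", names(est)[i], est[i])
    if (!is.null(se)) line <- sprintf("%s  (%.4f)", line, se[i])
    out(line)
  }
  out("")
  out("uniqueness conditions:")
  u <- fit$uniqueness
  out(sprintf("  k_rank_B = %d, k_rank_C = %d, kruskal (>= S+2): %s",
              u$k_rank_B, u$k_rank_C, u$kruskal_satisfied))
  out(sprintf("  row_deletion: %s, occasions full rank: %d, variables full rank: %d",
              u$row_deletion_satisfied, u$occasion_rank_count,
              u$variable_rank_count))
  out(sprintf("  conditions for this psi structure satisfied: %s",
              u$relevant_satisfied))
  invisible(path)
}
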