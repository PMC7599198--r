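#' Chi-square test of overall fit
#'
#' Tests the null hypothesis that the population covariance matrix has the
#' model structure, `\Sigma = \Sigma(\theta)`, against an unrestricted
#' positive definite alternative.  The statistic is `(I - 1)` times the
#' minimized discrepancy, referred to a chi-square distribution with
#' `df = JK(JK+1)/2 - q` degrees of freedom, where `q` is the number of free
#' parameters.
#'
#' @param F_hat minimized discrepancy value (nonnegative).
#' @param sample_size number of observations `I` (at least 2).
#' @param q number of free parameters.
#' @param JK order of the covariance matrix.
#' @return List with `chi_square`, `df`, `p_value`.
#' @examples
#' chi_square_test(0.7418, 68, 42, 12)
#' @export
chi_square_test <- function(F_hat, sample_size, q, JK) {
  if (F_hat < 0) stop("`F_hat` must be nonnegative", call. = FALSE)
  if (sample_size < 2) stop("`sample_size` must be at least 2", call. = FALSE)
  df <- JK * (JK + 1) / 2 - q
  if (df <= 0)
    stop("model is saturated or over-parameterized: df = ", df, call. = FALSE)
  chi2 <- (sample_size - 1) * F_hat
  list(chi_square = chi2, df = as.integer(df),
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Information criteria for covariance structure models
#'
#' `AIC = chi^2 + 2q` and `BIC = chi^2 + q log(I)`, the penalized fit
#' measures conventionally reported alongside the chi-square statistic in
#' covariance structure analysis (they order models identically to the
#' likelihood-based definitions, differing only by a constant shared across
#' models fitted to the same sample).
#'
#' @param chi_square chi-square statistic `(I - 1) * F_hat`.
#' @param q number of free parameters.
#' @param sample_size number of observations `I`.
#' @return List with `aic` and `bic`.
#' @export
information_criteria <- function(chi_square, q, sample_size) {
  stopifnot(chi_square >= 0, q >= 0, sample_size >= 1)
  list(aic = chi_square + 2 * q,
       bic = chi_square + q * log(sample_size))
}

#' Grid of structural Parafac model specifications
#'
#' Builds the list of [parafac_model()] specifications obtained by crossing
#' factor counts, common-factor structures and specific-factor structures,
#' in the conventional comparison-table order (specific-factor structure
#' slowest within each factor count, common-factor structure fastest).  The
#' default arguments produce the 12-model grid of the
#' multitrait-multimethod application.
#'
#' @param S factor counts to cross.
#' @param phi_structures common-factor covariance structures.
#' @param psi_structures specific-factor covariance structures.
#' @param invariance,identification passed to [parafac_model()].
#' @return List of [parafac_model()] objects.
#' @export
model_grid <- function(S = c(2L, 3L),
                       phi_structures = c("orthogonal", "oblique"),
                       psi_structures = c("diagonal",
                                          "banded_within_variable",
                                          "block_within_occasion"),
                       invariance = "psi_unit_diag",
                       identification = "first_row_unit") {
  grid <- expand.grid(phi = phi_structures, psi = psi_structures, S = S,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    parafac_model(grid$S[i], grid$phi[i], grid$psi[i],
                  invariance = invariance, identification = identification))
}

#' Fit and compare a grid of models
#'
#' Fits every specification in `grid` to the same sample covariance matrix
#' and tabulates discrepancy, chi-square test, AIC, BIC and parameter
#' counts.  Models with a diagonal specific-factor covariance are fitted by
#' the full multi-start protocol; models with correlated specific factors
#' are then fitted starting from the best-fitting diagonal solution with the
#' same factor count and common-factor structure (fitting it on the fly if
#' it is not part of the grid), the strategy that proved necessary to avoid
#' local optima in the multitrait-multimethod application.
#' `warm_extra_starts` random starts can be added to those fits as a
#' safeguard (none by default, mirroring the application's protocol).
#'
#' @param S_mat `JK x JK` sample covariance matrix.
#' @param sample_size number of observations behind `S_mat`.
#' @param layout a [three_way_layout()].
#' @param grid list of [parafac_model()] specifications (see [model_grid()]).
#' @param options a [fit_options()] list; `n_starts` applies to the
#'   diagonal-structure fits.
#' @param alpha significance level used to flag models whose chi-square null
#'   hypothesis is not rejected.
#' @param warm_extra_starts random starts added to each warm-started fit.
#' @return An object of class `"parafac_scan"`: a data frame with one row
#'   per specification (columns `S`, `phi`, `psi`, `q`, `F_hat`,
#'   `chi_square`, `df`, `p_value`, `aic`, `bic`, `n_at_global`,
#'   `not_rejected`, `error`) carrying the fitted objects in attribute
#'   `"fits"`.
#' @export
parafac_scan <- function(S_mat, sample_size, layout, grid = model_grid(),
                         options = fit_options(), alpha = 0.05,
                         warm_extra_starts = 0L) {
  stopifnot(length(grid) >= 1L)
  key <- function(m) paste(m$S, m$phi_structure, m$invariance,
                           m$identification, sep = "/")
  diag_fits <- list()

  fit_diagonal <- function(m) {
    k <- key(m)
    if (is.null(diag_fits[[k]])) {
      md <- parafac_model(m$S, m$phi_structure, "diagonal",
                          invariance = m$invariance,
                          identification = m$identification)
      diag_fits[[k]] <<- parafac_fit(S_mat, sample_size, md, layout, options)
    }
    diag_fits[[k]]
  }

  fit_one <- function(m) {
    if (m$psi_structure == "diagonal") return(fit_diagonal(m))
    base <- fit_diagonal(m)
    warm_opts <- options
    warm_opts$n_starts <- 1L + as.integer(warm_extra_starts)
    # embed the diagonal solution in the richer Psi structure (off-
    # diagonal support entries start at zero)
    init <- parafac_params(base$params$B, base$params$C, base$params$Phi,
                           base$params$Psi, D = base$params$d)
    parafac_fit(S_mat, sample_size, m, layout, warm_opts, init = init)
  }

  fits <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    m <- grid[[i]]
    f <- tryCatch(fit_one(m), error = function(e) e)
    fits[[i]] <- f
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(
        S = m$S, phi = m$phi_structure, psi = m$psi_structure,
        q = NA_integer_, F_hat = NA_real_, chi_square = NA_real_,
        df = NA_integer_, p_value = NA_real_, aic = NA_real_,
        bic = NA_real_, n_at_global = NA_integer_, not_rejected = NA,
        error = conditionMessage(f), stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        S = m$S, phi = m$phi_structure, psi = m$psi_structure,
        q = f$n_parameters, F_hat = f$F_hat, chi_square = f$chi_square,
        df = f$df, p_value = f$p_value, aic = f$aic, bic = f$bic,
        n_at_global = f$n_at_global,
        not_rejected = !is.na(f$p_value) && f$p_value > alpha,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, fits = fits, alpha = alpha, sample_size = sample_size,
            class = c("parafac_scan", "data.frame"))
}

#' Extract a fitted model from a scan
#'
#' @param scan a [parafac_scan()] result.
#' @param i row index of the model to extract.
#' @return The corresponding [parafac_fit()] object.
#' @export
scan_fit <- function(scan, i) {
  stopifnot(inherits(scan, "parafac_scan"))
  f <- attr(scan, "fits")[[i]]
  if (inherits(f, "error")) stop("model ", i, " failed: ",
                                 conditionMessage(f), call. = FALSE)
  f
}

#' @export
print.parafac_scan <- function(x, digits = 4, ...) {
  cat("Structural Parafac model comparison (I =", attr(x, "sample_size"),
      ", alpha =", attr(x, "alpha"), ")\n")
  tab <- as.data.frame(x)
  tab$F_hat <- round(tab$F_hat, digits)
  tab$chi_square <- round(tab$chi_square, 2)
  tab$p_value <- signif(tab$p_value, 3)
  tab$aic <- round(tab$aic, 2)
  tab$bic <- round(tab$bic, 2)
  print(tab)
  invisible(x)
}
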