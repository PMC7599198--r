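#' Options controlling the multi-start fit
#'
#' @param method discrepancy to minimize: `"ml"` (normal-theory maximum
#'   likelihood), `"gls"` (quadratic discrepancy with `W = S`) or `"ols"`
#'   (`W = I`; not scale invariant).
#' @param n_starts number of optimization runs from independent starting
#'   points (the best local minimum is reported).
#' @param max_iter iteration cap per optimizer run.
#' @param rel_tol relative convergence tolerance passed to the optimizer.
#' @param conv_grad_tol gradient infinity-norm below which a returned point
#'   is accepted as converged regardless of the optimizer's status code.
#' @param seed integer seed for the random starts; `NULL` leaves the RNG
#'   state alone.
#' @param start_strategy `"ols_then_ml"` first minimizes the unweighted
#'   quadratic discrepancy from each random start and then refines with
#'   `method` (the protocol used in the multitrait-multimethod application);
#'   `"random"` goes straight to `method`.
#' @param start_scale standard deviation of the centered draws generating
#'   random starts on the internal parameter scale.
#' @param compute_se whether to attempt delta-method standard errors at the
#'   optimum.
#' @return A list of class `"parafac_fit_options"`.
#' @export
fit_options <- function(method = c("ml", "gls", "ols"),
                        n_starts = 100L,
                        max_iter = 500L,
                        rel_tol = 1e-12,
                        conv_grad_tol = 1e-4,
                        seed = NULL,
                        start_strategy = c("ols_then_ml", "random"),
                        start_scale = 0.5,
                        compute_se = TRUE) {
  method <- match.arg(method)
  start_strategy <- match.arg(start_strategy)
  if (n_starts < 1L) stop("`n_starts` must be at least 1", call. = FALSE)
  if (rel_tol <= 0 || max_iter < 1) stop("invalid tolerances", call. = FALSE)
  structure(list(method = method, n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 conv_grad_tol = conv_grad_tol,
                 seed = seed, start_strategy = start_strategy,
                 start_scale = start_scale, compute_se = compute_se),
            class = "parafac_fit_options")
}

# one optimizer run (optionally OLS pre-phase then target method); a start
# counts as converged when the optimizer reports success or the gradient at
# the returned point is numerically zero (the PORT routine often labels a
# fully converged run "false convergence" under tight tolerances)
run_start <- function(theta0, obj_main, obj_pre, map, options) {
  ctrl <- list(iter.max = options$max_iter, eval.max = 10L * options$max_iter,
               rel.tol = options$rel_tol)
  theta <- theta0
  if (!is.null(obj_pre)) {
    pre <- tryCatch(
      stats::nlminb(theta, obj_pre$fn, gradient = obj_pre$gr,
                    lower = map$lower, upper = map$upper, control = ctrl),
      error = function(e) NULL)
    if (!is.null(pre)) theta <- pre$par
  }
  res <- NULL
  gnorm <- Inf
  # restart the optimizer from its endpoint up to three times: on very flat
  # discrepancy surfaces a fresh quasi-Newton model often finishes a run
  # that stalled against the iteration cap
  for (round in 1:3) {
    res_i <- tryCatch(
      stats::nlminb(theta, obj_main$fn, gradient = obj_main$gr,
                    lower = map$lower, upper = map$upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res_i) || !is.finite(res_i$objective)) break
    res <- res_i
    theta <- res$par
    gnorm <- max(abs(obj_main$gr(res$par)))
    if (res$convergence == 0 || gnorm < options$conv_grad_tol) break
  }
  if (is.null(res)) {
    return(list(ok = FALSE, value = Inf, par = theta0,
                message = "optimizer error"))
  }
  list(ok = res$convergence == 0 || gnorm < options$conv_grad_tol,
       value = res$objective, par = res$par, grad_norm = gnorm,
       message = res$message)
}

#' Fit a structural Parafac model to a sample covariance matrix
#'
#' Minimizes the chosen discrepancy between `S_mat` and the model-implied
#' covariance `\Sigma(\theta)` over a multi-start protocol: each start draws
#' the internal free parameters i.i.d. from a centered distribution,
#' optionally pre-optimizes the unweighted least squares discrepancy, and
#' then refines with the target method using an analytic-gradient
#' quasi-Newton optimizer.  The best local minimum over all converged starts
#' is reported together with how many starts reached it (agreement judged on
#' the first four decimal digits of the discrepancy).
#'
#' @param S_mat `JK x JK` sample covariance (or correlation) matrix.
#' @param sample_size number of observations `I` behind `S_mat`; used for
#'   the chi-square statistic, information criteria and standard errors.
#' @param model a [parafac_model()].
#' @param layout a [three_way_layout()].
#' @param options a [fit_options()] list.
#' @param init optional warm start: a [parafac_params()] set (or internal
#'   parameter vector) used as the first start; the remaining
#'   `n_starts - 1` starts are random.
#' @return An object of class `"parafac_fit"` with elements `params`
#'   (estimates under the model's identification convention), `F_hat`,
#'   `chi_square`, `df`, `p_value`, `aic`, `bic`, `n_parameters`,
#'   `estimates` (named natural-scale free parameters),
#'   `standard_errors`, `n_converged`, `n_at_global`, `start_values`
#'   (per-start minima), `uniqueness` (a [uniqueness_report()]), plus
#'   echoes of the model, layout, options and inputs.
#' @examples
#' \donttest{
#' bm <- bentler_mcclain()
#' model <- parafac_model(2, "orthogonal", "diagonal",
#'                        invariance = "psi_unit_diag",
#'                        identification = "first_row_unit")
#' fit <- parafac_fit(bm$R, bm$sample_size, model, bm$layout,
#'                    fit_options(n_starts = 10, seed = 1))
#' fit
#' }
#' @export
parafac_fit <- function(S_mat, sample_size, model, layout,
                        options = fit_options(), init = NULL) {
  stopifnot(inherits(model, "parafac_model"),
            inherits(layout, "three_way_layout"))
  S_mat <- as.matrix(S_mat)
  JK <- layout$J * layout$K
  if (nrow(S_mat) != JK || ncol(S_mat) != JK)
    stop("`S_mat` must be ", JK, " x ", JK,
         " for this layout (J*K = ", JK, ")", call. = FALSE)
  if (max(abs(S_mat - t(S_mat))) > 1e-8 * max(abs(S_mat)))
    stop("`S_mat` must be symmetric", call. = FALSE)
  S_mat <- (S_mat + t(S_mat)) / 2

  map <- par_map(model, layout)
  q <- tryCatch(count_parameters(model, layout), error = function(e) NA_integer_)
  if (!is.na(q) && sample_size <= q)
    warning("sample size ", sample_size, " does not exceed the ", q,
            " free parameters; fit statistics are unreliable", call. = FALSE)

  obj_main <- make_objective(S_mat, model, layout, method = options$method,
                             map = map)
  obj_pre <- if (options$start_strategy == "ols_then_ml" &&
                 options$method != "ols") {
    make_objective(S_mat, model, layout, method = "ols", map = map)
  } else NULL

  if (!is.null(options$seed)) set.seed(options$seed)
  starts <- vector("list", options$n_starts)
  first <- 1L
  if (!is.null(init)) {
    starts[[1L]] <- if (inherits(init, "parafac_params"))
      params_to_theta(init, map) else as.numeric(init)
    if (length(starts[[1L]]) != map$n_theta)
      stop("`init` has the wrong number of internal parameters", call. = FALSE)
    first <- 2L
  }
  for (i in seq.int(first, length.out = options$n_starts - first + 1L))
    starts[[i]] <- random_theta(map, options$start_scale)

  # a supplied warm start goes straight to the target method; the OLS
  # pre-phase is only a device for taming random starts
  runs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    pre_i <- if (!is.null(init) && i == 1L) NULL else obj_pre
    runs[[i]] <- run_start(starts[[i]], obj_main = obj_main, obj_pre = pre_i,
                           map = map, options = options)
  }
  values <- vapply(runs, `[[`, numeric(1), "value")
  ok <- vapply(runs, `[[`, logical(1), "ok") & is.finite(values)
  if (!any(ok)) {
    stop("no optimization start converged; per-start diagnostics: ",
         paste(utils::head(vapply(runs, `[[`, character(1), "message"), 5),
               collapse = "; "), call. = FALSE)
  }
  use <- which(ok)
  best <- use[which.min(values[use])]
  theta_hat <- runs[[best]]$par
  # the ML discrepancy can round to a tiny negative number at an exact fit
  F_hat <- max(values[best], 0)
  n_at_global <- sum(round(values[use], 4) == round(F_hat, 4))

  params_raw <- theta_to_params(theta_hat, map)
  params_hat <- standardize_params(params_raw, model)

  chi2 <- df <- p <- aic <- bic <- NA_real_
  if (!is.na(q)) {
    st <- tryCatch(chi_square_test(F_hat, sample_size, q, JK),
                   error = function(e) NULL)
    if (!is.null(st)) {
      chi2 <- st$chi_square; df <- st$df; p <- st$p_value
      ic <- information_criteria(chi2, q, sample_size)
      aic <- ic$aic; bic <- ic$bic
    }
  }

  estimates <- natural_from_theta(theta_hat, map)
  ses <- NULL
  if (isTRUE(options$compute_se)) {
    ses <- tryCatch(
      se_natural(obj_main, theta_hat, sample_size, map),
      error = function(e) {
        warning("standard errors unavailable: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }

  uniq <- uniqueness_report(
    params_hat, model, layout,
    loadings = if (model$invariance == "none") "khatri_rao" else "scaled")

  structure(
    list(params = params_hat, F_hat = F_hat,
         chi_square = chi2, df = df, p_value = p, aic = aic, bic = bic,
         n_parameters = q,
         estimates = estimates, standard_errors = ses,
         n_converged = sum(ok), n_at_global = n_at_global,
         start_values = values,
         uniqueness = uniq,
         theta = theta_hat, map = map,
         model = model, layout = layout, options = options,
         S_mat = S_mat, sample_size = sample_size),
    class = "parafac_fit")
}

# delta-method standard errors on the natural parameter scale:
# cov(theta) = (2/(I-1)) H^{-1} with H the Hessian of the discrepancy at
# the optimum; natural-scale covariance via the numerical Jacobian of the
# internal-to-natural map
se_natural <- function(obj, theta_hat, sample_size, map) {
  H <- pracma::hessian(obj$fn, theta_hat)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-6 * max(abs(ev)))
    stop("Hessian at the optimum is singular or not positive definite ",
         "(flat or unidentified directions)")
  cov_theta <- (2 / (sample_size - 1)) * chol2inv(chol(H))
  Jn <- pracma::jacobian(function(th) unname(natural_from_theta(th, map)),
                         theta_hat)
  se <- sqrt(pmax(diag(Jn %*% cov_theta %*% t(Jn)), 0))
  stats::setNames(se, names(natural_from_theta(theta_hat, map)))
}

#' Standard errors of a fitted model
#'
#' Returns the delta-method standard errors of the natural-scale free
#' parameters: the inverse Hessian of the discrepancy at the optimum scaled
#' by `2/(I-1)`, mapped through the Jacobian of the internal-to-natural
#' parameter transform.  If they were not computed during fitting they are
#' computed now; an indefinite Hessian yields a warning and `NULL` rather
#' than fabricated values.
#'
#' @param fit a [parafac_fit()] result.
#' @return Named numeric vector of standard errors, or `NULL`.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "parafac_fit"))
  if (!is.null(fit$standard_errors)) return(fit$standard_errors)
  obj <- make_objective(fit$S_mat, fit$model, fit$layout,
                        method = fit$options$method, map = fit$map)
  tryCatch(se_natural(obj, fit$theta, fit$sample_size, fit$map),
           error = function(e) {
             warning("standard errors unavailable: ", conditionMessage(e),
                     call. = FALSE)
             NULL
           })
}

#' @export
print.parafac_fit <- function(x, digits = 4, ...) {
  cat("Structural Parafac fit (", x$options$method, ", ",
      x$n_converged, "/", length(x$start_values), " starts converged, ",
      x$n_at_global, " at the reported minimum)\n", sep = "")
  print(x$model)
  cat(sprintf("  discrepancy F-hat = %.*f\n", digits, x$F_hat))
  if (!is.na(x$chi_square))
    cat(sprintf("  chi-square = %.*f on df = %d, p = %.4f (I = %d, q = %d)\n",
                2, x$chi_square, x$df, x$p_value, x$sample_size,
                x$n_parameters))
  if (!is.na(x$aic))
    cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$aic, x$bic))
  cat("\nEstimates:\n")
  est <- x$estimates
  if (!is.null(x$standard_errors)) {
    tab <- data.frame(estimate = round(est, digits),
                      se = round(x$standard_errors, digits))
    print(tab)
  } else {
    print(round(est, digits))
  }
  invisible(x)
}
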