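#' Fit a histogram model by Levenberg-Marquardt least squares
#'
#' Minimizes the unweighted sum of squared residuals between the observed
#' counts and the composite model over the masked bins, using
#' \code{minpack.lm::nls.lm} (Levenberg-Marquardt with native box
#' constraints). Fitting is deterministic for fixed inputs: there are no
#' random restarts. Non-convergence is reported in the result, never raised.
#'
#' @param model A \code{histogram_model}.
#' @param hist The \code{fcs_histogram} the model was built for.
#' @param max_iter Iteration cap. Default 1024.
#' @param tolerance Relative reduction in the objective below which the fit is
#'   declared converged. Default 1e-8.
#' @param init Optional replacement initial values (full named vector);
#'   defaults to the model's own initial estimates.
#' @return A \code{fit_result}: list with \code{params} (named converged
#'   vector), \code{param_errors} (approximate standard errors from the
#'   Jacobian, NA where the Jacobian is singular), \code{fitted_curve},
#'   \code{converged}, \code{n_iter}, \code{rcs}, \code{message},
#'   \code{objective}, \code{model}, \code{hist}.
#' @export
fit_histogram <- function(model, hist, max_iter = 1024L, tolerance = 1e-8,
                          init = NULL) {
  stopifnot(inherits(model, "histogram_model"), inherits(hist, "fcs_histogram"))
  init <- init %||% model$init_values
  init <- pmin(pmax(init, model$lower_bounds), model$upper_bounds)
  mask <- model$fit_mask
  obs <- hist$counts[mask]
  bases <- model_bases(model, hist)

  resid_fn <- function(p) {
    obs - eval_model(model, p, hist, bases)[mask]
  }

  # non-convergence is part of the result contract, not a warning condition
  out <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = init,
      lower = model$lower_bounds,
      upper = model$upper_bounds,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(as.integer(max_iter), 1024L),
        ftol = tolerance, maxfev = 100000L)
    )),
    error = function(e) e
  )

  if (inherits(out, "error")) {
    return(structure(list(
      params = init, param_errors = rep(NA_real_, length(init)),
      fitted_curve = eval_model(model, init, hist),
      converged = FALSE, n_iter = 0L, rcs = NA_real_,
      message = paste("solver error:", conditionMessage(out)),
      objective = sum(resid_fn(init)^2),
      model = model, hist = hist
    ), class = "fit_result"))
  }

  pars <- stats::setNames(out$par, model$param_names)
  pars <- pmin(pmax(pars, model$lower_bounds), model$upper_bounds)
  converged <- out$info %in% c(1L, 2L, 3L)
  fitted_curve <- eval_model(model, pars, hist, bases)

  # approximate standard errors: sigma^2 * (J'J)^{-1}, hessian = 2 J'J.
  # Parameters pinned at a bound have no interior curvature information; they
  # are excluded from the solve and reported as NA.
  p_err <- rep(NA_real_, length(pars))
  dof <- sum(mask) - length(pars)
  if (dof > 0) {
    tol <- 1e-8 * (1 + abs(pars))
    free <- (pars - model$lower_bounds > tol) &
      (model$upper_bounds - pars > tol)
    if (any(free)) {
      cov_try <- tryCatch({
        s2 <- out$deviance / dof
        hf <- out$hessian[free, free, drop = FALSE]
        d <- sqrt(diag(hf))  # equilibrate: component scales differ by ~1e9
        hs <- hf / tcrossprod(d)
        2 * s2 * diag(solve(hs)) / d^2
      }, error = function(e) NULL)
      if (!is.null(cov_try) && all(is.finite(cov_try)) && all(cov_try >= 0)) {
        p_err[free] <- sqrt(cov_try)
      }
    }
  }

  rcs <- residual_chi_square(hist, fitted_curve, mask, length(pars))
  structure(list(
    params = pars,
    param_errors = stats::setNames(p_err, model$param_names),
    fitted_curve = fitted_curve,
    converged = converged,
    n_iter = out$niter,
    rcs = rcs,
    message = out$message,
    objective = out$deviance,
    model = model,
    hist = hist
  ), class = "fit_result")
}

#' Residual chi-square goodness-of-fit statistic
#'
#' A rough per-degree-of-freedom goodness-of-fit measure for the histogram
#' regression: \code{sum((H - F)^2 / max(F, 1)) / (n_mask - n_params)} over
#' the masked bins, using the fitted count as the (Poisson-like) variance with
#' a floor of one count. Values near 1 indicate residuals at counting-noise
#' scale.
#'
#' @param hist Observed \code{fcs_histogram}.
#' @param fitted_curve Fitted counts per bin.
#' @param mask Logical per-bin inclusion vector.
#' @param n_params Number of fitted parameters.
#' @return The RCS value (dimensionless, >= 0).
#' @export
residual_chi_square <- function(hist, fitted_curve, mask, n_params) {
  stopifnot(inherits(hist, "fcs_histogram"))
  n_mask <- sum(mask)
  if (n_mask <= n_params) {
    pf_error(sprintf(
      "degrees of freedom exhausted: %d masked bins <= %d parameters",
      n_mask, n_params), "pf_dof_error")
  }
  h <- hist$counts[mask]
  f <- fitted_curve[mask]
  sum((h - f)^2 / pmax(f, 1)) / (n_mask - n_params)
}

#' Refit from modified initial values
#'
#' Batch replacement for interactive correction of a poor fit: re-runs the
#' fit with selected initial values replaced, all other initial estimates
#' retained.
#'
#' @param result A \code{fit_result}.
#' @param overrides Named list or vector mapping parameter names to new
#'   initial values. Empty overrides reproduce the original fit exactly.
#' @param ... Passed on to [fit_histogram()] (e.g. \code{max_iter}).
#' @return A new \code{fit_result}.
#' @export
refit_with_overrides <- function(result, overrides = list(), ...) {
  stopifnot(inherits(result, "fit_result"))
  model <- result$model
  overrides <- unlist(overrides)
  unknown <- setdiff(names(overrides), model$param_names)
  if (length(unknown)) {
    pf_error(sprintf("unknown parameter(s) %s; model parameters: %s",
                     paste(unknown, collapse = ", "),
                     paste(model$param_names, collapse = ", ")),
             "pf_lookup_error")
  }
  init <- model$init_values
  init[names(overrides)] <- as.numeric(overrides)
  # widen position bounds around an overridden mean: the user is asserting a
  # better location than the detector's
  for (p in names(overrides)) {
    if (grepl("^mu_", p)) {
      model$lower_bounds[p] <- 0.9 * init[p]
      model$upper_bounds[p] <- 1.1 * init[p]
    }
  }
  fit_histogram(model, result$hist, init = init, ...)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s after %d iterations; RCS = %.3f\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$rcs))
  print(round(x$params, 4))
  invisible(x)
}
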