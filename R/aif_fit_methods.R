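# S3 methods for fitted AIF models.

#' Fit an arterial input function model
#'
#' Umbrella fitting interface dispatching to the model classes:
#' `"triexp"` ([fit_parametric_aif()]), `"gam"` ([fit_gam_aif()]) or
#' `"hgam"` ([fit_hgam_aif()], which expects a list of prepared
#' examinations).
#'
#' @param prep an `aif_prep` from [prepare_examination()] (a `blood_exam`
#'   is accepted and prepared with defaults), or a list of these for
#'   `model = "hgam"`.
#' @param model `"gam"` (default), `"triexp"` or `"hgam"`.
#' @param ... passed to the model-specific fitting function.
#' @return An object of class `aif_fit`.
#' @export
fit_aif <- function(prep, model = c("gam", "triexp", "hgam"), ...) {
  model <- match.arg(model)
  as_prep <- function(p) {
    if (inherits(p, "blood_exam")) prepare_examination(p) else p
  }
  switch(model,
    gam = fit_gam_aif(as_prep(prep), ...),
    triexp = fit_parametric_aif(as_prep(prep), ...),
    hgam = fit_hgam_aif(lapply(prep, as_prep), ...))
}

#' @export
print.aif_fit <- function(x, ...) {
  kind <- switch(x$kind,
    parametric = "tri-exponential (nonlinear Poisson)",
    gam = sprintf("%s GAM (%s%s, k = %d)",
                  x$engine$family$name,
                  if (x$shape_constrained) "shape-constrained B-spline"
                  else "thin-plate spline",
                  if (x$log_time) ", log time" else ", linear time",
                  x$block$info$k %||% NA_integer_),
    hgam = sprintf("hierarchical %s GAM (%d examinations)",
                   x$engine$family$name, length(x$exam_ids)))
  cat("AIF model fit:", kind, "\n")
  cat(sprintf("  n = %d samples, edf = %.2f, logLik = %.2f, AIC = %.2f\n",
              length(x$engine$y), x$engine$edf, x$engine$log_likelihood,
              x$engine$aic))
  if (x$engine$family$name == "negbin") {
    cat(sprintf("  dispersion psi = %.4f\n", x$engine$family$psi))
  }
  ba <- x$beta_abss
  if (!is.null(ba)) {
    cat("  ABSS bias factor exp(beta_abss):",
        paste(signif(exp(ba), 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.aif_fit <- function(object, ...) {
  out <- list(kind = object$kind, family = object$engine$family$name,
              psi = object$engine$family$psi,
              n = length(object$engine$y), edf = object$engine$edf,
              edf_term = object$engine$edf_term,
              log_likelihood = object$engine$log_likelihood,
              aic = object$engine$aic, sp = object$engine$sp,
              beta_abss = object$beta_abss,
              pearson_dispersion = pearson_dispersion(object),
              converged = object$engine$converged)
  class(out) <- "summary.aif_fit"
  out
}

#' @export
print.summary.aif_fit <- function(x, ...) {
  cat(sprintf("%s fit, family %s\n", x$kind, x$family))
  cat(sprintf("  n = %d, edf = %.2f, logLik = %.2f, AIC = %.2f\n",
              x$n, x$edf, x$log_likelihood, x$aic))
  if (length(x$sp)) cat("  smoothing parameters:", signif(x$sp, 4), "\n")
  if (x$family == "negbin") cat("  psi =", signif(x$psi, 4), "\n")
  if (!is.null(x$beta_abss)) {
    cat("  ABSS bias factor:", paste(signif(exp(x$beta_abss), 4),
                                     collapse = ", "), "\n")
  }
  cat("  Pearson dispersion:", signif(x$pearson_dispersion, 4), "\n")
  if (!isTRUE(x$converged)) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.aif_fit <- function(object, ...) {
  if (object$kind == "parametric") {
    c(stats::setNames(object$engine$params$A, paste0("A", 1:3)[
        seq_along(object$engine$params$A)]),
      stats::setNames(object$engine$params$gamma, paste0("gamma", 1:3)[
        seq_along(object$engine$params$gamma)]),
      if (!is.null(object$beta_abss)) c(beta_abss = object$beta_abss))
  } else {
    object$engine$coefficients
  }
}

#' @export
fitted.aif_fit <- function(object, ...) object$engine$fitted

#' @export
logLik.aif_fit <- function(object, ...) {
  structure(object$engine$log_likelihood, df = object$engine$df,
            nobs = length(object$engine$y), class = "logLik")
}

#' @export
predict.aif_fit <- function(object, t_grid = NULL, ...) {
  if (is.null(t_grid)) {
    tr <- range(object$data$t)
    t_grid <- exp(seq(log(tr[1]), log(tr[2]), length.out = 200))
  }
  predict_aif(object, t_grid, ...)
}

#' @export
residuals.aif_fit <- function(object, type = c("quantile", "pearson"),
                              seed = 1L, ...) {
  type <- match.arg(type)
  if (type == "quantile") {
    randomized_quantile_residuals(object, seed = seed)$residuals
  } else {
    eng <- object$engine
    (eng$y - eng$fitted) / sqrt(family_variance(eng$family, eng$fitted))
  }
}

#' @export
simulate.aif_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eng <- object$engine
  out <- as.data.frame(replicate(nsim, family_draw(eng$family, eng$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.aif_fit <- function(x, exam = NULL, reference = "manual",
                         log = "y", ...) {
  d <- x$data
  keep <- if (x$kind == "hgam" && !is.null(exam)) d$group == exam else
    rep(TRUE, length(d$t))
  rate <- d$y[keep] / exp(d$log_tau[keep])
  tt <- d$t[keep]
  abss <- d$abss[keep] > 0
  tr <- range(tt)
  grid <- exp(seq(log(tr[1]), log(tr[2]), length.out = 200))
  pr <- predict_aif(x, grid, reference = reference, exam = exam)
  graphics::plot(tt[abss], rate[abss], pch = 16, cex = 0.3, col = "grey60",
                 log = log, xlab = "time (min)",
                 ylab = "decay-corrected parent plasma rate (counts/s/mL)",
                 ylim = range(c(rate, pr$estimate), na.rm = TRUE), ...)
  graphics::points(tt[!abss], rate[!abss], pch = 16, col = "black")
  graphics::polygon(c(grid, rev(grid)), c(pr$lower, rev(pr$upper)),
                    col = grDevices::adjustcolor("red", 0.2), border = NA)
  graphics::lines(grid, pr$estimate, col = "red", lwd = 2)
  invisible(x)
}
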