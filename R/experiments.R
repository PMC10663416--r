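# Orchestration of the two headline experiments: the model-evolution AIC
# comparison (four model classes per examination) and the pseudo-leave-
# one-out missing-data study for the hierarchical model.

#' Model-evolution AIC comparison
#'
#' Fits the four model classes to each examination — tri-exponential
#' parametric Poisson, shape-constrained Poisson GAM, thin-plate
#' negative-binomial GAM on linear time, and thin-plate negative-binomial
#' GAM on log time — and tabulates per-examination AIC with mean and range
#' differences against the log-time negative-binomial reference.
#' Individual model failures are recorded, not fatal.
#'
#' @param preps list of `aif_prep` objects.
#' @param k basis dimension for the single-examination GAMs.
#' @return A list of class `aif_evolution`: `fits` (per model per exam,
#'   `NULL` on failure), `comparison` (an `aif_aic_comparison` over the
#'   examinations where all four models fitted), and `failures`.
#' @export
run_model_evolution <- function(preps, k = 15) {
  model_fns <- list(
    triexp_poisson = function(p) fit_parametric_aif(p),
    scop_poisson = function(p) fit_gam_aif(p, family = "poisson",
                                           shape_constrained = TRUE,
                                           log_time = FALSE, k = k),
    tps_negbin_linear = function(p) fit_gam_aif(p, family = "negbin",
                                                shape_constrained = FALSE,
                                                log_time = FALSE, k = k),
    tps_negbin_log = function(p) fit_gam_aif(p, family = "negbin",
                                             shape_constrained = FALSE,
                                             log_time = TRUE, k = k))
  fits <- lapply(names(model_fns), function(m) {
    lapply(preps, function(p) {
      f <- try(suppressWarnings(model_fns[[m]](p)), silent = TRUE)
      if (inherits(f, "try-error")) NULL else f
    })
  })
  names(fits) <- names(model_fns)
  ok <- Reduce(`&`, lapply(fits, function(fl)
    vapply(fl, Negate(is.null), logical(1))))
  failures <- which(!ok)
  comparison <- if (any(ok)) {
    compare_models_aic(lapply(fits, function(fl) fl[ok]),
                       reference = "tps_negbin_log")
  } else NULL
  structure(list(fits = fits, comparison = comparison, failures = failures),
            class = "aif_evolution")
}

#' @export
print.aif_evolution <- function(x, ...) {
  cat("Model evolution over", length(x$fits[[1]]), "examination(s)\n")
  if (length(x$failures)) {
    cat("  failed examinations:", paste(x$failures, collapse = ", "), "\n")
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Pseudo-leave-one-out missing-data study
#'
#' For each examination in turn and each missingness pattern, reduces that
#' examination to two manual samples (the others keep complete data),
#' refits the hierarchical model, predicts at the held-out manual times,
#' and scores the predictions against the full-data hierarchical fit (and
#' against ground truth when supplied).
#'
#' @param preps list of `aif_prep` objects (>= 3).
#' @param patterns subset of `c("first_last", "first_two", "last_two")`.
#' @param truths optional list of generator ground truths (same order as
#'   `preps`) for truth-referenced errors.
#' @param k_global,k_exam hierarchical basis dimensions.
#' @param drop_abss drop the reduced examination's ABSS stream (default).
#' @return A data.frame of class `aif_loo`: one row per examination x
#'   pattern with median/max absolute percentage error of the reduced-data
#'   predictions vs the full fit (`ape_vs_full`), vs truth when available
#'   (`ape_vs_truth`), and a convergence flag.
#' @export
run_pseudo_loo <- function(preps, patterns = c("first_last", "first_two",
                                               "last_two"),
                           truths = NULL, k_global = 20, k_exam = 5,
                           drop_abss = TRUE) {
  if (length(preps) < 3) stop("need at least 3 examinations", call. = FALSE)
  full_fit <- fit_hgam_aif(preps, k_global = k_global, k_exam = k_exam)
  ids <- full_fit$exam_ids
  rows <- list()
  for (i in seq_along(preps)) {
    manual_t <- with(preps[[i]]$exam$samples,
                     sort(unique(time_min[detector == "manual"])))
    for (pat in patterns) {
      reduced <- preps
      ex_red <- preps[[i]]
      ex_red$exam <- make_missing(ex_red$exam, pat, drop_abss = drop_abss)
      keep_rows <- match(interaction(ex_red$exam$samples$time_min,
                                     ex_red$exam$samples$detector,
                                     ex_red$exam$samples$compartment),
                         interaction(preps[[i]]$exam$samples$time_min,
                                     preps[[i]]$exam$samples$detector,
                                     preps[[i]]$exam$samples$compartment))
      ex_red$offsets <- preps[[i]]$offsets[keep_rows, , drop = FALSE]
      reduced[[i]] <- ex_red
      kept_t <- sort(unique(ex_red$exam$samples$time_min[
        ex_red$exam$samples$detector == "manual"]))
      held_out <- setdiff(manual_t, kept_t)
      fit_red <- try(suppressWarnings(
        fit_hgam_aif(reduced, k_global = k_global, k_exam = k_exam)),
        silent = TRUE)
      if (inherits(fit_red, "try-error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          exam = ids[i], pattern = pat, median_ape_vs_full = NA_real_,
          max_ape_vs_full = NA_real_, median_ape_vs_truth = NA_real_,
          max_ape_vs_truth = NA_real_, converged = FALSE)
        next
      }
      pr_red <- predict_aif(fit_red, held_out, exam = ids[i])$estimate
      pr_full <- predict_aif(full_fit, held_out, exam = ids[i])$estimate
      ape_full <- 100 * abs(pr_red - pr_full) / pr_full
      ape_truth <- if (!is.null(truths)) {
        tr <- truths[[i]]$f_fun(held_out)
        100 * abs(pr_red - tr) / tr
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        exam = ids[i], pattern = pat,
        median_ape_vs_full = stats::median(ape_full),
        max_ape_vs_full = max(ape_full),
        median_ape_vs_truth = stats::median(ape_truth),
        max_ape_vs_truth = max(ape_truth),
        converged = isTRUE(fit_red$engine$converged))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("aif_loo", "data.frame")
  attr(out, "full_fit") <- full_fit
  out
}
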