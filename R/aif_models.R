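# Assembly of the four AIF model classes over the engine: tri-exponential
# nonlinear Poisson regression, shape-constrained Poisson GAM, thin-plate
# negative-binomial GAM (linear or log time), and the hierarchical GAM
# across examinations. All fitting functions return an `aif_fit`.

#' Prepare an examination for model fitting
#'
#' Runs the preprocessing pipeline: background subtraction (when
#' pre-injection ABSS samples are present), descent selection, and the
#' offset sub-models (blood-to-plasma ratio spline, parent-fraction
#' sigmoid), then assembles the per-sample offsets.
#'
#' @param exam a `blood_exam`.
#' @param background subtract ABSS background (skipped with a message when
#'   no pre-injection samples exist).
#' @param descent restrict to the descent of the curve.
#' @param window peak-detection moving-average window (see
#'   [select_descent()]).
#' @param bpr_k basis dimension of the blood-to-plasma ratio spline.
#' @param dispersion_smooth_window smoothing window for the ABSS dispersion
#'   factor (see [assemble_offsets()]).
#' @return A list of class `aif_prep` with elements `exam`, `offsets`,
#'   `bpr_model`, `pf_params`.
#' @export
prepare_examination <- function(exam, background = TRUE, descent = TRUE,
                                window = 5L, bpr_k = 10,
                                dispersion_smooth_window = 9L) {
  if (background && any(exam$samples$pre_injection)) {
    exam <- subtract_background(exam)
  } else {
    exam$samples <- exam$samples[!exam$samples$pre_injection, , drop = FALSE]
  }
  if (descent) exam <- select_descent(exam, window)
  bpr_model <- fit_bpr(exam, k = bpr_k)
  pf_params <- fit_parent_fraction(exam$pf_measurements)
  offsets <- assemble_offsets(exam, bpr_model, pf_params,
                              dispersion_smooth_window)
  structure(list(exam = exam, offsets = offsets, bpr_model = bpr_model,
                 pf_params = pf_params), class = "aif_prep")
}

new_aif_fit <- function(kind, engine, meta) {
  structure(c(list(kind = kind, engine = engine), meta), class = "aif_fit")
}

prep_data <- function(prep) {
  s <- prep$exam$samples
  list(t = s$time_min, y = s$counts,
       log_tau = prep$offsets$log_tau_total,
       abss = as.numeric(s$detector == "abss"),
       exam_id = prep$exam$exam_id)
}

#' Fit the tri-exponential parametric AIF model
#'
#' Curve-stripping starting values followed by nonlinear Poisson
#' regression of the counts on \eqn{\log f(t, \theta) + \log \tau}, with a
#' multiplicative ABSS-bias fixed effect.
#'
#' @param prep an `aif_prep` from [prepare_examination()].
#' @param n_exp number of exponentials (default 3).
#' @return An `aif_fit` of kind `"parametric"`.
#' @export
fit_parametric_aif <- function(prep, n_exp = 3) {
  d <- prep_data(prep)
  start <- curve_strip_init(d$t, d$y / exp(d$log_tau), n_exp = n_exp)
  engine <- nls_poisson_fit(d$t, d$y, d$log_tau, start, abss = d$abss)
  new_aif_fit("parametric", engine,
              list(data = d, start = start, prep = prep,
                   beta_abss = engine$beta_abss))
}

#' Fit a generalized additive AIF model to one examination
#'
#' A penalized smooth of (log-)time plus an ABSS indicator fixed effect,
#' with REML-selected smoothing and, for the negative binomial, a jointly
#' profiled dispersion. `shape_constrained = TRUE` uses the monotone-
#' decreasing B-spline construction (Poisson only in the original
#' development, but any family is accepted); otherwise an unconstrained
#' thin-plate spline. The preferred configuration is
#' `family = "negbin", shape_constrained = FALSE, log_time = TRUE`.
#'
#' @param prep an `aif_prep`.
#' @param family `"poisson"` or `"negbin"`.
#' @param shape_constrained use the monotone-decreasing construction.
#' @param log_time smooth over `log(t)` instead of `t`.
#' @param k basis dimension (default 15).
#' @param control engine control, see [pg_control()].
#' @return An `aif_fit` of kind `"gam"`.
#' @export
fit_gam_aif <- function(prep, family = c("negbin", "poisson"),
                        shape_constrained = FALSE, log_time = TRUE,
                        k = 15, control = pg_control()) {
  family <- match.arg(family)
  d <- prep_data(prep)
  u <- if (log_time) log(d$t) else d$t
  fam <- aif_family(family)
  if (shape_constrained) {
    block <- scop_decreasing_design(u, k)
    terms <- list(pg_term_block(block, "s(time)"),
                  pg_term_linear(cbind(abss = d$abss), "abss"))
  } else {
    block <- tps_design(u, k, drop_const = TRUE, center = TRUE)
    terms <- list(pg_term_linear(cbind(intercept = 1, abss = d$abss),
                                 "fixed"),
                  pg_term_block(block, "s(time)"))
  }
  engine <- reml_optimize(terms, d$y, d$log_tau, fam, control = control)
  new_aif_fit("gam", engine,
              list(data = d, block = block, log_time = log_time,
                   shape_constrained = shape_constrained, prep = prep,
                   beta_abss = abss_coef_gam(engine, shape_constrained)))
}

abss_coef_gam <- function(engine, shape_constrained) {
  if (shape_constrained) {
    engine$coefficients[engine$term_idx[[2]]][1]
  } else {
    engine$coefficients[engine$term_idx[[1]]][2]
  }
}

#' Fit the hierarchical AIF model across examinations
#'
#' A joint negative-binomial fit to all examinations: per-examination
#' intercepts and per-examination ABSS-indicator effects (fixed), one
#' global smooth of log time (thin-plate, basis dimension `k_global`), and
#' a factor-smooth deviation block (thin-plate, dimension `k_exam` per
#' examination, one shared smoothing parameter, full-rank penalty so the
#' deviations shrink to zero exactly as the penalty grows).
#'
#' @param preps list of `aif_prep` objects (>= 2 examinations).
#' @param k_global global smooth basis dimension (default 20).
#' @param k_exam per-examination deviation basis dimension (default 5).
#' @param family `"negbin"` (default) or `"poisson"`.
#' @param control engine control.
#' @return An `aif_fit` of kind `"hgam"`.
#' @export
fit_hgam_aif <- function(preps, k_global = 20, k_exam = 5,
                         family = c("negbin", "poisson"),
                         control = pg_control()) {
  family <- match.arg(family)
  keep <- vapply(preps, function(p) nrow(p$exam$samples) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " examination(s) with no data",
            call. = FALSE)
    preps <- preps[keep]
  }
  if (length(preps) < 2) stop("need at least 2 examinations", call. = FALSE)
  dd <- lapply(preps, prep_data)
  ids <- vapply(dd, `[[`, "", "exam_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  g <- factor(rep(ids, vapply(dd, function(x) length(x$y), integer(1))),
              levels = ids)
  t_all <- unlist(lapply(dd, `[[`, "t"))
  y_all <- unlist(lapply(dd, `[[`, "y"))
  tau_all <- unlist(lapply(dd, `[[`, "log_tau"))
  abss_all <- unlist(lapply(dd, `[[`, "abss"))
  u <- log(t_all)
  G <- nlevels(g)
  Xg <- stats::model.matrix(~ g - 1)
  colnames(Xg) <- paste0("exam_", levels(g))
  Xab <- Xg * abss_all
  colnames(Xab) <- paste0("abss_", levels(g))
  global <- tps_design(u, k_global, drop_const = TRUE, center = TRUE)
  fs <- factor_smooth_design(u, g, k_exam)
  terms <- list(pg_term_linear(cbind(Xg, Xab), "fixed"),
                pg_term_block(global, "s(time)"),
                pg_term_block(fs, "s(time, exam)"))
  engine <- reml_optimize(terms, y_all, tau_all, aif_family(family),
                          control = control)
  b_fixed <- engine$coefficients[engine$term_idx[[1]]]
  new_aif_fit("hgam", engine,
              list(data = list(t = t_all, y = y_all, log_tau = tau_all,
                               abss = abss_all, group = g),
                   global_block = global, fs_block = fs, exam_ids = ids,
                   log_time = TRUE, preps = preps,
                   intercepts = stats::setNames(b_fixed[seq_len(G)], ids),
                   beta_abss = stats::setNames(b_fixed[G + seq_len(G)], ids)))
}

# prediction design on the *working* (linearized) coefficient scale plus
# the corresponding linear predictor; shared by estimate and interval
predict_design <- function(fit, t, reference, exam = NULL) {
  eng <- fit$engine
  b <- eng$coefficients
  if (fit$kind == "parametric") {
    params <- eng$params
    K <- length(params$A)
    Et <- exp(outer(t, -params$gamma))
    f <- drop(Et %*% params$A)
    eta <- log(f)
    W <- Et / f
    Xw <- cbind(W * rep(params$A, each = length(t)),
                -t * W * rep(params$A * params$gamma, each = length(t)))
    if (!is.null(eng$beta_abss)) {
      ab <- as.numeric(reference == "abss")
      eta <- eta + ab * eng$beta_abss
      Xw <- cbind(Xw, rep(ab, length(t)))
    } else if (reference == "abss") {
      stop("fit has no ABSS data: reference = \"abss\" unavailable",
           call. = FALSE)
    }
    return(list(eta = eta, Xw = Xw))
  }
  if (fit$kind == "gam") {
    u <- if (fit$log_time) log(t) else t
    B <- basis_eval(fit$block, u)
    ab <- as.numeric(reference == "abss")
    if (fit$shape_constrained) {
      bs <- b[eng$term_idx[[1]]]
      eta <- drop(B %*% fit$block$transform(bs)) + ab * fit$beta_abss
      Xw <- cbind(B %*% fit$block$jacobian(bs), rep(ab, length(t)))
    } else {
      bf <- b[eng$term_idx[[1]]]
      bsm <- b[eng$term_idx[[2]]]
      eta <- bf[1] + ab * bf[2] + drop(B %*% bsm)
      Xw <- cbind(1, rep(ab, length(t)), B)
    }
    return(list(eta = eta, Xw = Xw))
  }
  # hgam
  if (is.null(exam)) exam <- fit$exam_ids[1]
  exam <- as.character(exam)
  if (!exam %in% fit$exam_ids) stop("unknown examination: ", exam,
                                    call. = FALSE)
  gpos <- match(exam, fit$exam_ids)
  G <- length(fit$exam_ids)
  u <- log(t)
  Bg <- basis_eval(fit$global_block, u)
  Bf <- basis_eval(fit$fs_block, u, group = exam)
  ab <- as.numeric(reference == "abss")
  Xfix <- matrix(0, length(t), 2 * G)
  Xfix[, gpos] <- 1
  Xfix[, G + gpos] <- ab
  Xw <- cbind(Xfix, Bg, Bf)
  eta <- drop(Xw %*% b)
  list(eta = eta, Xw = Xw)
}

#' Predict the decay-corrected parent-plasma curve
#'
#' Evaluates a fitted AIF at a time grid with pointwise intervals from the
#' coefficient covariance (delta method on the log scale, exponentiated).
#' The manual reference excludes the ABSS bias term (manual samples are
#' treated as the gold standard); `reference = "abss"` multiplies by
#' `exp(beta_abss)`.
#'
#' @param fit an `aif_fit`.
#' @param t_grid times (minutes).
#' @param reference `"manual"` (default) or `"abss"`.
#' @param exam examination id (hierarchical fits only).
#' @param level interval coverage (default 0.95).
#' @return A data.frame with `time_min`, `estimate`, `lower`, `upper`.
#' @export
predict_aif <- function(fit, t_grid, reference = c("manual", "abss"),
                        exam = NULL, level = 0.95) {
  reference <- match.arg(reference)
  if (reference == "abss" && !any(fit$data$abss > 0)) {
    stop("fit has no ABSS data: reference = \"abss\" unavailable",
         call. = FALSE)
  }
  pd <- predict_design(fit, t_grid, reference, exam)
  se <- sqrt(pmax(rowSums((pd$Xw %*% fit$engine$Vb) * pd$Xw), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time_min = t_grid,
             estimate = exp(pd$eta),
             lower = exp(pd$eta - z * se),
             upper = exp(pd$eta + z * se))
}

#' Compare fitted models by AIC across examinations
#'
#' Tabulates per-examination AIC for each model and the difference
#' \eqn{\Delta AIC = AIC_{reference} - AIC_{model}} against a declared
#' reference model, plus its mean and range. Negative \eqn{\Delta AIC}
#' means the reference model is preferred (lower AIC).
#'
#' @param fits_by_model named list; each element is a list of `aif_fit`
#'   objects for the same examinations (same data and offsets).
#' @param reference name of the reference model (default: first).
#' @return A list of class `aif_aic_comparison` with the AIC `table`
#'   (exams x models), the `delta` table, and per-model `mean_delta` and
#'   `range_delta`.
#' @export
compare_models_aic <- function(fits_by_model,
                               reference = names(fits_by_model)[1]) {
  models <- names(fits_by_model)
  if (!reference %in% models) stop("unknown reference model", call. = FALSE)
  n_exam <- length(fits_by_model[[1]])
  y_ref <- lapply(fits_by_model[[1]], function(f) f$engine$y)
  for (m in models) {
    if (length(fits_by_model[[m]]) != n_exam) {
      stop("models were fitted to different examination sets", call. = FALSE)
    }
    for (i in seq_len(n_exam)) {
      if (!identical(as.numeric(fits_by_model[[m]][[i]]$engine$y),
                     as.numeric(y_ref[[i]]))) {
        stop("mismatched data between fits for examination ", i,
             call. = FALSE)
      }
    }
  }
  aic <- sapply(models, function(m)
    vapply(fits_by_model[[m]], model_aic, numeric(1)))
  aic <- matrix(aic, nrow = n_exam, dimnames = list(NULL, models))
  delta <- aic[, reference] - aic
  structure(list(table = aic, delta = delta,
                 mean_delta = colMeans(delta),
                 range_delta = apply(delta, 2, range),
                 reference = reference),
            class = "aif_aic_comparison")
}

#' @export
print.aif_aic_comparison <- function(x, ...) {
  cat("AIC comparison (delta = AIC[", x$reference,
      "] - AIC[model]; negative favours the reference)\n", sep = "")
  tab <- rbind(mean_delta = x$mean_delta,
               min_delta = x$range_delta[1, ],
               max_delta = x$range_delta[2, ])
  print(round(tab, 2))
  invisible(x)
}
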