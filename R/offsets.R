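# Exposure offsets: every multiplicative factor that converts the modelled
# decay-corrected parent-plasma rate f(t) (counts / s / mL at injection-time
# calibration) into the expected number of recorded counts for a sample.
# Convention used throughout: lambda_i = f(t_i) * tau_i, so components that
# *reduce* the measured signal (decay, parent fraction < 1) enter tau as
# factors < 1 or as divisors respectively.

#' Radioactive decay factor
#'
#' Fraction of activity remaining `t_min` minutes after injection.
#'
#' @param t_min elapsed time in minutes (>= 0).
#' @param half_life_min isotope half-life in minutes (> 0).
#' @return `2^(-t/half_life)`, in `(0, 1]`.
#' @export
decay_factor <- function(t_min, half_life_min) {
  if (any(half_life_min <= 0)) stop("half_life_min must be > 0", call. = FALSE)
  if (any(t_min < 0)) stop("t_min must be >= 0", call. = FALSE)
  2^(-t_min / half_life_min)
}

#' Gamma-counter volume calibration factor
#'
#' Historical calibration for a small deviation from linearity of the gamma
#' counter with sample volume.
#'
#' @param volume_mL sample volume (>= 0).
#' @param rho_per_mL calibration factor \eqn{\rho}.
#' @return `exp(rho * volume)`.
#' @export
volume_calibration_factor <- function(volume_mL, rho_per_mL) {
  exp(rho_per_mL * volume_mL)
}

cumtrapz <- function(t, v) {
  n <- length(v)
  c(0, cumsum((v[-1] + v[-n]) / 2 * diff(t)))
}

check_uniform_grid <- function(times_s) {
  dt <- diff(times_s)
  if (length(dt) == 0) stop("need at least two grid points", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt[1]), 1)) {
    stop("time grid is not uniform: resample to a uniform grid first",
         call. = FALSE)
  }
  dt[1]
}

#' Correct an ABSS series for external dispersion
#'
#' Inverts the exponential smearing of the continuous detector signal caused
#' by tracer sticking in the tubing. The cumulative true signal is
#' \eqn{\int_0^t C_{true} = \kappa C_{meas}(t) + \int_0^t C_{meas}},
#' integrated by the trapezoidal rule on the uniform grid, and the true
#' signal is then recovered by central differencing over \eqn{2\Delta t}
#' (one-sided over \eqn{\Delta t} at the endpoints).
#'
#' @param times_s uniform time grid in seconds.
#' @param values measured signal on the grid.
#' @param kappa_s dispersion constant \eqn{\kappa} in seconds (>= 0);
#'   `kappa_s = 0` returns the input unchanged.
#' @return The dispersion-corrected series on the same grid.
#' @export
dispersion_correct <- function(times_s, values, kappa_s) {
  if (kappa_s < 0) stop("kappa_s must be >= 0", call. = FALSE)
  dt <- check_uniform_grid(times_s)
  if (kappa_s == 0) return(values)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  I_true <- kappa_s * values + cumtrapz(times_s, values)
  n <- length(values)
  out <- numeric(n)
  if (n > 2) {
    out[2:(n - 1)] <- (I_true[3:n] - I_true[1:(n - 2)]) / (2 * dt)
  }
  out[1] <- (I_true[2] - I_true[1]) / dt
  out[n] <- (I_true[n] - I_true[n - 1]) / dt
  out
}

#' Per-sample dispersion offset component
#'
#' The model predicts the *true* curve, so the ABSS offset component maps
#' the true rate onto the measured expectation: `uncorrected / corrected`.
#' Manual samples drawn after the cutoff never pass through the tubing and
#' receive a component of exactly 1.
#'
#' @param corrected dispersion-corrected value (> 0).
#' @param uncorrected measured value (> 0).
#' @param detector `"abss"` or `"manual"`.
#' @param time_min draw time in minutes.
#' @param cutoff_min tubing cutoff (default 10 min).
#' @return The multiplicative offset component.
#' @export
dispersion_offset_component <- function(corrected, uncorrected, detector,
                                        time_min, cutoff_min = 10) {
  if (detector == "manual" && time_min > cutoff_min) return(1)
  if (corrected <= 0 || uncorrected <= 0) {
    stop("dispersion component needs positive corrected and uncorrected ",
         "values", call. = FALSE)
  }
  uncorrected / corrected
}

#' Fit the whole-blood-to-plasma ratio curve
#'
#' Pairs every manual whole-blood sample with the plasma sample centrifuged
#' from it (matched by draw time), forms decay-matched count rates per
#' (volume x duration), and fits a penalized thin-plate regression spline
#' (basis dimension `k`, REML smoothing, Gaussian working family) to the
#' whole-blood / plasma ratio over time.
#'
#' @param exam a `blood_exam`.
#' @param k basis dimension (default 10).
#' @return An object of class `bpr_model` with a `predict(t)`-style
#'   interface via [predict_bpr()]; extrapolation beyond the sampled range
#'   is constant at the boundary value. With fewer than 4 pairs, falls back
#'   to the time-constant mean ratio with a warning.
#' @export
fit_bpr <- function(exam, k = 10) {
  s <- exam$samples[!exam$samples$pre_injection, , drop = FALSE]
  man <- s[s$detector == "manual", , drop = FALSE]
  wb <- man[man$compartment == "whole_blood", , drop = FALSE]
  pl <- man[man$compartment == "plasma", , drop = FALSE]
  shared <- intersect(wb$time_min, pl$time_min)
  wb <- wb[match(shared, wb$time_min), , drop = FALSE]
  pl <- pl[match(shared, pl$time_min), , drop = FALSE]
  rho <- exam$rho_per_mL
  rate <- function(d) d$counts / (d$duration_s * d$volume_mL *
                                    volume_calibration_factor(d$volume_mL, rho))
  ratio <- rate(wb) / rate(pl)  # decay cancels at a shared draw time
  tt <- shared
  if (length(ratio) < 4) {
    warning("fewer than 4 whole-blood/plasma pairs: using a time-constant ",
            "mean BPR", call. = FALSE)
    return(structure(list(constant = mean(ratio), range = range(tt, 0, 1)),
                     class = "bpr_model"))
  }
  k <- min(k, length(unique(tt)))
  block <- tps_design(tt, k)
  fit <- reml_optimize(list(pg_term_block(block, "bpr")), y = ratio,
                       log_offset = rep(0, length(ratio)),
                       family = aif_family("gaussian"))
  structure(list(block = block, fit = fit, range = range(tt),
                 times = tt, ratio = ratio), class = "bpr_model")
}

#' Evaluate a fitted blood-to-plasma ratio curve
#'
#' @param model a `bpr_model` from [fit_bpr()].
#' @param t_min times in minutes; values outside the fitted range are held
#'   constant at the boundary.
#' @param floor lower bound on the returned ratio: the true ratio is
#'   physically positive, but a spline fitted to very noisy ratios can
#'   overshoot below zero (default 0.01).
#' @return Ratio estimates `r(t) > 0`.
#' @export
predict_bpr <- function(model, t_min, floor = 0.01) {
  if (!is.null(model$constant)) {
    return(pmax(rep(model$constant, length(t_min)), floor))
  }
  t_clamp <- pmin(pmax(t_min, model$range[1]), model$range[2])
  X <- basis_eval(model$block, t_clamp)
  pmax(drop(X %*% model$fit$coefficients), floor)
}

#' Fit the plasma parent-fraction sigmoid
#'
#' Fits the three-parameter Hill-type sigmoid
#' \eqn{pf(t) = a + (1 - a) / (1 + (t/t_{50})^k)} to measured parent
#' fractions by bounded least squares with multiple starts over a log-grid
#' of midpoints, so `pf(0) = 1` and the curve decreases towards the floor
#' `a`.
#'
#' @param pf_measurements data.frame with `time_min` (> 0) and
#'   `parent_fraction` in `[0, 1]`; at least 3 rows.
#' @param n_starts number of multi-start midpoints (>= 5).
#' @return An object of class `pf_sigmoid` with elements `a`, `t50_min`,
#'   `k` and the achieved residual sum of squares.
#' @export
fit_parent_fraction <- function(pf_measurements, n_starts = 7) {
  tt <- pf_measurements$time_min
  pf <- pf_measurements$parent_fraction
  if (length(tt) < 3) stop("need at least 3 parent-fraction measurements",
                           call. = FALSE)
  if (any(tt <= 0)) stop("parent-fraction times must be > 0", call. = FALSE)
  if (any(pf < 0 | pf > 1)) stop("parent fractions must be in [0, 1]",
                                 call. = FALSE)
  obj <- function(par) {
    a <- stats::plogis(par[1]); t50 <- exp(par[2]); kk <- exp(par[3])
    sum((pf - (a + (1 - a) / (1 + (tt / t50)^kk)))^2)
  }
  t50_grid <- exp(seq(log(max(min(tt), 0.5)), log(max(tt) * 2),
                      length.out = max(5, n_starts)))
  best <- NULL
  for (t50_0 in t50_grid) {
    for (k0 in c(1, 2.5)) {
      res <- try(stats::optim(c(stats::qlogis(0.05), log(t50_0), log(k0)),
                              obj, method = "Nelder-Mead",
                              control = list(maxit = 2000,
                                             reltol = 1e-12)), silent = TRUE)
      if (!inherits(res, "try-error") &&
          (is.null(best) || res$value < best$value)) best <- res
    }
  }
  if (is.null(best)) stop("parent-fraction sigmoid fit failed from every start",
                          call. = FALSE)
  # polish from the best start
  best <- stats::optim(best$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  structure(list(a = stats::plogis(best$par[1]), t50_min = exp(best$par[2]),
                 k = exp(best$par[3]), rss = best$value), class = "pf_sigmoid")
}

#' Evaluate a fitted parent-fraction sigmoid
#'
#' @param params a `pf_sigmoid` from [fit_parent_fraction()] (or a list with
#'   `a`, `t50_min`, `k`).
#' @param t_min times in minutes (>= 0).
#' @return Parent fraction estimates in `(a, 1]`, with `pf(0) = 1`.
#' @export
pf_sigmoid <- function(params, t_min) {
  params$a + (1 - params$a) / (1 + (t_min / params$t50_min)^params$k)
}

abss_dispersion_factors <- function(exam, smooth_window = 9L) {
  s <- exam$samples
  abss <- which(s$detector == "abss" & !s$pre_injection)
  if (length(abss) < 3 || exam$kappa_s == 0) {
    return(rep(1, length(abss)))
  }
  cps <- s$counts[abss] / s$duration_s[abss]
  sm <- pmax(moving_average(cps, smooth_window), 1e-8)
  corrected <- dispersion_correct(s$time_min[abss] * 60, sm, exam$kappa_s)
  fac <- sm / pmax(corrected, 1e-8)
  # guard against pathological factors where counts approach zero
  pmin(pmax(fac, 0.2), 5)
}

#' Assemble per-sample model offsets
#'
#' Computes every multiplicative exposure component and the total log offset
#' \eqn{\log \tau_i} for each post-injection sample:
#' \deqn{\tau_i = duration \cdot volume \cdot e^{\rho vol} \cdot
#'   2^{-t/T_{1/2}} \cdot dispersion \cdot bpr / PF(t)}
#' so that the expected counts are `f(t_i) * tau_i` with `f` the
#' decay-corrected parent-plasma rate. The blood-to-plasma ratio multiplies
#' whole-blood samples only (1 for plasma); the parent fraction divides all
#' samples; the ABSS dispersion component is `uncorrected/corrected` from a
#' smoothed counts-per-second series, 1 for manual samples.
#'
#' @param exam a `blood_exam` (post-injection samples only, e.g. after
#'   [subtract_background()] and [select_descent()]).
#' @param bpr_model a `bpr_model` from [fit_bpr()].
#' @param pf_params a `pf_sigmoid` from [fit_parent_fraction()].
#' @param dispersion_smooth_window moving-average window (in ABSS samples)
#'   used to stabilize the dispersion factor; 1 uses the raw counts.
#' @return A data.frame of class `aif_offsets`, one row per sample, with
#'   each component and `log_tau_total`.
#' @export
assemble_offsets <- function(exam, bpr_model, pf_params,
                             dispersion_smooth_window = 9L) {
  s <- exam$samples
  if (any(s$pre_injection)) {
    stop("assemble_offsets expects post-injection samples only", call. = FALSE)
  }
  n <- nrow(s)
  comp <- data.frame(
    duration_s = s$duration_s,
    volume_mL = s$volume_mL,
    vol_calibration = volume_calibration_factor(s$volume_mL, exam$rho_per_mL),
    decay = decay_factor(s$time_min, exam$half_life_min),
    dispersion_component = rep(1, n),
    bpr = rep(1, n),
    inv_parent_fraction = 1 / pf_sigmoid(pf_params, s$time_min)
  )
  abss <- s$detector == "abss"
  comp$dispersion_component[abss] <-
    abss_dispersion_factors(exam, dispersion_smooth_window)
  wb <- s$compartment == "whole_blood"
  comp$bpr[wb] <- predict_bpr(bpr_model, s$time_min[wb])
  for (nm in names(comp)) {
    bad <- which(!is.finite(comp[[nm]]) | comp[[nm]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("offset component '%s' is non-positive for sample row %d",
                   nm, bad[1L]), call. = FALSE)
    }
  }
  comp$log_tau_total <- rowSums(log(as.matrix(comp)))
  class(comp) <- c("aif_offsets", "data.frame")
  comp
}
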