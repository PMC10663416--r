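# Synthetic blood examinations with known ground truth, emulating the
# acquisition protocol: a ~1 Hz ABSS whole-blood stream for the first
# 10 min (with external dispersion, a calibration bias relative to the
# manual samples, and Poisson background), paired manual whole-blood and
# plasma draws at 14 scheduled times, and parent-fraction measurements at
# 8 scheduled times.

#' Default acquisition schedules
#'
#' Manual draw times and parent-fraction measurement times (minutes post
#' injection) of the acquisition protocol the generator emulates.
#'
#' @format Numeric vectors of times in minutes.
#' @export
MANUAL_TIMES_MIN <- c(1, 3, 5, 7, 9, 10.5, 20, 30, 40, 50, 60, 70, 80, 90)

#' @rdname MANUAL_TIMES_MIN
#' @export
PF_TIMES_MIN <- c(1, 3, 5, 10.5, 20, 40, 60, 90)

#' Simulation configuration
#'
#' Defaults reproduce the acquisition protocol the package targets: ABSS
#' sampling each second for 10 minutes, manual draws at 1, 3, 5, 7, 9,
#' 10.5, 20, 30, 40, 50, 60, 70, 80 and 90 min, parent fraction at 1, 3, 5,
#' 10.5, 20, 40, 60 and 90 min, manual whole-blood volumes of 1-3 mL and
#' plasma volumes of 0.8-1.5 mL, a carbon-11 half-life of 20.36 min, and a
#' 10% multiplicative ABSS bias. The post-peak truth is a decreasing
#' tri-exponential; the ascent is linear from injection to the peak.
#'
#' @param A,gamma tri-exponential truth amplitudes (counts/s/mL at
#'   injection-time calibration) and rates (per minute).
#' @param peak_time_min time of the whole-blood peak.
#' @param bpr_fun true whole-blood-to-plasma ratio function of time (min).
#' @param pf true parent-fraction sigmoid parameters (`a`, `t50_min`, `k`).
#' @param family `"poisson"` or `"negbin"`; `psi` the negbin dispersion.
#' @param abss_bias multiplicative ABSS calibration bias (manual = 1).
#' @param abss_rate_hz ABSS sampling rate; `abss_window_min` its duration.
#' @param manual_times_min,pf_times_min sampling schedules.
#' @param manual_duration_s gamma-counter counting duration per manual
#'   sample.
#' @param manual_wb_vol_range,plasma_vol_range uniform volume ranges (mL).
#' @param abss_vol_mL_per_s nominal ABSS draw volume per second (absorbed,
#'   with detector efficiency, into the ABSS bias term).
#' @param kappa_s external dispersion constant; 0 disables dispersion.
#' @param rho_per_mL gamma-counter volume-calibration factor.
#' @param background_rate_cps detector background rate (counts/s).
#' @param n_pre_injection number of pre-injection ABSS background samples.
#' @param pf_hplc_counts effective HPLC count budget per parent-fraction
#'   measurement; observed fractions are binomial proportions
#'   `rbinom(pf_hplc_counts, pf) / pf_hplc_counts`, so measurement error
#'   scales as \eqn{\sqrt{pf(1-pf)/n}} like real count-derived fractions.
#' @param half_life_min isotope half-life.
#' @param seed default RNG seed for [simulate_examination()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(A = c(5e4, 1e4, 2e3), gamma = c(3, 0.3, 0.03),
                       peak_time_min = 0.7,
                       bpr_fun = function(t) 0.8 + 0.2 * exp(-t / 20),
                       pf = list(a = 0.05, t50_min = 10, k = 2),
                       family = "poisson", psi = 0,
                       abss_bias = 1.10,
                       abss_rate_hz = 1, abss_window_min = 10,
                       manual_times_min = MANUAL_TIMES_MIN,
                       pf_times_min = PF_TIMES_MIN,
                       manual_duration_s = 10,
                       manual_wb_vol_range = c(1, 3),
                       plasma_vol_range = c(0.8, 1.5),
                       abss_vol_mL_per_s = 0.01,
                       kappa_s = 2.5, rho_per_mL = 0.005,
                       background_rate_cps = 2,
                       n_pre_injection = 30,
                       pf_hplc_counts = 2000,
                       half_life_min = 20.36,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$A > 0), all(cfg$gamma > 0), cfg$peak_time_min > 0,
            cfg$psi >= 0, cfg$abss_bias > 0, cfg$kappa_s >= 0,
            cfg$half_life_min > 0, !is.unsorted(cfg$manual_times_min),
            !is.unsorted(cfg$pf_times_min))
  structure(cfg, class = "sim_config")
}

#' Forward external dispersion of a uniformly sampled signal
#'
#' Discrete convolution with the exponential kernel
#' \eqn{(1/\kappa) e^{-t/\kappa}}, normalized to unit mass on the grid, so
#' the smeared signal conserves total counts; `kappa_s = 0` is the
#' identity. This is the physical forward operation that
#' [dispersion_correct()] inverts.
#'
#' @param times_s uniform time grid (seconds).
#' @param values signal on the grid.
#' @param kappa_s dispersion constant (seconds).
#' @return The dispersed signal on the same grid.
#' @export
apply_forward_dispersion <- function(times_s, values, kappa_s) {
  dt <- check_uniform_grid(times_s)
  if (kappa_s == 0) return(values)
  J <- ceiling(12 * kappa_s / dt)
  w <- exp(-(0:J) * dt / kappa_s)
  w <- w / sum(w)
  n <- length(values)
  padded <- c(rep(0, J), values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(w * padded[(J + i):i])
  }
  out
}

truth_curve <- function(config) {
  params <- triexp_params(config$A, config$gamma)
  peak <- config$peak_time_min
  f_peak <- triexp_eval(params, peak)
  function(t) {
    ifelse(t >= peak, triexp_eval(params, pmax(t, peak)),
           f_peak * pmax(t, 0) / peak)
  }
}

#' Simulate a complete blood examination with known ground truth
#'
#' Builds the true parent-plasma curve (linear ascent, tri-exponential
#' descent), composes whole-blood and plasma signals through the true
#' blood-to-plasma ratio and parent fraction, applies forward dispersion
#' and the ABSS bias to the continuous stream, adds Poisson background
#' counts, and draws all counts from the configured family. Deterministic
#' given the seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param exam_id examination label.
#' @return A list with `exam` (a `blood_exam`, including pre-injection
#'   background samples) and `truth` (the ground-truth ledger: true curve
#'   function and parameters, BPR and PF functions, ABSS bias, dispersion
#'   constant, per-sample true expected counts `lambda`, and the peak
#'   time).
#' @export
simulate_examination <- function(config = sim_config(), seed = config$seed,
                                 exam_id = "sim") {
  set.seed(seed)
  fam <- aif_family(if (config$family == "negbin") "negbin" else "poisson",
                    psi = config$psi)
  f_true <- truth_curve(config)
  pf_fun <- function(t) pf_sigmoid(config$pf, t)
  bpr_fun <- config$bpr_fun
  hl <- config$half_life_min
  rho <- config$rho_per_mL

  dt_s <- 1 / config$abss_rate_hz
  t_s <- seq(dt_s, config$abss_window_min * 60, by = dt_s)
  t_abss <- t_s / 60
  # whole-blood activity concentration at the detector (counts/s/mL)
  a_wb <- f_true(t_abss) * decay_factor(t_abss, hl) * bpr_fun(t_abss) /
    pf_fun(t_abss)
  a_disp <- apply_forward_dispersion(t_s, a_wb, config$kappa_s)
  vol_abss <- config$abss_vol_mL_per_s * dt_s
  lam_abss <- a_disp * dt_s * vol_abss *
    volume_calibration_factor(vol_abss, rho) * config$abss_bias
  y_abss <- family_draw(fam, pmax(lam_abss, 1e-12)) +
    stats::rpois(length(lam_abss), config$background_rate_cps * dt_s)

  pre <- data.frame(
    time_min = 0, counts = stats::rpois(config$n_pre_injection,
                                        config$background_rate_cps * dt_s),
    duration_s = dt_s, volume_mL = vol_abss,
    detector = "abss", compartment = "whole_blood", pre_injection = TRUE)

  abss <- data.frame(time_min = t_abss, counts = y_abss, duration_s = dt_s,
                     volume_mL = vol_abss, detector = "abss",
                     compartment = "whole_blood", pre_injection = FALSE)

  mt <- config$manual_times_min
  vol_wb <- stats::runif(length(mt), config$manual_wb_vol_range[1],
                         config$manual_wb_vol_range[2])
  vol_pl <- stats::runif(length(mt), config$plasma_vol_range[1],
                         config$plasma_vol_range[2])
  dur <- config$manual_duration_s
  lam_wb <- f_true(mt) * dur * vol_wb * volume_calibration_factor(vol_wb, rho) *
    decay_factor(mt, hl) * bpr_fun(mt) / pf_fun(mt)
  lam_pl <- f_true(mt) * dur * vol_pl * volume_calibration_factor(vol_pl, rho) *
    decay_factor(mt, hl) / pf_fun(mt)
  wb <- data.frame(time_min = mt, counts = family_draw(fam, lam_wb),
                   duration_s = dur, volume_mL = vol_wb, detector = "manual",
                   compartment = "whole_blood", pre_injection = FALSE)
  pl <- data.frame(time_min = mt, counts = family_draw(fam, lam_pl),
                   duration_s = dur, volume_mL = vol_pl, detector = "manual",
                   compartment = "plasma", pre_injection = FALSE)

  n_hplc <- config$pf_hplc_counts
  pf_meas <- data.frame(
    time_min = config$pf_times_min,
    parent_fraction = pmax(stats::rbinom(length(config$pf_times_min),
                                         n_hplc,
                                         pf_fun(config$pf_times_min)) /
                             n_hplc, 0.001))

  exam <- blood_exam(rbind(pre, abss, wb, pl), pf_meas,
                     half_life_min = hl, kappa_s = config$kappa_s,
                     rho_per_mL = rho, exam_id = exam_id)
  truth <- list(
    f_fun = f_true, params = triexp_params(config$A, config$gamma),
    bpr_fun = bpr_fun, pf = config$pf, abss_bias = config$abss_bias,
    psi = config$psi, kappa_s = config$kappa_s,
    peak_time_min = config$peak_time_min,
    lambda = list(abss = lam_abss, manual_wb = lam_wb, plasma = lam_pl),
    config = config, seed = seed
  )
  list(exam = exam, truth = truth)
}

#' Simulate a suite of examinations sharing a smooth curve family
#'
#' Generates `n_exams` examinations whose true curves are drawn from a
#' shared family: the base tri-exponential amplitudes and rates are
#' jittered log-normally per examination (so shapes are similar but not
#' identical, as across participants of one study), and counts are drawn
#' independently per examination.
#'
#' @param n_exams number of examinations.
#' @param config base [sim_config()].
#' @param jitter_A,jitter_gamma log-normal SD of the per-examination
#'   amplitude and rate multipliers (0 for identical truths).
#' @param seed suite seed; examination `i` uses `seed + i` for its counts.
#' @return A list with `sims` (each a `simulate_examination()` result) and
#'   the per-examination configs.
#' @export
simulate_suite <- function(n_exams = 10, config = sim_config(),
                           jitter_A = 0.15, jitter_gamma = 0.1,
                           seed = config$seed) {
  set.seed(seed)
  mult_A <- matrix(exp(stats::rnorm(n_exams * length(config$A), 0, jitter_A)),
                   n_exams)
  mult_g <- matrix(exp(stats::rnorm(n_exams * length(config$gamma), 0,
                                    jitter_gamma)), n_exams)
  sims <- vector("list", n_exams)
  for (i in seq_len(n_exams)) {
    cfg_i <- config
    cfg_i$A <- config$A * mult_A[i, ]
    cfg_i$gamma <- config$gamma * mult_g[i, ]
    sims[[i]] <- simulate_examination(cfg_i, seed = seed + i,
                                      exam_id = sprintf("exam_%02d", i))
  }
  list(sims = sims, seed = seed)
}

#' Remove manual samples to emulate incomplete examinations
#'
#' Retains exactly two manual draw times (with both their whole-blood and
#' plasma samples) according to the pattern, drops the rest, and by default
#' also drops the ABSS stream, so the examination is reduced to two manual
#' data points plus its parent-fraction measurements.
#'
#' @param exam a `blood_exam` with at least 2 manual draw times.
#' @param pattern `"first_last"`, `"first_two"` or `"last_two"`.
#' @param drop_abss drop the ABSS stream (default `TRUE`).
#' @return The reduced `blood_exam`.
#' @export
make_missing <- function(exam, pattern = c("first_last", "first_two",
                                           "last_two"),
                         drop_abss = TRUE) {
  pattern <- match.arg(pattern)
  s <- exam$samples
  mt <- sort(unique(s$time_min[s$detector == "manual" & !s$pre_injection]))
  if (length(mt) < 2) stop("need at least 2 manual samples", call. = FALSE)
  keep_t <- switch(pattern,
    first_last = c(mt[1], mt[length(mt)]),
    first_two = mt[1:2],
    last_two = mt[c(length(mt) - 1, length(mt))])
  keep <- (s$detector == "manual" & s$time_min %in% keep_t) | s$pre_injection
  if (!drop_abss) keep <- keep | s$detector == "abss"
  exam$samples <- s[keep, , drop = FALSE]
  rownames(exam$samples) <- NULL
  validate_exam(exam)
  exam
}
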