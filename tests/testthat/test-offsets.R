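test_that("decay factor has half-life semantics and is multiplicative", {
  expect_equal(decay_factor(0, 20.36), 1)
  expect_equal(decay_factor(20.36, 20.36), 0.5)
  expect_equal(decay_factor(2 * 20.36, 20.36), 0.25)
  expect_error(decay_factor(5, -1), "half_life")
  t1 <- c(1, 7.3, 40)
  t2 <- c(2.2, 11, 0.5)
  expect_equal(decay_factor(t1 + t2, 20.36),
               decay_factor(t1, 20.36) * decay_factor(t2, 20.36))
  expect_true(all(diff(decay_factor(seq(0, 90, by = 0.5), 20.36)) < 0))
})

test_that("volume calibration is exp(rho * vol)", {
  expect_equal(volume_calibration_factor(3, 0), 1)
  expect_equal(volume_calibration_factor(0, 0.4), 1)
  expect_equal(volume_calibration_factor(3, 0.005), exp(0.015))
})

test_that("dispersion correction inverts the forward convolution", {
  t_s <- seq(1, 300, by = 1)
  f <- 5e4 * exp(-3 * t_s / 60) + 1e4 * exp(-0.3 * t_s / 60) +
    2e3 * exp(-0.03 * t_s / 60)

  expect_identical(dispersion_correct(t_s, f, 0), f)
  expect_identical(apply_forward_dispersion(t_s, f, 0), f)
  const <- rep(7, 100)
  expect_equal(dispersion_correct(seq_len(100), const, 2.5), const,
               tolerance = 1e-10)
  expect_error(dispersion_correct(c(1, 2, 4), 1:3, 2.5), "uniform")
  expect_error(apply_forward_dispersion(c(1, 2, 4), 1:3, 2.5), "uniform")

  # oracle: direct numerical convolution with the exponential kernel,
  # round-trip must recover the original to < 1% RMS of its maximum
  for (kappa in c(1, 2.5, 5)) {
    J <- ceiling(12 * kappa)
    w <- exp(-(0:J) / kappa)
    w <- w / sum(w)
    padded <- c(rep(0, J), f)
    dispersed <- vapply(seq_along(f),
                        function(i) sum(w * padded[(J + i):i]), numeric(1))
    expect_equal(apply_forward_dispersion(t_s, f, kappa), dispersed,
                 tolerance = 1e-12)
    recovered <- dispersion_correct(t_s, dispersed, kappa)
    interior <- 3:(length(f) - 2)
    rms <- sqrt(mean((recovered[interior] - f[interior])^2))
    expect_lt(rms / max(f), 0.01)
  }

  # unit-mass kernel conserves the total for a series decaying to ~0
  g <- exp(-(1:300) / 20)
  expect_equal(sum(apply_forward_dispersion(1:300, g, 2.5)), sum(g),
               tolerance = 1e-3)
})

test_that("dispersion offset component follows the stated convention", {
  expect_equal(dispersion_offset_component(120, 100, "manual", 20), 1)
  expect_equal(dispersion_offset_component(55, 55, "abss", 2), 1)
  expect_equal(dispersion_offset_component(200, 100, "abss", 2), 0.5)
  expect_error(dispersion_offset_component(0, 100, "abss", 2), "positive")
})

test_that("BPR spline recovers constant and smooth ratio curves", {
  # noiseless wb = 2 x plasma at every shared time
  exam <- toy_exam()
  mt <- MANUAL_TIMES_MIN
  wb <- data.frame(time_min = mt, counts = 20000, duration_s = 10,
                   volume_mL = 1, detector = "manual",
                   compartment = "whole_blood", pre_injection = FALSE)
  pl <- wb
  pl$compartment <- "plasma"
  pl$counts <- 10000
  exam$samples <- rbind(wb, pl)
  m <- fit_bpr(exam)
  expect_equal(predict_bpr(m, seq(1, 90, length.out = 50)),
               rep(2, 50), tolerance = 1e-3)

  # r(t) = 0.8 + 0.2 exp(-t/20) + noise, RMSE < 0.02 over 20 seeds
  rmse <- vapply(1:20, function(s) {
    set.seed(s)
    r_true <- 0.8 + 0.2 * exp(-mt / 20)
    robs <- r_true + rnorm(length(mt), 0, 0.02)
    wb2 <- wb
    wb2$counts <- round(10000 * robs)
    pl2 <- pl
    pl2$counts <- 10000
    exam$samples <- rbind(wb2, pl2)
    m2 <- fit_bpr(exam)
    sqrt(mean((predict_bpr(m2, mt) - r_true)^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.02)

  # < 4 pairs falls back to a constant with a warning
  exam$samples <- rbind(wb[1:3, ], pl[1:3, ])
  expect_warning(m3 <- fit_bpr(exam), "constant")
  expect_equal(predict_bpr(m3, c(1, 50)), rep(2, 2))
})

test_that("parent-fraction sigmoid is recovered and has its stated shape", {
  true <- list(a = 0.05, t50_min = 10, k = 2)
  tt <- PF_TIMES_MIN
  pf <- data.frame(time_min = tt,
                   parent_fraction = pf_sigmoid(true, tt))
  fit <- fit_parent_fraction(pf)
  # independent bounded nonlinear least-squares oracle
  skip_if_not_installed("minpack.lm")
  or <- minpack.lm::nlsLM(
    parent_fraction ~ a + (1 - a) / (1 + (time_min / t50)^k),
    data = pf, start = list(a = 0.1, t50 = 5, k = 1),
    lower = c(0, 1e-3, 1e-3), upper = c(0.999, 1e3, 50))
  oc <- coef(or)
  expect_equal(fit$a, true$a, tolerance = 1e-3)
  expect_equal(fit$t50_min, true$t50_min, tolerance = 1e-2)
  expect_equal(fit$k, true$k, tolerance = 1e-3)
  expect_equal(unname(oc["a"]), fit$a, tolerance = 1e-3)
  expect_equal(unname(oc["t50"]), fit$t50_min, tolerance = 1e-2)

  expect_equal(pf_sigmoid(fit, 0), 1)
  expect_equal(pf_sigmoid(fit, fit$t50_min), fit$a + (1 - fit$a) / 2)
  v <- pf_sigmoid(fit, seq(0, 200, by = 0.5))
  expect_true(all(diff(v) <= 0))
  expect_true(all(v > fit$a & v <= 1))
})

test_that("assembled offsets multiply components and sum logs exactly", {
  exam <- toy_exam()
  exam$samples <- exam$samples[exam$samples$detector == "manual", ]
  pfp <- structure(list(a = 0.05, t50_min = 10, k = 2), class = "pf_sigmoid")
  bpr <- structure(list(constant = 1.4, range = c(0, 90)),
                   class = "bpr_model")
  off <- assemble_offsets(exam, bpr, pfp)
  expect_equal(off$log_tau_total,
               rowSums(log(as.matrix(off[, setdiff(names(off),
                                                   "log_tau_total")]))),
               tolerance = 1e-12)
  # hand computation: duration 2 s, vol 0.01 mL, rho 0, decay 0.5,
  # dispersion 1, bpr 1.4, PF 0.7 -> tau = 0.02
  s1 <- exam$samples[1, ]
  s1$duration_s <- 2
  s1$volume_mL <- 0.01
  exam2 <- exam
  exam2$samples <- s1
  exam2$rho_per_mL <- 0
  exam2$half_life_min <- s1$time_min  # elapsed = one half-life -> 0.5
  pf_const <- structure(list(a = 0.7, t50_min = 1e-9, k = 1),
                        class = "pf_sigmoid")  # pf(t) ~ floor = 0.7
  off2 <- assemble_offsets(exam2, bpr, pf_const)
  expect_equal(exp(off2$log_tau_total), 2 * 0.01 * 0.5 * 1.4 / 0.7,
               tolerance = 1e-9)
  # PF = 0.5 with everything else 1 doubles tau
  expect_equal(off2$inv_parent_fraction, 1 / 0.7, tolerance = 1e-8)
  # doubling volume at rho = 0 doubles tau
  s2 <- s1
  s2$volume_mL <- 0.02
  exam2$samples <- s2
  off3 <- assemble_offsets(exam2, bpr, pf_const)
  expect_equal(exp(off3$log_tau_total), 2 * exp(off2$log_tau_total),
               tolerance = 1e-9)
  # plasma samples get bpr exactly 1
  expect_equal(off$bpr[exam$samples$compartment == "plasma"], rep(1, 3))
})
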