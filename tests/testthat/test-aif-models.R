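test_that("parametric fit tracks the generator truth at manual times", {
  qp <- quick_prep(seed = 1)
  fit <- fit_parametric_aif(qp$prep)
  tt <- MANUAL_TIMES_MIN
  pr <- predict_aif(fit, tt)$estimate
  rel <- abs(pr - qp$truth$f_fun(tt)) / qp$truth$f_fun(tt)
  # late-time accuracy is limited by parent-fraction estimation error
  expect_lt(median(rel), 0.05)
  expect_lt(max(rel), 0.12)
  expect_equal(fit$engine$aic,
               -2 * fit$engine$log_likelihood + 2 * 7)  # 6 params + bias
})

test_that("a heavy-tailed four-exponential truth is underpredicted late", {
  # truth with a slow fourth component that the tri-exponential misses
  sims <- lapply(1:5, function(s) {
    cfg <- sim_config(A = c(5e4, 1e4, 2e3, 450),
                      gamma = c(3, 0.3, 0.05, 0.005))
    simulate_examination(cfg, seed = 400 + s)
  })
  signs <- vapply(sims, function(sim) {
    prep <- prepare_examination(sim$exam)
    fit <- fit_parametric_aif(prep)
    s <- prep$exam$samples
    late <- which(s$detector == "manual" &
                    s$time_min >= sort(unique(s$time_min[
                      s$detector == "manual"]), decreasing = TRUE)[3])
    resid <- s$counts[late] - fit$engine$fitted[late]
    mean(resid)
  }, numeric(1))
  expect_gte(sum(signs > 0), 4)
})

test_that("shape-constrained fits are non-increasing everywhere", {
  qp <- quick_prep(seed = 2)
  fit <- fit_gam_aif(qp$prep, family = "poisson", shape_constrained = TRUE,
                     log_time = FALSE)
  tr <- range(qp$prep$exam$samples$time_min)
  grid <- seq(tr[1], tr[2], length.out = 1000)
  pr <- predict_aif(fit, grid)$estimate
  expect_true(all(diff(pr) <= 1e-10))
})

test_that("negbin beats poisson by AIC on overdispersed examinations", {
  wins <- vapply(1:10, function(s) {
    sim <- simulate_examination(sim_config(psi = 0.3, family = "negbin"),
                                seed = 500 + s)
    prep <- prepare_examination(sim$exam)
    ap <- model_aic(fit_gam_aif(prep, family = "poisson"))
    an <- model_aic(fit_gam_aif(prep, family = "negbin"))
    an < ap
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("the ABSS bias factor is recovered at high counts", {
  ratios <- vapply(1:5, function(s) {
    qp <- quick_prep(seed = 600 + s)
    fit <- fit_gam_aif(qp$prep, family = "negbin")
    exp(fit$beta_abss)
  }, numeric(1))
  expect_true(all(ratios > 1.05 & ratios < 1.15))
})

test_that("no spurious ABSS bias is detected when none is simulated", {
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_examination(sim_config(abss_bias = 1), seed = 650 + s)
    prep <- prepare_examination(sim$exam)
    fit <- fit_gam_aif(prep, family = "negbin")
    j <- fit$engine$term_idx[[1]][2]          # abss column of fixed block
    se <- sqrt(fit$engine$Vb[j, j])
    hits <- hits + (abs(fit$beta_abss) < 2 * se)
  }
  expect_gte(hits, 17)
})

test_that("abss-reference predictions scale by exp(beta_abss)", {
  qp <- quick_prep(seed = 3)
  fit <- fit_gam_aif(qp$prep, family = "negbin")
  tt <- c(1, 2, 5, 9)
  pm <- predict_aif(fit, tt, reference = "manual")
  pa <- predict_aif(fit, tt, reference = "abss")
  expect_equal(pa$estimate / pm$estimate,
               rep(exp(fit$beta_abss), length(tt)), tolerance = 1e-10)
  expect_true(all(pm$lower < pm$estimate & pm$estimate < pm$upper))
  expect_true(all(pm$lower > 0))
})

test_that("fitted means equal predicted rate times tau at each sample", {
  qp <- quick_prep(seed = 3)
  for (fit in list(fit_gam_aif(qp$prep, family = "negbin"),
                   fit_parametric_aif(qp$prep))) {
    s <- qp$prep$exam$samples
    tau <- exp(qp$prep$offsets$log_tau_total)
    refs <- ifelse(s$detector == "abss", "abss", "manual")
    est <- numeric(nrow(s))
    for (r in c("abss", "manual")) {
      i <- refs == r
      est[i] <- predict_aif(fit, s$time_min[i], reference = r)$estimate
    }
    expect_equal(est * tau, unname(fit$engine$fitted), tolerance = 1e-8)
  }
})

test_that("refits on the same data reproduce coefficients exactly", {
  qp <- quick_prep(seed = 4)
  f1 <- fit_gam_aif(qp$prep, family = "negbin")
  f2 <- fit_gam_aif(qp$prep, family = "negbin")
  expect_identical(f1$engine$coefficients, f2$engine$coefficients)
})

test_that("hierarchical deviations vanish under infinite shrinkage", {
  suite <- simulate_suite(3, sim_config(), jitter_A = 0.1,
                          jitter_gamma = 0.05, seed = 700)
  preps <- lapply(suite$sims, function(s) prepare_examination(s$exam))
  h <- fit_hgam_aif(preps, k_global = 12, k_exam = 5)
  # refit at essentially infinite deviation-block smoothing
  eng <- h$engine
  fit_inf <- pirls_solve(eng$terms, eng$y, eng$log_offset, eng$family,
                         sp = c(eng$sp[1], 1e10))
  h_inf <- h
  h_inf$engine <- fit_inf
  grid <- exp(seq(log(1), log(85), length.out = 40))
  # per-exam predictions collapse onto global curve x exam intercept
  base <- NULL
  for (ex in h$exam_ids) {
    pr <- predict_aif(h_inf, grid, exam = ex)$estimate
    gpos <- match(ex, h$exam_ids)
    scaled <- pr / exp(fit_inf$coefficients[gpos])
    if (is.null(base)) base <- scaled
    expect_equal(scaled, base, tolerance = 1e-3)
  }
  # deviation-block edf is near zero there
  expect_lt(fit_inf$edf_term[["s(time, exam)"]], 0.01)
})

test_that("shared truths shrink deviations; distinct truths use them", {
  # near-noiseless parent fractions so the examinations share their
  # effective truth (PF estimation error would otherwise induce genuine
  # per-examination deviations through the offsets)
  suite_same <- simulate_suite(4, sim_config(pf_hplc_counts = 1e6),
                               jitter_A = 0,
                               jitter_gamma = 0, seed = 800)
  preps_same <- lapply(suite_same$sims,
                       function(s) prepare_examination(s$exam))
  h_same <- fit_hgam_aif(preps_same, k_global = 15, k_exam = 5)
  expect_lt(h_same$engine$edf_term[["s(time, exam)"]] /
              length(preps_same), 2)

  suite_diff <- simulate_suite(4, sim_config(), jitter_A = 0.4,
                               jitter_gamma = 0.3, seed = 900)
  preps_diff <- lapply(suite_diff$sims,
                       function(s) prepare_examination(s$exam))
  h_diff <- fit_hgam_aif(preps_diff, k_global = 15, k_exam = 5)
  tt <- MANUAL_TIMES_MIN
  # per-exam predictions beat the shared global-only curve
  mape_exam <- numeric(4)
  mape_global <- numeric(4)
  for (i in 1:4) {
    truth <- suite_diff$sims[[i]]$truth$f_fun(tt)
    pr <- predict_aif(h_diff, tt, exam = h_diff$exam_ids[i])$estimate
    # global-only: average of per-exam predictions on the log scale
    all_pr <- sapply(h_diff$exam_ids, function(ex)
      log(predict_aif(h_diff, tt, exam = ex)$estimate))
    pr_global <- exp(rowMeans(all_pr))
    mape_exam[i] <- median(abs(pr - truth) / truth)
    mape_global[i] <- median(abs(pr_global - truth) / truth)
  }
  expect_lt(mean(mape_exam), mean(mape_global))
})

test_that("AIC comparison tables have the stated arithmetic and guards", {
  qp <- quick_prep(seed = 5)
  f1 <- fit_gam_aif(qp$prep, family = "negbin")
  cmp_self <- compare_models_aic(list(a = list(f1), b = list(f1)),
                                 reference = "a")
  expect_equal(unname(cmp_self$delta[, "b"]), 0)

  fake <- function(aic) {
    structure(list(engine = structure(list(aic = aic, y = c(1, 2, 3)),
                                      class = "pg_fit")),
              class = "aif_fit")
  }
  cmp <- compare_models_aic(
    list(ref = list(fake(10), fake(10), fake(10)),
         other = list(fake(11), fake(12), fake(13))), reference = "ref")
  expect_equal(unname(cmp$mean_delta[["other"]]), -2)
  expect_equal(unname(cmp$range_delta[, "other"]), c(-3, -1))

  qp2 <- quick_prep(seed = 6)
  f2 <- fit_gam_aif(qp2$prep, family = "negbin")
  expect_error(compare_models_aic(list(a = list(f1), b = list(f2))),
               "mismatched")
})
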