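test_that("family log-likelihoods have their closed forms and limits", {
  expect_equal(family_loglik(aif_family("poisson"), 2, 2),
               2 * log(2) - 2 - log(2))
  y <- c(0, 1, 5, 20)
  mu <- c(1, 1, 4, 18)
  expect_lt(abs(family_loglik(aif_family("negbin", psi = 1e-8), y, mu) -
                  family_loglik(aif_family("poisson"), y, mu)), 1e-5)
  # psi -> 0 limit over a mean grid with psi * mu << 1 (beyond that the
  # two likelihoods genuinely differ by O(psi * mu))
  mu_grid <- 10^seq(-3, 3, length.out = 30)
  y_grid <- round(mu_grid)
  d <- abs(vapply(seq_along(mu_grid), function(i)
    family_loglik(aif_family("negbin", psi = 1e-8), y_grid[i], mu_grid[i]) -
      family_loglik(aif_family("poisson"), y_grid[i], mu_grid[i]),
    numeric(1)))
  expect_lt(max(d), 1e-5)
  expect_error(family_loglik(aif_family("poisson"), 1, -1), "mu")
})

test_that("negative-binomial draws realize the mu + psi mu^2 variance", {
  set.seed(31)
  mu <- 10
  psi <- 0.5
  y <- stats::rnbinom(1e5, size = 1 / psi, mu = mu)
  v_true <- mu + psi * mu^2
  # SE of the sample variance via the fourth moment
  se <- sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(var(y) - v_true), 3 * se)
  expect_equal(family_variance(aif_family("negbin", psi = psi), mu), v_true)
})

test_that("PIRLS reproduces closed-form Poisson MLEs", {
  fam <- aif_family("poisson")
  int <- pg_term_linear(cbind(rep(1, 3)), "int")
  fit <- pirls_solve(list(int), c(2, 4, 6), rep(0, 3), fam)
  expect_equal(unname(fit$coefficients), log(4), tolerance = 1e-8)

  int2 <- pg_term_linear(cbind(rep(1, 2)), "int")
  fit2 <- pirls_solve(list(int2), c(4, 8), log(c(1, 3)), fam)
  expect_equal(unname(fit2$coefficients), log(3), tolerance = 1e-8)
})

test_that("penalized PIRLS matches a direct numerical maximizer", {
  set.seed(5)
  X <- cbind(1, rnorm(40))
  eta <- 1 + 0.5 * X[, 2]
  y <- rpois(40, exp(eta))
  S <- diag(2)
  term <- pg_term_linear(X, "x", S = S)
  fit <- pirls_solve(list(term), y, rep(0, 40), aif_family("poisson"),
                     sp = 1)
  oracle <- penalized_poisson_oracle(X, y, rep(0, 40), S)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)

  # sp = 0 equals the unpenalized GLM solution
  fit0 <- pirls_solve(list(term), y, rep(0, 40), aif_family("poisson"),
                      sp = 0)
  gl <- glm(y ~ X[, 2], family = poisson())
  expect_equal(unname(fit0$coefficients), unname(coef(gl)),
               tolerance = 1e-6)
})

test_that("offsets shift only the intercept, never the fitted counts", {
  set.seed(8)
  n <- 100
  t <- exp(seq(log(1), log(90), length.out = 100))
  f <- 1e3 * exp(-0.2 * t) + 50
  y <- rpois(100, f)
  blk <- tps_design(log(t), k = 8, drop_const = TRUE, center = TRUE)
  terms <- list(pg_term_linear(matrix(1, n, 1), "int"), pg_term_block(blk, "s"))
  fit1 <- pirls_solve(terms, y, rep(0, 100), aif_family("poisson"), sp = 1)
  cc <- 7.3
  fit2 <- pirls_solve(terms, y, rep(log(cc), 100), aif_family("poisson"),
                      sp = 1)
  expect_equal(fit2$coefficients[1], fit1$coefficients[1] - log(cc),
               tolerance = 1e-6)
  expect_equal(fit2$coefficients[-1], fit1$coefficients[-1],
               tolerance = 1e-6)
  expect_equal(fit2$fitted, fit1$fitted, tolerance = 1e-8)
})

test_that("LAML at fixed sp matches an independent Laplace computation", {
  set.seed(12)
  t <- seq(0.5, 5, length.out = 20)
  f <- 40 * exp(-0.5 * t)
  y <- rpois(20, f)
  blk <- bspline_design(t, k = 6)
  term <- pg_term_block(blk, "s")
  sp <- 2.7
  fit <- pirls_solve(list(term), y, rep(0, 20), aif_family("poisson"),
                     sp = sp)
  V <- aifcount:::laml_criterion(fit)

  # independent implementation: explicit determinant formula around an
  # independently maximized penalized likelihood
  S <- sp * blk$penalty
  b_hat <- penalized_poisson_oracle(blk$design, y, rep(0, 20), S,
                                    start = fit$coefficients)
  mu <- exp(drop(blk$design %*% b_hat))
  ll <- sum(dpois(y, mu, log = TRUE))
  pen <- 0.5 * drop(b_hat %*% (S %*% b_hat))
  H <- crossprod(blk$design, blk$design * mu) + S
  ev <- eigen(sp * blk$penalty, symmetric = TRUE, only.values = TRUE)$values
  ev_pos <- ev[ev > max(ev) * 1e-10]
  Mp <- 6 - length(ev_pos)
  V_oracle <- ll - pen + 0.5 * (sum(log(ev_pos)) -
                                  determinant(H)$modulus[1]) +
    0.5 * Mp * log(2 * pi)
  expect_equal(V, V_oracle, tolerance = 1e-6)
})

test_that("REML shrinks to the null space for linear truths, not wiggly ones", {
  set.seed(2024)
  n <- 200
  t <- exp(seq(log(1), log(90), length.out = n))
  u <- log(t)
  edf_lin <- numeric(20)
  edf_wig <- numeric(20)
  for (s in 1:20) {
    # truth linear in log-time, high counts
    eta_lin <- 8 - 0.6 * u
    y_lin <- rpois(n, exp(eta_lin))
    blk <- tps_design(u, k = 10)
    fit <- reml_optimize(list(pg_term_block(blk, "s")), y_lin, rep(0, n),
                         aif_family("poisson"))
    edf_lin[s] <- fit$edf
    # wiggly 3-hump truth
    eta_wig <- 6 + sin(3 * u) * 1.2
    y_wig <- rpois(n, exp(eta_wig))
    fitw <- reml_optimize(list(pg_term_block(blk, "s")), y_wig, rep(0, n),
                          aif_family("poisson"))
    edf_wig[s] <- fitw$edf
  }
  expect_lt(abs(median(edf_lin) - 2), 0.5)   # null space {1, x}
  expect_gte(sum(edf_wig > 5), 18)
})

test_that("profiled negbin dispersion recovers psi and detects Poisson", {
  set.seed(77)
  n <- 300
  t <- exp(seq(log(1), log(90), length.out = n))
  u <- log(t)
  eta <- 6 - 0.8 * u                       # mu in ~5-500
  blk <- tps_design(u, k = 8, drop_const = TRUE, center = TRUE)
  terms <- list(pg_term_linear(matrix(1, n, 1), "int"), pg_term_block(blk, "s"))
  psi_pois <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rpois(n, exp(eta))
    estimate_negbin_dispersion(terms, y, rep(0, n), sp = c(1))$psi
  }, numeric(1))
  expect_gte(sum(psi_pois <= 0.01), 18)

  psi_nb <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    y <- rnbinom(600, size = 1 / 0.2,
                 mu = exp(6 - 0.8 * log(exp(seq(log(1), log(90),
                                               length.out = 600)))))
    u6 <- log(exp(seq(log(1), log(90), length.out = 600)))
    blk6 <- tps_design(u6, k = 8, drop_const = TRUE, center = TRUE)
    terms6 <- list(pg_term_linear(matrix(1, 600, 1), "int"),
                   pg_term_block(blk6, "s"))
    estimate_negbin_dispersion(terms6, y, rep(0, 600), sp = c(1))$psi
  }, numeric(1))
  expect_gte(sum(psi_nb >= 0.15 & psi_nb <= 0.25), 16)

  # maximizer property: profile loglik at psi-hat beats the boundary
  set.seed(3)
  y <- rnbinom(n, size = 1 / 0.2, mu = exp(eta))
  est <- estimate_negbin_dispersion(terms, y, rep(0, n), sp = c(1))
  fit_lo <- pirls_solve(terms, y, rep(0, n), aif_family("negbin", 1e-8),
                        sp = c(1))
  expect_gte(est$fit$log_likelihood, fit_lo$log_likelihood)
})

test_that("AIC identities hold for penalized and shrunk fits", {
  set.seed(21)
  n <- 80
  t <- seq(1, 50, length.out = 80)
  y <- rpois(80, 200 * exp(-0.1 * t) + 20)
  blk <- tps_design(t, k = 8, drop_const = TRUE, center = TRUE)
  terms <- list(pg_term_linear(matrix(1, n, 1), "int"), pg_term_block(blk, "s"))
  fit <- pirls_solve(terms, y, rep(0, 80), aif_family("poisson"), sp = 3)
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$df,
               tolerance = 1e-8)
  expect_equal(model_aic(fit), fit$aic)

  # full-rank-penalty block shrinks to edf ~ 0 as sp -> infinity
  g <- rep(c("a", "b"), each = 40)
  fsb <- factor_smooth_design(t, g, k = 5)
  terms2 <- list(pg_term_linear(matrix(1, n, 1), "int"), pg_term_block(fsb, "fs"))
  fit_inf <- pirls_solve(terms2, y, rep(0, 80), aif_family("poisson"),
                         sp = 1e12)
  expect_lt(fit_inf$edf_term[["fs"]], 0.01)

  # delta-AIC identity between two fits
  fit2 <- pirls_solve(terms, y, rep(0, 80), aif_family("poisson"), sp = 30)
  expect_equal(fit$aic - fit2$aic,
               -2 * (fit$log_likelihood - fit2$log_likelihood) +
                 2 * (fit$df - fit2$df), tolerance = 1e-8)
})

test_that("nonlinear Poisson regression recovers exact tri-exponentials", {
  cfg <- sim_config()
  t_abss <- seq(1 / 60, 10, by = 1 / 60)
  t_man <- cfg$manual_times_min
  t <- c(t_abss[t_abss >= 0.7], t_man)
  truth <- triexp_params(c(5e4, 1e4, 2e3), c(3, 0.3, 0.03))
  tau <- c(rep(0.01, sum(t_abss >= 0.7)), rep(20, length(t_man)))
  lam <- triexp_eval(truth, t) * tau
  y <- round(lam)
  start <- curve_strip_init(t, y / tau)
  fit <- nls_poisson_fit(t, y, log(tau), start)
  expect_equal(fit$params$A, truth$A, tolerance = 0.01)
  expect_equal(fit$params$gamma, truth$gamma, tolerance = 0.01)

  # model nesting: deviance no worse than the best single exponential
  s1 <- curve_strip_init(t, y / tau, n_exp = 1)
  f1 <- nls_poisson_fit(t, y, log(tau), s1)
  expect_lte(fit$deviance, f1$deviance)

  # multi-start consistency under +-20% start perturbations
  set.seed(4)
  for (rep in 1:3) {
    pert <- triexp_params(truth$A * exp(runif(3, -0.2, 0.2)),
                          truth$gamma * exp(runif(3, -0.2, 0.2)))
    fp <- nls_poisson_fit(t, y, log(tau), pert)
    expect_lt(abs(fp$deviance - fit$deviance), 1e-4 * (fit$deviance + 1))
  }
})

test_that("curve stripping lands in the basin of attraction", {
  # single exponential: exact recovery from the log-linear closed form
  t <- seq(1, 60, length.out = 50)
  A <- 800; g <- 0.15
  r <- A * exp(-g * t)
  cs <- curve_strip_init(t, r, n_exp = 1)
  expect_equal(cs$A, A, tolerance = 1e-10)
  expect_equal(cs$gamma, g, tolerance = 1e-10)

  # exact tri-exponential: every rate within a factor of 2
  t3 <- exp(seq(log(0.7), log(90), length.out = 400))
  truth <- triexp_params(c(5e4, 1e4, 2e3), c(3, 0.3, 0.03))
  r3 <- triexp_eval(truth, t3)
  cs3 <- curve_strip_init(t3, r3)
  expect_true(all(cs3$A > 0 & cs3$gamma > 0))
  expect_true(all(cs3$gamma / truth$gamma < 2 &
                    cs3$gamma / truth$gamma > 0.5))
  y3 <- round(r3)
  fit3 <- nls_poisson_fit(t3, y3, rep(0, length(t3)), cs3)
  expect_equal(fit3$params$gamma, truth$gamma, tolerance = 0.01)
})
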