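# Shared fixtures and independent oracles used across test files.

# small hand-built examination: 6 ABSS seconds + 3 manual draw times
toy_exam <- function(kappa_s = 0, rho = 0) {
  abss <- data.frame(
    time_min = (1:6) / 60, counts = c(50, 90, 120, 100, 80, 60),
    duration_s = 1, volume_mL = 0.01, detector = "abss",
    compartment = "whole_blood", pre_injection = FALSE)
  wb <- data.frame(
    time_min = c(1, 3, 9), counts = c(4000, 2500, 900), duration_s = 10,
    volume_mL = c(2, 1.5, 2.5), detector = "manual",
    compartment = "whole_blood", pre_injection = FALSE)
  pl <- data.frame(
    time_min = c(1, 3, 9), counts = c(4400, 2800, 1100), duration_s = 10,
    volume_mL = c(1, 0.9, 1.2), detector = "manual",
    compartment = "plasma", pre_injection = FALSE)
  blood_exam(rbind(abss, wb, pl),
             pf_measurements = data.frame(time_min = c(1, 3, 9),
                                          parent_fraction = c(0.95, 0.8, 0.5)),
             half_life_min = 20.36, kappa_s = kappa_s, rho_per_mL = rho)
}

# independent de Boor recursion for B-spline evaluation
deboor_basis <- function(x, knots, degree) {
  k <- length(knots) - degree - 1
  sapply(seq_len(k), function(j) {
    vapply(x, function(xx) deboor_one(xx, j, degree, knots), numeric(1))
  })
}
deboor_one <- function(x, j, d, tk) {
  if (d == 0) {
    # right-closed at the final boundary so the last basis reaches 1
    hi <- tk[j + 1]
    is_last <- abs(hi - tk[length(tk)]) < 1e-14
    return(as.numeric(x >= tk[j] & (x < hi || (is_last && x <= hi))))
  }
  a <- 0
  if (tk[j + d] > tk[j]) {
    a <- (x - tk[j]) / (tk[j + d] - tk[j]) * deboor_one(x, j, d - 1, tk)
  }
  b <- 0
  if (tk[j + d + 1] > tk[j + 1]) {
    b <- (tk[j + d + 1] - x) / (tk[j + d + 1] - tk[j + 1]) *
      deboor_one(x, j + 1, d - 1, tk)
  }
  a + b
}

# direct numerical maximizer of a penalized Poisson log-likelihood
penalized_poisson_oracle <- function(X, y, off, S, start = NULL) {
  f <- function(b) {
    eta <- drop(X %*% b) + off
    -(sum(y * eta - exp(eta)) - 0.5 * drop(b %*% (S %*% b)))
  }
  g <- function(b) {
    eta <- drop(X %*% b) + off
    -(drop(crossprod(X, y - exp(eta))) - drop(S %*% b))
  }
  if (is.null(start)) start <- rep(0, ncol(X))
  o <- stats::optim(start, f, g, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  o$par
}

# simulated + prepared examination cache (kept tiny where possible)
quick_prep <- function(seed = 1, ...) {
  sim <- simulate_examination(sim_config(...), seed = seed)
  list(prep = prepare_examination(sim$exam), truth = sim$truth)
}
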