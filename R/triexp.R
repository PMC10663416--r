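# Parametric AIF model: f(t) = sum_k A_k exp(-gamma_k t), fitted by
# nonlinear Poisson regression with a log link and exposure offsets,
# initialized by classic curve stripping (exponential peeling).

#' Construct tri-exponential parameters
#'
#' @param A amplitudes (> 0), counts/s/mL scale.
#' @param gamma decay rates (> 0), per minute; sorted into strictly
#'   decreasing order (ties broken by descending amplitude).
#' @return An object of class `triexp_params`.
#' @export
triexp_params <- function(A, gamma) {
  if (length(A) != length(gamma)) stop("A and gamma lengths differ",
                                       call. = FALSE)
  if (any(A <= 0) || any(gamma <= 0)) {
    stop("amplitudes and rates must be > 0", call. = FALSE)
  }
  ord <- order(-gamma, -A)
  structure(list(A = A[ord], gamma = gamma[ord]), class = "triexp_params")
}

#' Evaluate a sum-of-exponentials curve
#'
#' @param params a [triexp_params()].
#' @param t times in minutes.
#' @return `sum_k A_k exp(-gamma_k t)`.
#' @export
triexp_eval <- function(params, t) {
  drop(exp(outer(t, -params$gamma)) %*% params$A)
}

#' Curve-stripping starting values for multi-exponential fits
#'
#' Exponential peeling: a log-linear regression over the last third of the
#' points estimates the slowest component, which is subtracted; the
#' procedure repeats on the earlier residuals for each faster component.
#' Negative residuals are dropped before each log step.
#'
#' @param t sample times (minutes), ascending order not required.
#' @param rate_estimates positive rate estimates (counts / tau) per sample.
#' @param n_exp number of exponentials (default 3); reduced with a warning
#'   when a stage has fewer than 2 usable points.
#' @return A [triexp_params()] with `n_exp` (or fewer) components.
#' @export
curve_strip_init <- function(t, rate_estimates, n_exp = 3) {
  keep <- is.finite(rate_estimates) & rate_estimates > 0
  d <- data.frame(t = t[keep], r = rate_estimates[keep])
  d <- d[order(d$t), ]
  if (nrow(d) < 2 * n_exp) {
    n_exp <- max(1L, nrow(d) %/% 2L)
    warning("too few usable points: reduced to ", n_exp, " exponentials",
            call. = FALSE)
  }
  # segment boundaries equally spaced in log time: multi-exponential
  # components separate on the log-time axis, and the acquisition schedule
  # (dense ABSS early, sparse manual late) is far from uniform in t
  breaks <- exp(seq(log(min(d$t)), log(max(d$t)), length.out = n_exp + 1))
  A <- numeric(0); gam <- numeric(0)
  for (comp in rev(seq_len(n_exp))) {     # slowest component first
    if (nrow(d) < 2) {
      warning("curve stripping ran out of points at component ",
              n_exp - comp + 1L, ": returning ", length(A), " exponentials",
              call. = FALSE)
      break
    }
    seg <- d[d$t >= breaks[comp], , drop = FALSE]
    if (nrow(seg) < 2) seg <- utils::tail(d, 2)
    fit <- stats::lm(log(r) ~ t, data = seg)
    g <- max(-stats::coef(fit)[["t"]], 1e-6)
    a <- exp(stats::coef(fit)[["(Intercept)"]])
    A <- c(A, a); gam <- c(gam, g)
    d$r <- d$r - a * exp(-g * d$t)
    d <- d[d$r > 0 & d$t < min(seg$t), , drop = FALSE]
  }
  triexp_params(A, gam)
}

#' Nonlinear Poisson regression for a sum of exponentials
#'
#' Maximizes the Poisson log-likelihood of
#' \eqn{\log \lambda_i = \log f(t_i, \theta) + x_i \beta_{abss} +
#' \log \tau_i} over the log-parameterized curve parameters
#' \eqn{(\log A_k, \log \gamma_k)} (and an optional ABSS-bias coefficient)
#' by quasi-Newton search with the analytic gradient. Rates are sorted into
#' decreasing order on output.
#'
#' @param t sample times (minutes).
#' @param y observed counts.
#' @param log_offset per-sample log exposure.
#' @param start a [triexp_params()] starting value.
#' @param abss optional 0/1 indicator of ABSS samples (adds a multiplicative
#'   bias coefficient).
#' @param control see [pg_control()].
#' @return A `pg_fit`-like object with `$params` (a `triexp_params`),
#'   optional `$beta_abss`, exact log-likelihood, `edf` equal to the
#'   parameter count, AIC and the observed-information covariance.
#' @export
nls_poisson_fit <- function(t, y, log_offset, start, abss = NULL,
                            control = pg_control()) {
  K <- length(start$A)
  has_abss <- !is.null(abss) && any(abss > 0)
  par0 <- c(log(start$A), log(start$gamma), if (has_abss) 0)
  np <- length(par0)
  comps <- function(par) {
    A <- exp(par[1:K]); g <- exp(par[K + 1:K])
    Et <- exp(outer(t, -g))          # n x K
    f <- drop(Et %*% A)
    eta <- log(f) + log_offset
    if (has_abss) eta <- eta + par[2 * K + 1] * abss
    list(A = A, g = g, Et = Et, f = f, lam = exp(pmin(eta, control$eta_clamp)))
  }
  negll <- function(par) {
    cc <- comps(par)
    if (any(!is.finite(cc$lam)) || any(cc$lam <= 0)) return(1e12)
    -sum(y * log(cc$lam) - cc$lam - lgamma(y + 1))
  }
  grad <- function(par) {
    cc <- comps(par)
    resid <- y - cc$lam             # dll/deta_i
    # d eta / d logA_k = A_k e^{-g_k t} / f ; d eta / d log g_k = -g_k t A_k e^{-g_k t}/f
    W <- cc$Et / cc$f
    gA <- colSums(resid * W * rep(cc$A, each = length(t)))
    gG <- colSums(resid * (-t) * W * rep(cc$A * cc$g, each = length(t)))
    out <- c(gA, gG, if (has_abss) sum(resid * abss))
    -out
  }
  opt <- stats::optim(par0, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll, grad, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$convergence != 0 && opt$value >= 1e12) {
      stop("nonlinear Poisson fit failed to converge; best parameters: ",
           paste(signif(exp(opt$par), 4), collapse = ", "), call. = FALSE)
    }
  }
  par <- opt$par
  H <- stats::optimHess(par, negll, grad)
  Vb <- try(chol2inv(chol_safe(H)), silent = TRUE)
  if (inherits(Vb, "try-error")) Vb <- matrix(NA_real_, np, np)
  cc <- comps(par)
  ll <- -opt$value
  params <- triexp_params(exp(par[1:K]), exp(par[K + 1:K]))
  fit <- structure(list(
    params = params,
    beta_abss = if (has_abss) par[2 * K + 1] else NULL,
    coefficients = par, fitted = cc$lam, y = y, log_offset = log_offset,
    family = aif_family("poisson"), t = t, abss = abss,
    edf = np, df = np, log_likelihood = ll, aic = -2 * ll + 2 * np,
    deviance = family_deviance(aif_family("poisson"), y, cc$lam),
    Vb = Vb, converged = opt$convergence == 0, iterations = NA_integer_
  ), class = c("triexp_fit", "pg_fit"))
  fit
}
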