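# Residual-based model criticism: randomized quantile residuals (exactly
# standard normal under a correctly specified discrete model), Q-Q
# summaries, and the Pearson overdispersion statistic.

#' Randomized quantile residuals
#'
#' For each sample, \eqn{r_i = \Phi^{-1}(u_i)} with
#' \eqn{u_i \sim U(F(y_i - 1; \hat\mu_i), F(y_i; \hat\mu_i))} and `F` the
#' fitted family CDF; under the true model the residuals are exactly
#' standard normal. Deterministic given the seed.
#'
#' @param fit a `pg_fit` or `aif_fit` with a discrete family.
#' @param seed RNG seed.
#' @return A list of class `residual_set`: `residuals`, `seed`, `family`,
#'   and a `summary` with mean, SD, the Kolmogorov-Smirnov statistic
#'   against N(0,1) and the Q-Q slope.
#' @export
randomized_quantile_residuals <- function(fit, seed = 1L) {
  eng <- if (inherits(fit, "aif_fit")) fit$engine else fit
  fam <- eng$family
  if (fam$name == "gaussian") {
    stop("quantile residuals are defined here for discrete families",
         call. = FALSE)
  }
  y <- eng$y
  mu <- eng$fitted
  set.seed(seed)
  lo <- family_cdf(fam, y - 1, mu)
  hi <- family_cdf(fam, y, mu)
  u <- stats::runif(length(y), lo, hi)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- stats::qnorm(u)
  qq <- qq_summary_stats(r)
  structure(list(residuals = r, seed = seed, family = fam$name,
                 summary = c(mean = mean(r), sd = stats::sd(r),
                             ks_stat = unname(qq["ks_stat"]),
                             qq_slope = unname(qq["slope"]))),
            class = "residual_set")
}

qq_summary_stats <- function(r) {
  n <- length(r)
  theo <- stats::qnorm(stats::ppoints(n))
  emp <- sort(r)
  co <- stats::coef(stats::lm(emp ~ theo))
  ks <- suppressWarnings(stats::ks.test(r, "pnorm")$statistic)
  c(slope = unname(co[2]), intercept = unname(co[1]),
    ks_stat = unname(ks))
}

#' Q-Q summary of a residual set
#'
#' Regresses the ordered residuals on standard-normal quantiles and
#' reports the slope, intercept and Kolmogorov-Smirnov statistic; a slope
#' near 1 and intercept near 0 indicate a well-calibrated error
#' distribution.
#'
#' @param residual_set a `residual_set` (or numeric residual vector,
#'   >= 10 values).
#' @param plot_data_path optional TSV path for the theoretical vs empirical
#'   quantiles (plot data).
#' @return Named vector `(slope, intercept, ks_stat)`.
#' @export
qq_summary <- function(residual_set, plot_data_path = NULL) {
  r <- if (inherits(residual_set, "residual_set")) {
    residual_set$residuals
  } else as.numeric(residual_set)
  if (length(r) < 10) stop("need at least 10 residuals", call. = FALSE)
  out <- qq_summary_stats(r)
  if (!is.null(plot_data_path)) {
    utils::write.table(
      data.frame(theoretical = stats::qnorm(stats::ppoints(length(r))),
                 empirical = sort(r)),
      plot_data_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Pearson overdispersion statistic
#'
#' \eqn{\sum_i (y_i - \hat\mu_i)^2 / V(\hat\mu_i) / (n - edf)}: near 1 for
#' a well-specified variance function, well above 1 when a Poisson fit is
#' applied to overdispersed counts (approximately \eqn{1 + \psi\mu} for
#' negative-binomial data).
#'
#' @param fit a `pg_fit` or `aif_fit`.
#' @return The dispersion statistic.
#' @export
pearson_dispersion <- function(fit) {
  eng <- if (inherits(fit, "aif_fit")) fit$engine else fit
  v <- family_variance(eng$family, eng$fitted)
  sum((eng$y - eng$fitted)^2 / v) / (length(eng$y) - eng$edf)
}

#' @export
print.residual_set <- function(x, ...) {
  cat(sprintf("Randomized quantile residuals (%s family, n = %d, seed %d)\n",
              x$family, length(x$residuals), x$seed))
  print(round(x$summary, 4))
  invisible(x)
}
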