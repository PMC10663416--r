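# Spline basis constructions. Each constructor returns a `basis_block`:
# a design matrix, a symmetric positive-semidefinite penalty on the
# coefficients, the penalty null-space dimension, and enough metadata to
# re-evaluate the design at new covariate values (basis_eval). Penalized
# and unpenalized (null-space) directions live in the same coefficient
# block; the penalty has zero rows/columns for the latter.

new_basis_block <- function(kind, design, penalty, nullspace_dim, info) {
  ev <- eigen(penalty, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) && min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("penalty is not positive semidefinite", call. = FALSE)
  }
  structure(list(kind = kind, design = design, penalty = penalty,
                 nullspace_dim = nullspace_dim, info = info),
            class = "basis_block")
}

#' Cubic B-spline basis with a second-order difference penalty
#'
#' Knots are placed at quantiles of the covariate with replicated boundary
#' knots, so each design row is a partition of unity inside the data range.
#' The penalty is \eqn{D_2^T D_2} on the coefficients (null space: constant
#' and linear coefficient sequences).
#'
#' @param x covariate values.
#' @param k basis dimension (>= degree + 1).
#' @param degree spline degree (default 3, cubic).
#' @return A `basis_block` of kind `"bspline"`.
#' @export
bspline_design <- function(x, k, degree = 3) {
  if (k < degree + 1) stop("k must be at least degree + 1", call. = FALSE)
  xr <- range(x)
  n_interior <- k - degree - 1
  interior <- if (n_interior > 0) {
    stats::quantile(unique(x), probs = seq_len(n_interior) / (n_interior + 1),
                    names = FALSE, type = 7)
  } else numeric(0)
  knots <- c(rep(xr[1], degree + 1), interior, rep(xr[2], degree + 1))
  X <- splines::splineDesign(knots, pmin(pmax(x, xr[1]), xr[2]),
                             ord = degree + 1)
  D2 <- diff(diag(k), differences = 2)
  new_basis_block("bspline", X, crossprod(D2), nullspace_dim = 2,
                  info = list(knots = knots, degree = degree, k = k,
                              range = xr))
}

#' Shape-constrained (monotone decreasing) B-spline construction
#'
#' Builds the cubic B-spline basis of [bspline_design()] together with the
#' coefficient transform \eqn{\beta_j = \beta_1 - \sum_{l \le j}
#' e^{\delta_l}} mapping unconstrained working parameters
#' \eqn{(\beta_1, \delta_2, \dots, \delta_k)} to strictly non-increasing
#' B-spline coefficients, hence a non-increasing fitted curve for *every*
#' working-parameter value. The penalty is a first-order difference penalty
#' on the \eqn{\delta} working parameters (null space: the level
#' \eqn{\beta_1} and a common decrement, dimension 2).
#'
#' @inheritParams bspline_design
#' @return A `basis_block` of kind `"scop_decreasing"` with elements
#'   `transform(b)` (working to B-spline coefficients) and `jacobian(b)`.
#' @export
scop_decreasing_design <- function(x, k, degree = 3) {
  base <- bspline_design(x, k, degree)
  transform <- function(b) {
    b[1] - cumsum(c(0, exp(b[-1])))
  }
  jacobian <- function(b) {
    J <- matrix(0, k, k)
    J[, 1] <- 1
    for (l in 2:k) J[l:k, l] <- -exp(b[l])
    J
  }
  D1 <- diff(diag(k - 1))                 # differences of delta_2..delta_k
  S <- matrix(0, k, k)
  S[-1, -1] <- crossprod(D1)
  blk <- new_basis_block("scop_decreasing", base$design, S,
                         nullspace_dim = 2, info = base$info)
  blk$transform <- transform
  blk$jacobian <- jacobian
  blk
}

#' Thin-plate regression spline basis (1-D)
#'
#' Radial basis \eqn{|x - x_j|^3} on the unique covariate values, with the
#' polynomial constraint absorbed and the penalized subspace eigen-truncated
#' to `k - 2` columns; the unpenalized null space is \eqn{\{1, x\}}. The
#' penalty is diagonal (the retained eigenvalues), padded with zeros over
#' the null-space columns.
#'
#' @param x covariate values (1-D).
#' @param k basis dimension; reduced with a warning if it exceeds the number
#'   of unique covariate values.
#' @param drop_const drop the constant null-space column (used when the
#'   model carries an explicit intercept).
#' @param center subtract column means from the penalized and linear columns
#'   (stored for prediction); implies an identifiable smooth alongside an
#'   intercept.
#' @return A `basis_block` of kind `"tps"` with `nullspace_dim = 2` (or 1
#'   when `drop_const`).
#' @export
tps_design <- function(x, k, drop_const = FALSE, center = FALSE) {
  xu <- sort(unique(x))
  nu <- length(xu)
  if (k > nu) {
    warning(sprintf("tps basis dimension reduced from %d to %d unique values",
                    k, nu), call. = FALSE)
    k <- nu
  }
  if (k < 3) stop("tps basis needs k >= 3", call. = FALSE)
  E <- abs(outer(xu, xu, "-"))^3
  Tmat <- cbind(1, xu)
  Z <- qr.Q(qr(Tmat), complete = TRUE)[, -(1:2), drop = FALSE]  # null(T')
  M <- crossprod(Z, E %*% Z)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  keep <- seq_len(k - 2)
  V <- eg$vectors[, keep, drop = FALSE]
  lam <- pmax(eg$values[keep], 0)
  ZV <- Z %*% V
  nullcols <- if (drop_const) cbind(x = xu) else cbind(1, x = xu)
  p <- (k - 2) + ncol(nullcols)
  S <- diag(c(lam, rep(0, ncol(nullcols))), nrow = p)
  info <- list(xu = xu, ZV = ZV, k = k, drop_const = drop_const,
               center = center, col_center = rep(0, p))
  Xu <- cbind(E %*% ZV, nullcols)
  # evaluate at the data rows
  Kx <- abs(outer(x, xu, "-"))^3
  X <- cbind(Kx %*% ZV, if (drop_const) cbind(x) else cbind(1, x))
  if (center) {
    cc <- colMeans(X)
    if (!drop_const) cc[k - 1] <- 0   # keep an explicit constant column as-is
    X <- sweep(X, 2, cc)
    info$col_center <- cc
  }
  blk <- new_basis_block("tps", X, S,
                         nullspace_dim = ncol(nullcols), info = info)
  blk
}

#' Per-group thin-plate deviation smooths with a full-rank penalty
#'
#' One thin-plate basis of dimension `k` (including its \eqn{\{1, x\}}
#' null space) is built on the pooled covariate values and replicated for
#' every group, giving block-diagonal group columns that share a single
#' smoothing parameter and penalty. The basis is put in its natural
#' parameterization — penalized columns are scaled by
#' \eqn{1/\sqrt{\lambda_j}} so the wiggliness penalty becomes the
#' identity — the former null-space columns \eqn{\{1, x\}} are included
#' under the same identity penalty (full-rank shrinkage), and every column
#' is standardized to unit root-mean-square so all deviation directions
#' are penalized in a commensurate metric. As the smoothing parameter
#' grows, every group deviation therefore shrinks to zero exactly; a group
#' with very few observations is handled naturally because the basis and
#' penalty are shared, not rebuilt per group.
#'
#' @param x covariate values.
#' @param group_ids factor or vector of group labels (>= 2 groups).
#' @param k per-group basis dimension.
#' @return A `basis_block` of kind `"factor_smooth"`; total columns =
#'   (number of groups) x k, penalty rank = total columns,
#'   `nullspace_dim = 0`.
#' @export
factor_smooth_design <- function(x, group_ids, k) {
  g <- factor(group_ids)
  levels_g <- levels(g)
  G <- length(levels_g)
  if (G < 2) stop("need at least 2 groups", call. = FALSE)
  base <- tps_design(x, k)
  k_eff <- base$info$k
  lam <- diag(base$penalty)[seq_len(k_eff - 2)]
  Xall <- fs_natural_design(base, x, lam, sc = NULL)
  sc <- sqrt(colMeans(Xall^2))
  Xall <- sweep(Xall, 2, sc, "/")
  p1 <- ncol(Xall)
  n <- length(x)
  X <- matrix(0, n, G * p1)
  col_map <- list()
  for (i in seq_len(G)) {
    jj <- (i - 1L) * p1 + seq_len(p1)
    rows <- which(g == levels_g[i])
    X[rows, jj] <- Xall[rows, , drop = FALSE]
    col_map[[levels_g[i]]] <- jj
  }
  new_basis_block("factor_smooth", X, diag(1, G * p1), nullspace_dim = 0,
                  info = list(levels = levels_g, base = base, lam = lam,
                              sc = sc, col_map = col_map, k = k))
}

# common-basis columns in natural parameterization (penalty = identity on
# the wiggliness directions); sc standardizes columns when supplied
fs_natural_design <- function(base, x, lam, sc = NULL) {
  Xb <- basis_eval(base, x)
  np <- length(lam)
  Xp <- Xb[, seq_len(np), drop = FALSE] %*% diag(1 / sqrt(lam), np)
  Xn <- Xb[, np + 1:2, drop = FALSE]
  out <- cbind(Xp, Xn)
  if (!is.null(sc)) out <- sweep(out, 2, sc, "/")
  out
}

#' Evaluate a basis block at new covariate values
#'
#' @param block a `basis_block`.
#' @param x new covariate values (for factor smooths, supply `group` too).
#' @param group group label (factor smooths only).
#' @return The design matrix at `x`.
#' @export
basis_eval <- function(block, x, group = NULL) {
  info <- block$info
  switch(block$kind,
    bspline = ,
    scop_decreasing = {
      xr <- info$range
      splines::splineDesign(info$knots, pmin(pmax(x, xr[1]), xr[2]),
                            ord = info$degree + 1)
    },
    tps = {
      Kx <- abs(outer(x, info$xu, "-"))^3
      X <- cbind(Kx %*% info$ZV, if (info$drop_const) cbind(x) else cbind(1, x))
      if (info$center) X <- sweep(X, 2, info$col_center)
      X
    },
    factor_smooth = {
      if (is.null(group)) stop("factor smooth evaluation needs a group",
                               call. = FALSE)
      jj <- info$col_map[[as.character(group)]]
      if (is.null(jj)) stop("unknown group: ", group, call. = FALSE)
      X <- matrix(0, length(x), ncol(block$design))
      X[, jj] <- fs_natural_design(info$base, x, info$lam, info$sc)
      X
    },
    stop("unknown basis kind", call. = FALSE))
}
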