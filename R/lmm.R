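#' Mass-univariate random-intercept mixed model by profiled REML
#'
#' Fits, for every column of `Y` (e.g. every voxel), the linear mixed model
#' `y = X b + Z u + e`, `u ~ N(0, sigma_b^2)` a random intercept per level
#' of `group`, `e ~ N(0, sigma_e^2) iid`. The REML criterion is profiled
#' over the variance ratio `gamma = sigma_b^2 / sigma_e^2` on a dense grid
#' shared by all responses, which lets every quantity be computed for all
#' columns at once with dense linear algebra; this is what makes voxelwise
#' mixed-effects maps affordable. `gamma = 0` (the OLS boundary) is part of
#' the grid, so singular fits degrade gracefully and are counted.
#'
#' Degrees of freedom for the requested contrast use the Satterthwaite
#' approximation with the expected REML information of
#' `(sigma_e^2, sigma_b^2)`; for a fixed design both the contrast variance
#' factor and the df are functions of `gamma` alone, so they are
#' precomputed on the grid and looked up per response.
#'
#' @param Y Numeric matrix, observations x responses.
#' @param X Fixed-effects design matrix (full column rank).
#' @param group Factor of length `nrow(Y)`: the random-intercept grouping.
#' @param contrast Numeric contrast vector over columns of `X`, or a single
#'   column name/index.
#' @param gamma_grid Grid of variance ratios; defaults to 0 plus 240
#'   log-spaced points in [1e-4, 1e3].
#' @return List with per-response vectors `est`, `se`, `tstat`, `df`, `p`,
#'   `sigma2_e`, `sigma2_b`, `gamma`, plus `n_singular` (responses at the
#'   `gamma = 0` boundary) and the grid.
#' @export
lmm_mass_ranint <- function(Y, X, group, contrast,
                            gamma_grid = c(0, 10^seq(-4, 3, length.out = 240))) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  group <- droplevels(as.factor(group))
  n <- nrow(X); p <- ncol(X); v <- ncol(Y)
  if (nrow(Y) != n || length(group) != n)
    abort_arg("Y, X and group must agree in length")
  if (nlevels(group) < 2L) abort_arg("need at least 2 grouping levels")
  if (is.character(contrast) || length(contrast) == 1L) {
    ci <- if (is.character(contrast)) match(contrast, colnames(X))
          else as.integer(contrast)
    if (is.na(ci) || ci < 1 || ci > p) abort_arg("contrast column not found")
    cvec <- numeric(p); cvec[ci] <- 1
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != p) abort_arg("contrast length != ncol(X)")
  }

  Zmat <- stats::model.matrix(~ 0 + group)
  a <- as.vector(table(group))       # group sizes
  G <- length(a)
  S <- rowsum(X, group)              # G x p column sums per group
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  Ysum <- rowsum(Y, group)           # G x v
  yty <- colSums(Y^2)

  ng <- length(gamma_grid)
  crit <- matrix(NA_real_, ng, v)
  estg <- matrix(NA_real_, ng, v)
  qfg  <- matrix(NA_real_, ng, v)
  cvar <- dfg <- numeric(ng)

  for (gi in seq_len(ng)) {
    gam <- gamma_grid[gi]
    w <- gam / (1 + a * gam)
    XtViX <- XtX - crossprod(S, S * w)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) next
    C <- chol2inv(ch)
    XtViY <- XtY - crossprod(S, Ysum * w)
    ytViy <- yty - colSums(Ysum * (Ysum * w))
    B <- C %*% XtViY
    qf <- pmax(ytViy - colSums(XtViY * B), 0)
    logdetV <- sum(log1p(a * gam))
    logdetXtViX <- 2 * sum(log(diag(ch)))
    crit[gi, ] <- (n - p) * log(pmax(qf, 1e-300)) + logdetV + logdetXtViX
    estg[gi, ] <- as.vector(crossprod(cvec, B))
    qfg[gi, ]  <- qf

    # contrast variance factor and Satterthwaite df (functions of gamma only)
    u <- C %*% cvec
    cvar[gi] <- sum(cvec * u)
    D <- S / (1 + a * gam)                 # X' Vinv Z  (transposed layout, G x p)
    fprime <- sum((D %*% u)^2)
    Vi <- diag(n) - Zmat %*% (w * t(Zmat))
    A <- Vi %*% X
    P <- Vi - A %*% tcrossprod(C, A)
    t1 <- sum(P * P)
    Q <- P %*% Zmat
    t2 <- sum(Q * Q)
    M <- crossprod(Zmat, Q)
    t3 <- sum(M * M)
    gvec <- c(cvar[gi] - gam * fprime, fprime)
    Tm <- matrix(c(t1, t2, t2, t3), 2)
    dfg[gi] <- tryCatch(cvar[gi]^2 / sum(gvec * solve(Tm, gvec)),
                        error = function(e) NA_real_)
  }

  idx <- apply(crit, 2, which.min)
  pick <- cbind(idx, seq_len(v))
  gamma_hat <- gamma_grid[idx]
  sigma2_e <- qfg[pick] / (n - p)
  est <- estg[pick]
  se <- sqrt(sigma2_e * cvar[idx])
  df <- dfg[idx]
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  list(est = est, se = se, tstat = tstat, df = df, p = pval,
       sigma2_e = sigma2_e, sigma2_b = gamma_hat * sigma2_e,
       gamma = gamma_hat, n_singular = sum(gamma_hat == 0),
       gamma_grid = gamma_grid, contrast = cvec)
}
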