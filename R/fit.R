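# Batch weighted least squares across sites. All sites share one design
# matrix X (n x p) but each site has its own weight vector (column of W,
# n x m; weight 0 marks a masked entry, which is algebraically identical to
# dropping the observation from the normal equations -- only the residual
# degrees of freedom differ, and those are counted from unmasked entries).
# Precomputing (X'WX)^-1 per site lets every bootstrap refit reduce to a few
# BLAS-level matrix products, which is what makes 1000-replicate bootstrap
# calibration studies feasible in plain R.

wls_precompute <- function(X, W) {
  n <- nrow(X); p <- ncol(X); m <- ncol(W)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Z <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  Aflat <- crossprod(Z, W)                       # npair x m
  n_used <- colSums(W > 0)
  Ainv <- matrix(NA_real_, p * p, m)             # column j = vec((X'W_jX)^-1)
  ok <- rep(TRUE, m)
  A <- matrix(0, p, p)
  iu <- pairs[, 1] + (pairs[, 2] - 1L) * p
  il <- pairs[, 2] + (pairs[, 1] - 1L) * p
  for (j in seq_len(m)) {
    A[iu] <- Aflat[, j]; A[il] <- Aflat[, j]
    Aj <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Aj) || n_used[j] <= p) ok[j] <- FALSE
    else Ainv[, j] <- Aj
  }
  list(X = X, W = W, p = p, n = n, m = m, Ainv = Ainv, ok = ok,
       n_used = n_used, df = n_used - p)
}

# Solve beta = (X'WX)^-1 X'Wy for all sites at once; returns p x m.
wls_beta <- function(pre, b) {
  p <- pre$p
  beta <- matrix(0, p, pre$m)
  for (k in seq_len(p)) {
    acc <- numeric(pre$m)
    for (l in seq_len(p))
      acc <- acc + pre$Ainv[k + (l - 1L) * p, ] * b[l, ]
    beta[k, ] <- acc
  }
  beta
}

# Fit all sites for response matrix Y (n x m; NAs allowed where weight 0).
# Returns coefficients, and t/p for the column named in `coef`.
wls_fit <- function(pre, Y, coef_index) {
  Y0 <- Y
  Y0[is.na(Y0)] <- 0
  WY <- pre$W * Y0
  b <- crossprod(pre$X, WY)                      # p x m
  beta <- wls_beta(pre, b)
  rss <- colSums(WY * Y0) - colSums(beta * b)
  rss <- pmax(rss, 0)
  sigma2 <- rss / pre$df
  add <- coef_index + (coef_index - 1L) * pre$p
  var_d <- sigma2 * pre$Ainv[add, ]
  beta_d <- beta[coef_index, ]
  tt <- beta_d / sqrt(var_d)
  pval <- 2 * pt(-abs(tt), df = pre$df)
  degenerate <- pre$ok & rss < 1e-10 * pmax(colSums(WY * Y0), 1)
  pval[degenerate & !is.na(tt) & abs(tt) > 0] <- 1e-300
  pval <- pmax(pval, 1e-300)
  pval[is.nan(pval)] <- NA
  bad <- !pre$ok
  beta_d[bad] <- NA; tt[bad] <- NA; pval[bad] <- NA
  list(beta = beta, beta_d = beta_d, se = sqrt(var_d), t = tt, p = pval,
       degenerate = degenerate)
}

#' Fit per-site weighted linear models
#'
#' Weighted least squares of percent methylation on the design at each site,
#' using `log10(coverage)` as weights (coverage >= 10 guarantees weights
#' >= 1); masked entries drop out. The diagnosis coefficient is reported in
#' percentage points (case minus control) with a two-sided t-test p-value on
#' `n_used - p` residual degrees of freedom.
#'
#' @param meth a [meth_matrix()].
#' @param design full design matrix from [build_design()] (must contain a
#'   `diagnosis` column).
#' @param weights optional n x m weight matrix; default `log10(coverage)`.
#' @return data.frame (class `SiteFitResult`): `site_id`, `beta_diag`, `se`,
#'   `t`, `p`, `direction`, `n_used`, `degenerate`. Sites whose design is
#'   rank deficient after masking are returned with `NA` statistics and
#'   counted in `attr(, "n_skipped")`.
#' @export
fit_site_models <- function(meth, design, weights = NULL) {
  ci <- match("diagnosis", colnames(design))
  if (is.na(ci)) stop("design has no diagnosis column")
  stopifnot(nrow(design) == length(meth$samples))
  Y <- t(meth$meth_pct)                          # n x m
  W <- if (is.null(weights)) t(log10(meth$coverage)) else t(weights)
  W[is.na(W) | is.na(Y)] <- 0
  pre <- wls_precompute(design, W)
  fit <- wls_fit(pre, Y, ci)
  out <- data.frame(site_id = meth$sites$site_id,
                    beta_diag = fit$beta_d, se = fit$se, t = fit$t,
                    p = fit$p, direction = sign(fit$beta_d),
                    n_used = pre$n_used, degenerate = fit$degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!pre$ok)
  if (any(!pre$ok))
    message(sum(!pre$ok), " site(s) skipped: rank-deficient after masking")
  class(out) <- c("SiteFitResult", class(out))
  out
}

#' Residual-bootstrap empirical null
#'
#' Fits the full and null (diagnosis dropped) models once per site. For each
#' bootstrap, one vector of sample indices is drawn with replacement and
#' shared across all sites, preserving cross-site correlation; the
#' pseudonull response is the null-model fitted values plus the full-model
#' residuals re-indexed by that vector. The full model is refit on the
#' pseudonull data and the diagnosis p-value and coefficient recorded per
#' site. Because the null fitted values lie in the column space of the null
#' design, the refit diagnosis coefficient carries no case-control signal.
#'
#' @param meth a [meth_matrix()].
#' @param design full design matrix (with `diagnosis` column).
#' @param null_design the same design without the diagnosis column; defaults
#'   to dropping it from `design`.
#' @param weights optional weight matrix; default `log10(coverage)`.
#' @param B number of bootstraps (default 1000).
#' @param seed integer seed; results are reproducible.
#' @return A `BootstrapNull` list: `B`, `seed`, `site_id`, `null_p` and
#'   `null_beta` (B x sites matrices), and `index` (B x n resample indices).
#' @export
residual_bootstrap <- function(meth, design, null_design = NULL,
                               weights = NULL, B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  ci <- match("diagnosis", colnames(design))
  if (is.na(ci)) stop("design has no diagnosis column")
  if (is.null(null_design))
    null_design <- design[, -ci, drop = FALSE]
  n <- nrow(design)
  Y <- t(meth$meth_pct)
  W <- if (is.null(weights)) t(log10(meth$coverage)) else t(weights)
  W[is.na(W) | is.na(Y)] <- 0
  pre_full <- wls_precompute(design, W)
  pre_null <- wls_precompute(null_design, W)
  Y0 <- Y; Y0[is.na(Y0)] <- 0
  fit_full <- wls_fit(pre_full, Y, ci)
  b_null <- crossprod(null_design, W * Y0)
  beta_null <- wls_beta(pre_null, b_null)
  fitted_null <- null_design %*% beta_null
  resid_full <- Y0 - design %*% fit_full$beta
  resid_full[W == 0] <- 0   # masked entries contribute nothing

  m <- ncol(Y)
  null_p <- null_beta <- matrix(NA_real_, B, m,
                                dimnames = list(NULL, meth$sites$site_id))
  index <- matrix(NA_integer_, B, n)
  set.seed(seed)
  for (bt in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    index[bt, ] <- idx
    Yb <- fitted_null + resid_full[idx, , drop = FALSE]
    fb <- wls_fit(pre_full, Yb, ci)
    null_p[bt, ] <- fb$p
    null_beta[bt, ] <- fb$beta_d
  }
  structure(list(B = B, seed = seed, site_id = meth$sites$site_id,
                 null_p = null_p, null_beta = null_beta, index = index),
            class = "BootstrapNull")
}

#' Study-wide significance from the bootstrap null
#'
#' Records the minimum null p-value across sites in each bootstrap; the
#' study-wide threshold is the `alpha` quantile of those B minima, and a
#' site is study-wide significant iff its observed p-value falls below it.
#' A per-site empirical p-value `(1 + #\{b: min-p_b <= p_site\}) / (B + 1)`
#' is reported alongside.
#'
#' @param fits [fit_site_models()] output.
#' @param null [residual_bootstrap()] output on the same sites.
#' @param alpha study-wide level (default 0.05).
#' @return list with `threshold`, `min_p` (B-vector), and `table` (data.frame
#'   `site_id`, `p`, `empirical_p`, `significant`).
#' @export
empirical_significance <- function(fits, null, alpha = 0.05) {
  stopifnot(identical(fits$site_id, null$site_id))
  min_p <- apply(null$null_p, 1, min, na.rm = TRUE)
  threshold <- quantile(min_p, alpha, names = FALSE)
  emp <- vapply(fits$p, function(p)
    (1 + sum(min_p <= p)) / (null$B + 1), numeric(1))
  list(threshold = threshold, min_p = min_p,
       table = data.frame(site_id = fits$site_id, p = fits$p,
                          empirical_p = emp,
                          significant = !is.na(fits$p) & fits$p < threshold,
                          stringsAsFactors = FALSE))
}
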