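# Surrogate variable estimation (iteratively reweighted), iterative SV-based
# sample outlier removal, per-sample library diagnostics, and cis-meQTL
# detection used to validate each outlier-removal round.

# residual sum of squares per site after projecting columns of Y (n x m)
# onto the column space of X
.rss_proj <- function(Y, X) {
  Q <- qr.Q(qr(X))
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

#' Estimate surrogate variables (iteratively reweighted SVA)
#'
#' A simplified iteratively-reweighted SVA: (1) residualize the
#' complete-case methylation matrix against the protected design, (2) take
#' the top-k left singular vectors of the residual matrix as candidate SVs,
#' (3) weight each site by evidence of association with the SVs but not the
#' protected variable, (4) recompute the SVD on the site-weighted matrix;
#' repeated for a fixed number of rounds. Returned SVs are orthonormal.
#'
#' @param meth a [meth_matrix()]; only complete-case sites are used (others
#'   are dropped with a message).
#' @param design protected design matrix, including the `diagnosis` column
#'   (case-control status is protected: it never enters the residualization
#'   weights positively).
#' @param k number of SVs (default 10); truncated with a warning if it
#'   exceeds the available rank.
#' @param n_iter reweighting rounds (default 5).
#' @return list (class `SurrogateVariableSet`) with `sv` (samples x k,
#'   orthonormal columns), `samples`, `method = "irw"`.
#' @export
estimate_svs <- function(meth, design, k = 10, n_iter = 5) {
  stopifnot(k >= 1)
  cc <- rowSums(is.na(meth$meth_pct)) == 0
  if (!all(cc)) {
    message("estimate_svs: using ", sum(cc), "/", length(cc),
            " complete-case sites")
    meth <- subset_sites(meth, which(cc))
  }
  Y <- t(meth$meth_pct)                           # n x m
  n <- nrow(Y)
  kmax <- n - qr(design)$rank
  if (k > kmax) {
    warning("k truncated from ", k, " to available rank ", kmax)
    k <- kmax
  }
  ci <- match("diagnosis", colnames(design))
  X0 <- if (!is.na(ci)) design[, -ci, drop = FALSE] else design
  Q <- qr.Q(qr(design))
  R <- Y - Q %*% crossprod(Q, Y)                  # residual to full design
  w <- rep(1, ncol(Y))
  sv <- NULL
  for (iter in seq_len(n_iter)) {
    Rw <- sweep(R, 2, w, `*`)
    e <- eigen(tcrossprod(Rw), symmetric = TRUE)
    sv <- e$vectors[, seq_len(k), drop = FALSE]
    if (iter == n_iter) break
    if (n - ncol(design) - k < 1) break  # no residual df to reweight with
    # evidence of association with SVs (F-test of SVs added to the design)
    rss1 <- .rss_proj(Y, cbind(design, sv))
    rss0 <- .rss_proj(Y, design)
    df1 <- n - ncol(design) - k
    f_sv <- pmax((rss0 - rss1), 0) / k / pmax(rss1 / df1, 1e-12)
    p_sv <- pf(f_sv, k, df1, lower.tail = FALSE)
    # evidence of association with the protected variable
    if (!is.na(ci)) {
      rss_null <- .rss_proj(Y, cbind(X0, sv))
      rss_full <- .rss_proj(Y, cbind(design, sv))
      dff <- n - ncol(design) - k
      f_dx <- pmax(rss_null - rss_full, 0) / pmax(rss_full / dff, 1e-12)
      p_dx <- pf(f_dx, 1, dff, lower.tail = FALSE)
    } else p_dx <- rep(1, ncol(Y))
    w <- (1 - p_sv) * p_dx
  }
  rownames(sv) <- meth$samples
  colnames(sv) <- paste0("SV", seq_len(k))
  structure(list(samples = meth$samples, sv = sv, method = "irw"),
            class = "SurrogateVariableSet")
}

#' Iterative SV-based sample outlier removal
#'
#' Each round estimates SVs on the current samples and flags any sample more
#' than `z_thresh` standard deviations (column SD including the candidate)
#' from the column mean in any SV; all flagged samples are removed and the
#' process repeats until no sample is flagged or `max_iter` rounds.
#'
#' @param meth a [meth_matrix()].
#' @param sheet sample sheet (the design is rebuilt each round).
#' @param z_thresh SD multiple (default 4).
#' @param k SVs per round (default 10).
#' @param max_iter maximum rounds (default 10).
#' @return list with `kept` (sample ids) and `log` (data.frame `round`,
#'   `sample_id`).
#' @export
detect_sv_outliers <- function(meth, sheet, z_thresh = 4, k = 10,
                               max_iter = 10) {
  kept <- meth$samples
  log <- data.frame(round = integer(), sample_id = character(),
                    stringsAsFactors = FALSE)
  for (round in seq_len(max_iter)) {
    cur <- subset_samples(meth, kept)
    design <- build_design(sheet[match(kept, sheet$sample_id), ])
    kk <- min(k, length(kept) - ncol(design) - 1)
    if (kk < 1) break
    svs <- estimate_svs(cur, design, k = kk)$sv
    z <- abs(scale(svs))
    flagged <- kept[apply(z > z_thresh, 1, any)]
    if (length(flagged) == 0) break
    if (length(flagged) >= length(kept))
      stop("all samples flagged as SV outliers: degenerate data")
    log <- rbind(log, data.frame(round = round, sample_id = flagged,
                                 stringsAsFactors = FALSE))
    kept <- setdiff(kept, flagged)
  }
  list(kept = kept, log = log)
}

#' Per-sample library QC diagnostics
#'
#' Reports, per sample: (a) the fraction of cytosines with methylation above
#' 50% (flag if > 0.99: failed bisulfite conversion / fully methylated
#' library); (b) the fraction of CpG sites with methylation in (20%, 80%)
#' (flag if > 0.5: non-bimodal CpG distribution); (c) the Kolmogorov-Smirnov
#' distance between the sample's log-coverage ECDF and the pooled ECDF of
#' all samples (flag if > 0.3: aberrant coverage distribution).
#'
#' @param counts raw per-sample [count_matrix()].
#' @param frac_hyper_thresh,midrange_thresh,ks_thresh flag thresholds.
#' @return data.frame with one row per sample: diagnostics, per-mode flags,
#'   and `flagged` (any mode).
#' @export
sample_qc <- function(counts, frac_hyper_thresh = 0.99,
                      midrange_thresh = 0.5, ks_thresh = 0.3) {
  frac <- 100 * counts$methylated / counts$coverage
  cpg <- counts$sites$context == "CpG"
  logcov <- log10(counts$coverage + 1)
  pooled <- sort(logcov[!is.na(logcov)])
  res <- lapply(seq_along(counts$samples), function(j) {
    fj <- frac[, j]
    frac_hyper <- mean(fj > 50, na.rm = TRUE)
    midrange <- if (any(cpg)) mean(fj[cpg] > 20 & fj[cpg] < 80, na.rm = TRUE)
    else NA_real_
    lj <- logcov[, j]
    lj <- lj[!is.na(lj)]
    # KS distance between sample ECDF and pooled ECDF
    grid <- sort(unique(lj))
    ks <- max(abs(ecdf(lj)(grid) - ecdf(pooled)(grid)))
    data.frame(sample_id = counts$samples[j], frac_hyper = frac_hyper,
               midrange_cpg = midrange, ks_coverage = ks,
               flag_hypermethylated = frac_hyper > frac_hyper_thresh,
               flag_non_bimodal = !is.na(midrange) &&
                 midrange > midrange_thresh,
               flag_coverage = ks > ks_thresh,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$flagged <- out$flag_hypermethylated | out$flag_non_bimodal |
    out$flag_coverage
  out
}

#' Detect cis-meQTLs
#'
#' For every SNP-site pair within `cis_window` (SNP position to cytosine
#' position, inclusive), ordinary least squares of percent methylation on
#' additive dosage plus covariates; pairs with p < `alpha` are reported.
#' Monomorphic SNPs are skipped and logged.
#'
#' @param meth a [meth_matrix()].
#' @param genotypes samples x SNPs dosage matrix (0/1/2).
#' @param snp_info data.frame `snp_id`, `chrom`, `pos`.
#' @param covariates samples x q covariate matrix (no intercept needed), or
#'   NULL.
#' @param cis_window max SNP-site distance in bp (default 1e6).
#' @param alpha reporting threshold (default 1e-4).
#' @return data.frame of pairs: `snp_id`, `site_id`, `distance`, `beta`,
#'   `p`; skipped monomorphic SNPs in `attr(, "skipped")`.
#' @export
detect_meqtls <- function(meth, genotypes, snp_info, covariates = NULL,
                          cis_window = 1e6, alpha = 1e-4) {
  shared <- intersect(meth$samples, rownames(genotypes))
  if (length(shared) < 3) stop("too few shared samples")
  meth <- subset_samples(meth, shared)
  G <- genotypes[shared, , drop = FALSE]
  C <- if (is.null(covariates)) NULL
  else as.matrix(covariates)[shared, , drop = FALSE]
  rows <- list()
  skipped <- character()
  for (s in seq_len(ncol(G))) {
    dos <- G[, s]
    if (length(unique(dos)) < 2) {
      skipped <- c(skipped, colnames(G)[s])
      next
    }
    info <- snp_info[match(colnames(G)[s], snp_info$snp_id), ]
    near <- which(meth$sites$chrom == info$chrom &
                    abs(meth$sites$pos - info$pos) <= cis_window)
    for (i in near) {
      y <- meth$meth_pct[i, ]
      ok <- !is.na(y)
      X <- cbind(1, dos, C)[ok, , drop = FALSE]
      if (sum(ok) <= ncol(X) || qr(X)$rank < ncol(X)) next
      fit <- stats::lm.fit(X, y[ok])
      rss <- sum(fit$residuals^2)
      df <- sum(ok) - ncol(X)
      XtXi <- chol2inv(chol(crossprod(X)))
      se <- sqrt(rss / df * XtXi[2, 2])
      tt <- fit$coefficients[2] / se
      p <- 2 * pt(-abs(tt), df)
      if (!is.na(p) && p < alpha)
        rows[[length(rows) + 1]] <- data.frame(
          snp_id = colnames(G)[s], site_id = meth$sites$site_id[i],
          distance = abs(meth$sites$pos[i] - info$pos),
          beta = unname(fit$coefficients[2]), p = p,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(snp_id = character(), site_id = character(),
                  distance = numeric(), beta = numeric(), p = numeric(),
                  stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Fraction of known meQTLs recovered
#'
#' `|detected intersect known| / |known assayable|`, where a known pair is
#' assayable iff its SNP and site are both present in the data at hand.
#'
#' @param detected [detect_meqtls()] output.
#' @param known data.frame `snp_id`, `site_id`.
#' @param snps_present,sites_present identifiers present in the genotype and
#'   methylation data.
#' @return fraction in \[0, 1\].
#' @export
known_meqtl_recovery <- function(detected, known, snps_present,
                                 sites_present) {
  assayable <- known[known$snp_id %in% snps_present &
                       known$site_id %in% sites_present, ]
  if (nrow(assayable) == 0) stop("no assayable known meQTLs")
  key <- function(d) paste(d$snp_id, d$site_id)
  mean(key(assayable) %in% key(detected))
}
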