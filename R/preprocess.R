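# Count -> methylation-percentage preprocessing: coverage filters, median
# normalization, uniting sites across samples, the 25%-least-variable filter,
# and single-pass per-site outlier masking.

#' Filter entries by coverage
#'
#' Masks entries with coverage below `min_cov` (default 10x retained), then
#' per sample masks entries above that sample's `upper_pctile` coverage
#' quantile (linear-interpolation quantile over entries surviving the lower
#' filter) to remove PCR-bias artifacts.
#'
#' @param counts a [count_matrix()].
#' @param min_cov minimum retained coverage (reads).
#' @param upper_pctile upper percentile (percent) above which entries are
#'   masked per sample.
#' @return Filtered `CountMatrix`.
#' @export
filter_coverage <- function(counts, min_cov = 10, upper_pctile = 99.9) {
  stopifnot(min_cov >= 1, upper_pctile > 0, upper_pctile <= 100)
  cov <- counts$coverage; met <- counts$methylated
  cov[!is.na(cov) & cov < min_cov] <- NA
  for (j in seq_along(counts$samples)) {
    v <- cov[, j]
    if (all(is.na(v))) {
      warning("sample ", counts$samples[j],
              " has no entries above minimum coverage; fully masked")
      next
    }
    thr <- quantile(v, upper_pctile / 100, na.rm = TRUE, names = FALSE)
    cov[!is.na(v) & v > thr, j] <- NA
  }
  met[is.na(cov)] <- NA
  count_matrix(counts$sites, counts$samples, cov, met)
}

#' Median-normalize coverage across samples
#'
#' Each sample is scaled so its median coverage matches the median of the
#' per-sample median coverages; coverage and methylated counts are both
#' scaled and rounded to the nearest integer, with methylated clipped to
#' coverage.
#'
#' @param counts a [count_matrix()].
#' @return Normalized `CountMatrix`.
#' @export
normalize_coverage <- function(counts) {
  meds <- apply(counts$coverage, 2, median, na.rm = TRUE)
  if (any(is.na(meds)))
    stop("sample(s) with no unmasked entries: ",
         paste(counts$samples[is.na(meds)], collapse = ", "))
  if (any(meds == 0)) stop("zero median coverage")
  ref <- median(meds)
  factors <- ref / meds
  cov <- round(sweep(counts$coverage, 2, factors, `*`))
  met <- round(sweep(counts$methylated, 2, factors, `*`))
  met <- pmin(met, cov)
  out <- count_matrix(counts$sites, counts$samples, cov, met)
  attr(out, "norm_factors") <- setNames(factors, counts$samples)
  out
}

#' Retain sites covered in enough cases and controls
#'
#' Keeps sites with unmasked data in at least `min_cases` cases and
#' `min_controls` controls; output sites are in genomic order.
#'
#' @param counts a [count_matrix()] (after [filter_coverage()]).
#' @param sheet sample sheet identifying case/control.
#' @param min_cases,min_controls group coverage thresholds (default 20/20).
#' @return `CountMatrix` of retained sites.
#' @export
unite_sites <- function(counts, sheet, min_cases = 20, min_controls = 20) {
  dx <- sheet$diagnosis[match(counts$samples, sheet$sample_id)]
  if (anyNA(dx)) stop("samples missing from sample sheet")
  n_case <- sum(dx == "case"); n_ctrl <- sum(dx == "control")
  if (min_cases > n_case || min_controls > n_ctrl)
    stop(sprintf("thresholds (%d/%d) exceed group sizes (%d cases/%d controls)",
                 min_cases, min_controls, n_case, n_ctrl))
  ok <- !is.na(counts$coverage)
  keep <- rowSums(ok[, dx == "case", drop = FALSE]) >= min_cases &
    rowSums(ok[, dx == "control", drop = FALSE]) >= min_controls
  out <- subset_sites(counts, which(keep))
  subset_sites(out, genomic_order(out$sites))
}

#' Convert counts to percent methylation
#'
#' @param counts a [count_matrix()].
#' @return A [meth_matrix()] with `meth_pct = 100 * methylated / coverage`;
#'   masks preserved and coverage carried alongside for model weights.
#' @export
percent_methylation <- function(counts) {
  meth_matrix(counts$sites, counts$samples,
              100 * counts$methylated / counts$coverage, counts$coverage)
}

#' Drop the least variable sites
#'
#' Sites are ranked by the standard deviation of percent methylation across
#' unmasked samples (n-1 denominator); the lowest `drop_fraction` are
#' removed, ties broken by genomic order with the lower coordinate dropped
#' first.
#'
#' @param meth a [meth_matrix()].
#' @param drop_fraction fraction in \[0, 1) of sites to remove (default 0.25,
#'   the 25% least variable).
#' @return Filtered `MethylationMatrix`.
#' @export
drop_invariant_sites <- function(meth, drop_fraction = 0.25) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  if (drop_fraction == 0) return(meth)
  sds <- apply(meth$meth_pct, 1, sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0
  n_drop <- floor(drop_fraction * nrow(meth$sites))
  if (n_drop == 0) return(meth)
  ord <- order(sds, meth$sites$chrom, meth$sites$pos)
  drop <- ord[seq_len(n_drop)]
  subset_sites(meth, sort(setdiff(seq_len(nrow(meth$sites)), drop)))
}

#' Mask per-site sample outliers
#'
#' Single pass: at each site, samples more than `z_thresh` standard
#' deviations (sample SD, n-1 denominator, computed once from all unmasked
#' values) from the site mean are masked. Sites with zero SD are untouched.
#' Note the analytic bound |z| <= (n-1)/sqrt(n): no masking can occur for
#' n < 11 at the default threshold of 3.
#'
#' @param meth a [meth_matrix()].
#' @param z_thresh SD multiple (default 3).
#' @return `MethylationMatrix` with outlying entries masked.
#' @export
mask_site_outliers <- function(meth, z_thresh = 3) {
  m <- meth$meth_pct
  mu <- rowMeans(m, na.rm = TRUE)
  sds <- apply(m, 1, sd, na.rm = TRUE)
  z <- abs(m - mu) / sds
  bad <- !is.na(z) & sds > 0 & z > z_thresh
  m[bad] <- NA
  cov <- meth$coverage
  cov[bad] <- NA
  meth_matrix(meth$sites, meth$samples, m, cov)
}

#' Restrict to sites with data in every sample
#' @param meth a [meth_matrix()].
#' @return `MethylationMatrix` of complete-case sites.
#' @export
complete_sites <- function(meth) {
  subset_sites(meth, which(rowSums(is.na(meth$meth_pct)) == 0))
}
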