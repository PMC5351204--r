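# Bump-hunting DMR detection: cluster sites by genomic gap, smooth per-site
# case-control coefficients within clusters, pick a data-driven cutoff, call
# maximal runs above the cutoff as candidate regions, and assign each a
# family-wise error rate from candidate regions recomputed on every residual
# bootstrap.

#' Cluster sites by genomic gap
#'
#' Adjacent sites on the same chromosome join one cluster iff the gap
#' between them is at most `maxgap` (transitive closure).
#'
#' @param chrom,pos site coordinates, sorted genomically within chromosome.
#' @param maxgap maximum gap in bp (default 300).
#' @return integer cluster labels, one per site.
#' @export
cluster_sites <- function(chrom, pos, maxgap = 300) {
  stopifnot(length(chrom) == length(pos))
  if (length(pos) == 0) return(integer(0))
  if (any(diff(pos) < 0 & chrom[-1] == chrom[-length(chrom)]))
    stop("positions must be sorted within chromosome")
  new_chrom <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  gap <- c(0, diff(pos))
  cumsum(new_chrom | (gap > maxgap))
}

#' Smooth per-site coefficients within clusters
#'
#' Within clusters of at least `min_sites` sites, a running mean over a
#' centered window of `window` sites (truncated at cluster edges); smaller
#' clusters pass through unsmoothed.
#'
#' @param beta per-site coefficients.
#' @param clusters labels from [cluster_sites()].
#' @param window window size in sites (default 5).
#' @param min_sites minimum cluster size for smoothing (default 7).
#' @return smoothed values aligned to the input sites.
#' @export
smooth_coefficients <- function(beta, clusters, window = 5, min_sites = 7) {
  out <- beta
  half <- (window - 1) %/% 2
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    nc <- length(idx)
    if (nc < min_sites) next
    v <- beta[idx]
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(nc) - half, 1)
    hi <- pmin(seq_len(nc) + half, nc)
    out[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Data-driven coefficient cutoff
#'
#' The `probs` quantile (linear interpolation) of the absolute smoothed
#' coefficients.
#'
#' @param smoothed smoothed coefficients.
#' @param probs quantile (default 0.99).
#' @return numeric cutoff.
#' @export
pick_cutoff <- function(smoothed, probs = 0.99) {
  if (length(smoothed) < 100)
    warning("pick_cutoff on fewer than 100 values; cutoff may be unstable")
  quantile(abs(smoothed), probs, na.rm = TRUE, names = FALSE)
}

#' Find candidate regions
#'
#' Maximal runs of consecutive sites within one cluster whose smoothed value
#' exceeds `cutoff` (hypermethylated) or falls below `-cutoff`
#' (hypomethylated). A region's `value` is the mean of its member sites' raw
#' coefficients; `length_bp` spans first to last member position.
#'
#' @param sites site table (`chrom`, `pos`), genomically sorted.
#' @param smoothed smoothed coefficients.
#' @param beta raw per-site coefficients.
#' @param clusters labels from [cluster_sites()].
#' @param cutoff positive cutoff from [pick_cutoff()].
#' @return data.frame of `CandidateRegion`s: `chrom`, `start`, `end`,
#'   `n_sites`, `value`, `length_bp`, `direction`.
#' @export
find_candidate_regions <- function(sites, smoothed, beta, clusters, cutoff) {
  stopifnot(cutoff > 0)
  state <- ifelse(is.na(smoothed), 0L,
                  ifelse(smoothed > cutoff, 1L,
                         ifelse(smoothed < -cutoff, -1L, 0L)))
  brk <- c(TRUE, state[-1] != state[-length(state)] |
             clusters[-1] != clusters[-length(clusters)])
  run <- cumsum(brk)
  rows <- lapply(split(seq_along(state), run), function(idx) {
    if (state[idx[1]] == 0L) return(NULL)
    data.frame(chrom = sites$chrom[idx[1]],
               start = sites$pos[idx[1]],
               end = sites$pos[idx[length(idx)]],
               n_sites = length(idx),
               value = mean(beta[idx]),
               length_bp = sites$pos[idx[length(idx)]] -
                 sites$pos[idx[1]] + 1,
               direction = state[idx[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(), value = numeric(),
                      length_bp = numeric(), direction = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Family-wise error rate for candidate regions
#'
#' For each observed region, the fraction of bootstraps containing at least
#' one null candidate region strictly more extreme on both axes: longer
#' (`length_bp`) and with higher `|value|`.
#'
#' @param regions observed [find_candidate_regions()] output.
#' @param boot_regions list of B data.frames of null candidate regions.
#' @return `regions` with an `fwer` column.
#' @export
compute_fwer <- function(regions, boot_regions) {
  B <- length(boot_regions)
  if (B == 0) stop("no bootstrap regions: B = 0")
  if (nrow(regions) == 0) {
    regions$fwer <- numeric(0)
    return(regions)
  }
  counts <- integer(nrow(regions))
  for (b in seq_len(B)) {
    q <- boot_regions[[b]]
    if (is.null(q) || nrow(q) == 0) next
    for (r in seq_len(nrow(regions))) {
      dom <- q$length_bp > regions$length_bp[r] &
        abs(q$value) > abs(regions$value[r])
      if (any(dom)) counts[r] <- counts[r] + 1L
    }
  }
  regions$fwer <- counts / B
  regions
}

#' Flag significant DMRs
#'
#' Bonferroni-style threshold `alpha / n_tests` on the FWER, applied at the
#' resolution of the FWER itself (strict inequality): with the default 24
#' chromosome-level tests, `0.05 / 24 ~= 0.00208` rounds to the operative
#' threshold 0.002, so a region with FWER 0.001 is significant and one with
#' 0.002 is not. `digits` matches the granularity of an FWER computed from
#' B = 1000 bootstraps.
#'
#' @param regions regions with `fwer` (see [compute_fwer()]).
#' @param n_tests number of independent analyses (default 24).
#' @param alpha overall level (default 0.05).
#' @param digits rounding applied to the raw threshold (default 3).
#' @return `regions` with a `significant` column; threshold in
#'   `attr(, "threshold")`.
#' @export
dmr_significance <- function(regions, n_tests = 24, alpha = 0.05,
                             digits = 3) {
  threshold <- round(alpha / n_tests, digits)
  regions$significant <- !is.na(regions$fwer) & regions$fwer < threshold
  attr(regions, "threshold") <- threshold
  regions
}

#' Run the DMR analysis end to end
#'
#' Fits per-site models, clusters sites, smooths the coefficients, picks a
#' data-driven cutoff, calls candidate regions, and assigns FWERs by
#' rerunning the identical candidate pipeline (with the observed cutoff) on
#' the per-site coefficients of every residual bootstrap.
#'
#' @param meth a [meth_matrix()] (relaxed-coverage DMR input), sites in
#'   genomic order.
#' @param design full design matrix.
#' @param maxgap,window,min_sites,quantile see the stage functions.
#' @param B bootstraps (default 1000).
#' @param seed integer seed.
#' @param null optional precomputed [residual_bootstrap()] on the same
#'   sites; when supplied, `B` and `seed` are ignored.
#' @return list with `regions` (candidate regions with `fwer`), `cutoff`,
#'   `fits`, `clusters`.
#' @export
run_dmr <- function(meth, design, maxgap = 300, window = 5, min_sites = 7,
                    quantile = 0.99, B = 1000, seed = 1, null = NULL) {
  fits <- fit_site_models(meth, design)
  clusters <- cluster_sites(meth$sites$chrom, meth$sites$pos, maxgap)
  beta <- fits$beta_diag
  beta[is.na(beta)] <- 0
  smoothed <- smooth_coefficients(beta, clusters, window, min_sites)
  cutoff <- pick_cutoff(smoothed, quantile)
  regions <- find_candidate_regions(meth$sites, smoothed, beta, clusters,
                                    cutoff)
  if (is.null(null))
    null <- residual_bootstrap(meth, design, B = B, seed = seed)
  boot_regions <- lapply(seq_len(null$B), function(b) {
    nb <- null$null_beta[b, ]
    nb[is.na(nb)] <- 0
    sm <- smooth_coefficients(nb, clusters, window, min_sites)
    find_candidate_regions(meth$sites, sm, nb, clusters, cutoff)
  })
  regions <- compute_fwer(regions, boot_regions)
  list(regions = regions, cutoff = cutoff, fits = fits, clusters = clusters)
}
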