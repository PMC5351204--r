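# Global hypermethylation-shift test: among sites nominally differentially
# methylated (p < cutoff), is the proportion with a positive case-control
# coefficient larger than the residual bootstrap null predicts?
# "Hypermethylated" is operationalized as diagnosis coefficient > 0 (case
# minus control difference greater than zero); exact-zero coefficients are
# excluded from both numerator and denominator.

#' Proportion of hypermethylated sites at a nominal cutoff
#'
#' @param fits [fit_site_models()] output (or any data.frame with `p` and
#'   `beta_diag`).
#' @param cutoff nominal p-value cutoff.
#' @return list with `n_nominal` (sites with p < cutoff) and `prop_hyper`
#'   (fraction with positive coefficient among nominal non-tied sites; `NA`
#'   when no site is nominal).
#' @export
hyper_proportion <- function(fits, cutoff) {
  stopifnot(nrow(fits) > 0)
  nom <- !is.na(fits$p) & fits$p < cutoff
  n_nominal <- sum(nom)
  use <- nom & fits$beta_diag != 0
  prop <- if (sum(use) == 0) NA_real_ else
    sum(fits$beta_diag[use] > 0) / sum(use)
  list(n_nominal = n_nominal, prop_hyper = prop)
}

# prop_hyper for one bootstrap's p/beta vectors
.boot_prop <- function(p, beta, cutoff) {
  use <- !is.na(p) & p < cutoff & !is.na(beta) & beta != 0
  if (!any(use)) return(NA_real_)
  sum(beta[use] > 0) / sum(use)
}

#' Global hypermethylation-shift test
#'
#' Computes the observed hypermethylated proportion at each cutoff and the
#' same quantity in every residual bootstrap; the one-sided empirical
#' p-value is `(1 + #\{b: prop_b >= observed\}) / (B' + 1)` over the `B'`
#' bootstraps in which any site was nominal. Cutoffs in which more than half
#' the bootstraps have no nominal site are flagged unstable.
#'
#' @param fits [fit_site_models()] output.
#' @param null [residual_bootstrap()] output (carries per-bootstrap p-values
#'   and coefficients).
#' @param cutoffs nominal p-value cutoffs (default `c(0.05, 5e-3, 5e-4)`).
#' @return data.frame (class `GlobalShiftResult`) with one row per cutoff:
#'   `cutoff`, `n_nominal`, `prop_hyper`, `boot_mean_prop`, `empirical_p`,
#'   `unstable`; the per-bootstrap proportions are in
#'   `attr(, "boot_props")`.
#' @export
global_shift_test <- function(fits, null, cutoffs = c(0.05, 5e-3, 5e-4)) {
  stopifnot(identical(fits$site_id, null$site_id))
  boot_props <- matrix(NA_real_, null$B, length(cutoffs),
                       dimnames = list(NULL, as.character(cutoffs)))
  out <- data.frame(cutoff = cutoffs, n_nominal = NA_integer_,
                    prop_hyper = NA_real_, boot_mean_prop = NA_real_,
                    empirical_p = NA_real_, unstable = FALSE)
  for (ci in seq_along(cutoffs)) {
    obs <- hyper_proportion(fits, cutoffs[ci])
    props <- vapply(seq_len(null$B), function(b)
      .boot_prop(null$null_p[b, ], null$null_beta[b, ], cutoffs[ci]),
      numeric(1))
    boot_props[, ci] <- props
    usable <- !is.na(props)
    out$n_nominal[ci] <- obs$n_nominal
    out$prop_hyper[ci] <- obs$prop_hyper
    out$boot_mean_prop[ci] <- mean(props[usable])
    out$unstable[ci] <- mean(!usable) > 0.5
    if (!is.na(obs$prop_hyper) && any(usable))
      out$empirical_p[ci] <- (1 + sum(props[usable] >= obs$prop_hyper)) /
        (sum(usable) + 1)
  }
  attr(out, "boot_props") <- boot_props
  class(out) <- c("GlobalShiftResult", class(out))
  out
}

#' Hypermethylated proportion as a function of effect size
#'
#' For each coefficient-magnitude threshold, the hypermethylated proportion
#' among sites with `p < p_cutoff` and `|beta_diag| >= threshold`. Under a
#' genuine hypermethylation signal this curve is expected to rise with the
#' threshold; under the null it stays flat near 0.5.
#'
#' @param fits [fit_site_models()] output.
#' @param min_abs_beta numeric grid of thresholds (percentage points);
#'   threshold 0 reproduces [hyper_proportion()] at `p_cutoff`.
#' @param p_cutoff nominal p-value cutoff (default 0.05).
#' @return data.frame `min_abs_beta`, `n`, `prop_hyper`.
#' @export
shift_vs_effect_size <- function(fits, min_abs_beta = seq(0, 5, by = 0.5),
                                 p_cutoff = 0.05) {
  stopifnot(nrow(fits) > 0)
  rows <- lapply(min_abs_beta, function(th) {
    use <- !is.na(fits$p) & fits$p < p_cutoff & !is.na(fits$beta_diag) &
      fits$beta_diag != 0 & abs(fits$beta_diag) >= th
    data.frame(min_abs_beta = th, n = sum(use),
               prop_hyper = if (any(use))
                 sum(fits$beta_diag[use] > 0) / sum(use) else NA_real_)
  })
  do.call(rbind, rows)
}
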