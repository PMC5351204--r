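# Core containers. Sites are rows, samples are columns, matching the layout
# of methylKit-style objects. A masked (filtered) entry is NA in *both* the
# coverage and methylated slots; masks always propagate jointly.

#' Construct a CountMatrix
#'
#' Per-site, per-sample read coverage and methylated-read counts, the raw
#' substrate of the pipeline. Masked entries are `NA` in both slots.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos` (1-based
#'   cytosine position), `strand` (`"+"`/`"-"`), `context` (`"CpG"`/`"CpH"`).
#' @param samples character vector of sample ids (column order).
#' @param coverage,methylated numeric matrices, sites x samples.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(sites, samples, coverage, methylated) {
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos", "strand", "context") %in%
                  names(sites)),
            nrow(coverage) == nrow(sites),
            ncol(coverage) == length(samples),
            identical(dim(coverage), dim(methylated)))
  if (anyDuplicated(sites[c("chrom", "pos", "strand")]))
    stop("duplicate (chrom, pos, strand) in site table")
  na_mask <- is.na(coverage)
  if (!identical(na_mask, is.na(methylated)))
    stop("coverage and methylated masks disagree")
  ok <- !na_mask
  if (any(methylated[ok] > coverage[ok]))
    stop("methylated counts exceed coverage")
  if (any(methylated[ok] < 0) || any(coverage[ok] < 0))
    stop("negative counts")
  storage.mode(coverage) <- storage.mode(methylated) <- "double"
  dimnames(coverage) <- dimnames(methylated) <- list(sites$site_id, samples)
  structure(list(sites = sites, samples = samples,
                 coverage = coverage, methylated = methylated),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d sites x %d samples (%.1f%% masked)\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$coverage))))
  cat(sprintf("  contexts: %s\n",
              paste(sprintf("%s=%d", names(table(x$sites$context)),
                            table(x$sites$context)), collapse = ", ")))
  invisible(x)
}

#' Construct a MethylationMatrix
#'
#' Percent-methylation values in \[0, 100\] with coverage retained alongside
#' for use as model weights. Masked entries are `NA` in both slots.
#'
#' @param sites site table (see [count_matrix()]).
#' @param samples character vector of sample ids.
#' @param meth_pct numeric matrix of percentages, sites x samples.
#' @param coverage numeric matrix of read coverage, sites x samples.
#' @return An object of class `MethylationMatrix`.
#' @export
meth_matrix <- function(sites, samples, meth_pct, coverage) {
  stopifnot(nrow(meth_pct) == nrow(sites),
            ncol(meth_pct) == length(samples),
            identical(dim(meth_pct), dim(coverage)))
  ok <- !is.na(meth_pct)
  if (any(meth_pct[ok] < 0 | meth_pct[ok] > 100))
    stop("meth_pct outside [0, 100]")
  dimnames(meth_pct) <- dimnames(coverage) <- list(sites$site_id, samples)
  structure(list(sites = sites, samples = samples,
                 meth_pct = meth_pct, coverage = coverage),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d sites x %d samples (%.1f%% masked)\n",
              nrow(x$sites), length(x$samples), 100 * mean(is.na(x$meth_pct))))
  invisible(x)
}

#' Subset a CountMatrix / MethylationMatrix
#'
#' @param x a [count_matrix()] or [meth_matrix()].
#' @param i integer site indices to keep.
#' @return object of the same class.
#' @export
subset_sites <- function(x, i) {
  x$sites <- x$sites[i, , drop = FALSE]
  for (f in intersect(c("coverage", "methylated", "meth_pct"), names(x)))
    x[[f]] <- x[[f]][i, , drop = FALSE]
  x
}

#' @rdname subset_sites
#' @param keep character vector of sample ids to keep (in order).
#' @export
subset_samples <- function(x, keep) {
  j <- match(keep, x$samples)
  if (anyNA(j)) stop("unknown sample ids: ",
                     paste(keep[is.na(j)], collapse = ", "))
  x$samples <- x$samples[j]
  for (f in intersect(c("coverage", "methylated", "meth_pct"), names(x)))
    x[[f]] <- x[[f]][, j, drop = FALSE]
  x
}

# Order sites genomically (chrom then position then strand).
genomic_order <- function(sites) {
  order(sites$chrom, sites$pos, sites$strand)
}

#' Build a design matrix from a sample sheet
#'
#' Columns: intercept, diagnosis (case = 1), age, sex (M = 1), one indicator
#' per brain bank beyond the first, and optional surrogate variables.
#'
#' @param sheet sample sheet data.frame (`sample_id`, `diagnosis`, `age`,
#'   `sex`, `bank`).
#' @param svs optional samples x k matrix of surrogate variables.
#' @param include_diagnosis if `FALSE`, the null design (diagnosis dropped).
#' @return numeric matrix, samples x columns; diagnosis column is named
#'   `"diagnosis"`.
#' @export
build_design <- function(sheet, svs = NULL, include_diagnosis = TRUE) {
  stopifnot(all(c("sample_id", "diagnosis", "age", "sex", "bank") %in%
                  names(sheet)))
  if (anyNA(sheet[c("diagnosis", "age", "sex", "bank")]))
    stop("sample sheet has missing covariates")
  X <- cbind(`(Intercept)` = 1,
             diagnosis = as.numeric(sheet$diagnosis == "case"),
             age = as.numeric(sheet$age),
             sexM = as.numeric(sheet$sex == "M"))
  banks <- sort(unique(sheet$bank))
  if (length(banks) > 1)
    for (b in banks[-1])
      X <- cbind(X, as.numeric(sheet$bank == b))
  colnames(X) <- c("(Intercept)", "diagnosis", "age", "sexM",
                   if (length(banks) > 1) paste0("bank", banks[-1]))
  if (!is.null(svs)) {
    svs <- as.matrix(svs)
    colnames(svs) <- paste0("SV", seq_len(ncol(svs)))
    X <- cbind(X, svs)
  }
  rownames(X) <- sheet$sample_id
  if (!include_diagnosis) X <- X[, colnames(X) != "diagnosis", drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}
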