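# Fisher-exact enrichment of hypermethylated sites within functional genomic
# categories, plus the interval utilities the category lists need. Intervals
# are 0-based half-open; a cytosine at 1-based position p overlaps (s, e)
# iff s <= p - 1 < e.

#' Flanking windows around beacon CpGs
#'
#' Each CpG at 1-based position `p` yields the half-open 0-based interval
#' `(p - 1 - flank/2, p + 1 + flank/2)` (default: 200 bp total, +/-100 bp),
#' clipped at 0. Set `per_side = TRUE` to read "flank" as bp on each side.
#'
#' @param chrom,pos beacon CpG coordinates (1-based).
#' @param flank window in bp (default 200, total).
#' @param per_side if `TRUE`, `flank` bp on each side.
#' @param name category name.
#' @return An [annotation_category()].
#' @export
flank_beacons <- function(chrom, pos, flank = 200, per_side = FALSE,
                          name = "beacons") {
  half <- if (per_side) flank else flank / 2
  annotation_category(name, data.frame(
    chrom = chrom,
    start = pmax(0, as.integer(pos - 1 - half)),
    end = as.integer(pos + 1 + half),
    stringsAsFactors = FALSE))
}

.to_iranges <- function(intervals) {
  # half-open (start, end) -> IRanges closed [start+1, end]
  split(IRanges::IRanges(start = intervals$start + 1L,
                         end = intervals$end),
        intervals$chrom)
}

.from_iranges <- function(irl, name) {
  rows <- lapply(names(irl), function(ch) {
    ir <- irl[[ch]]
    if (length(ir) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  iv <- do.call(rbind, rows)
  if (is.null(iv))
    iv <- data.frame(chrom = character(), start = integer(),
                     end = integer())
  annotation_category(name, iv[order(iv$chrom, iv$start), ])
}

#' Intersect replicate interval sets
#'
#' Genomic intersection: positions covered by every input set, emitted as
#' maximal disjoint intervals. Used to combine histone-mark tracks from
#' multiple individuals into one consensus category.
#'
#' @param categories list of [annotation_category()] objects (>= 1).
#' @param name name of the result (default: names joined).
#' @return An [annotation_category()].
#' @export
intersect_replicates <- function(categories, name = NULL) {
  stopifnot(length(categories) >= 1)
  name <- name %||% paste(vapply(categories, `[[`, "", "name"),
                          collapse = "&")
  acc <- lapply(.to_iranges(categories[[1]]$intervals), IRanges::reduce)
  for (cat in categories[-1]) {
    cur <- lapply(.to_iranges(cat$intervals), IRanges::reduce)
    chroms <- intersect(names(acc), names(cur))
    acc <- setNames(lapply(chroms, function(ch)
      IRanges::intersect(acc[[ch]], cur[[ch]])), chroms)
  }
  acc <- acc[vapply(acc, length, 1L) > 0]
  .from_iranges(acc, name)
}

#' Flag sites falling inside a category
#'
#' A site at 1-based position `p` is in-category iff some interval `(s, e)`
#' of the category satisfies `s <= p - 1 < e`.
#'
#' @param sites site table (`chrom`, `pos`).
#' @param category an [annotation_category()].
#' @return logical vector, one per site.
#' @export
annotate_sites <- function(sites, category) {
  iv <- category$intervals
  unmatched <- setdiff(unique(iv$chrom), unique(sites$chrom))
  if (length(unmatched))
    warning("category chromosomes absent from sites: ",
            paste(unmatched, collapse = ", "))
  out <- logical(nrow(sites))
  for (ch in intersect(unique(sites$chrom), unique(iv$chrom))) {
    si <- which(sites$chrom == ch)
    ivc <- iv[iv$chrom == ch, ]
    q <- IRanges::IRanges(start = sites$pos[si], width = 1L)
    s <- IRanges::IRanges(start = ivc$start + 1L, end = ivc$end)
    out[si] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Two-sided Fisher exact test (hypergeometric enumeration)
#'
#' Exact two-sided p: the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's (with a relative tolerance for floating-point ties).
#'
#' @param a,b,c,d 2x2 counts.
#' @return list with `odds_ratio` (`a*d / (b*c)`, `NA` on an empty margin)
#'   and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m == 0 || n == 0 || k == 0 || b + d == 0)
    return(list(odds_ratio = NA_real_, p = 1))
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  or <- if (b * c > 0) (a * d) / (b * c) else NA_real_
  list(odds_ratio = or, p = p)
}

#' Enrichment of hypermethylated sites in a category
#'
#' Builds the 2x2 table over all tested sites -- hypermethylated
#' (`p < cutoff` and positive coefficient) vs not, in-category vs not -- and
#' applies the two-sided Fisher exact test. The background is the set of all
#' tested sites.
#'
#' @param fits [fit_site_models()] output.
#' @param membership logical per-site category membership
#'   ([annotate_sites()]).
#' @param cutoff nominal p-value cutoff for calling a site hypermethylated.
#' @param name category name carried into the result.
#' @return one-row data.frame (`EnrichmentResult`): `category`, `cutoff`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `flagged` (empty margin).
#' @export
fisher_enrichment <- function(fits, membership, cutoff, name = "category") {
  stopifnot(length(membership) == nrow(fits))
  tested <- !is.na(fits$p) & !is.na(fits$beta_diag)
  hyper <- tested & fits$p < cutoff & fits$beta_diag > 0
  a <- sum(hyper & membership)
  b <- sum(hyper & !membership)
  cc <- sum(tested & !hyper & membership)
  d <- sum(tested & !hyper & !membership)
  ft <- fisher_exact_2x2(a, b, cc, d)
  data.frame(category = name, cutoff = cutoff, a = a, b = b, c = cc, d = d,
             odds_ratio = ft$odds_ratio, p = ft$p,
             flagged = is.na(ft$odds_ratio), stringsAsFactors = FALSE)
}

#' Enrichment across categories and cutoffs
#'
#' @param fits [fit_site_models()] output.
#' @param sites site table aligned with `fits`.
#' @param categories list of [annotation_category()] objects.
#' @param cutoffs p-value cutoffs (default `c(0.05, 5e-3, 5e-4)`).
#' @return data.frame, one row per category x cutoff.
#' @export
enrichment_scan <- function(fits, sites, categories,
                            cutoffs = c(0.05, 5e-3, 5e-4)) {
  rows <- list()
  for (cat in categories) {
    memb <- annotate_sites(sites, cat)
    for (co in cutoffs)
      rows[[length(rows) + 1]] <- fisher_enrichment(fits, memb, co,
                                                    name = cat$name)
  }
  do.call(rbind, rows)
}
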