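# Readers and writers for the plain-text formats the pipeline touches.
# Cytosine positions are 1-based throughout; BED intervals are 0-based
# half-open, preserved exactly as read. All readers and writers are
# gzip-transparent (R connections).

open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a per-sample cytosine methylation report
#'
#' Two dialects are supported. `cytosine_report` has columns `chrBase`,
#' `chr`, `base`, `strand`, `coverage`, `freqC`, `freqT` (percent methylated /
#' unmethylated; header line present); the methylated count is
#' `round(coverage * freqC / 100)`. `bismark_coverage` has columns chrom,
#' start, end, methylation%, count-methylated, count-unmethylated (no
#' header).
#'
#' @param path file path (plain or gzipped).
#' @param dialect `"cytosine_report"` or `"bismark_coverage"`.
#' @return data.frame with columns `chrom`, `pos`, `strand`, `coverage`,
#'   `methylated`.
#' @export
read_cytosine_report <- function(path,
                                 dialect = c("cytosine_report",
                                             "bismark_coverage")) {
  dialect <- match.arg(dialect)
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  header_offset <- 0L
  if (dialect == "cytosine_report" && length(lines) > 0 &&
      grepl("^chrBase", lines[1])) {
    lines <- lines[-1]
    header_offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty cytosine report: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), coverage = numeric(),
                      methylated = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (dialect == "cytosine_report") 7L else 6L
  nf <- lengths(fields)
  if (any(nf != want))
    stop(sprintf("malformed line %d in %s: expected %d fields, got %d",
                 which(nf != want)[1] + header_offset, path, want,
                 nf[nf != want][1]))
  m <- do.call(rbind, fields)
  if (dialect == "cytosine_report") {
    out <- data.frame(chrom = m[, 2], pos = as.integer(m[, 3]),
                      strand = m[, 4], coverage = as.numeric(m[, 5]),
                      methylated = round(as.numeric(m[, 5]) *
                                           as.numeric(m[, 6]) / 100),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                      strand = "*", coverage = as.numeric(m[, 5]) +
                        as.numeric(m[, 6]),
                      methylated = as.numeric(m[, 5]),
                      stringsAsFactors = FALSE)
  }
  if (anyNA(out$pos) || anyNA(out$coverage))
    stop("malformed line ",
         which(is.na(out$pos) | is.na(out$coverage))[1] + header_offset,
         " in ", path, ": non-numeric field")
  bad <- which(out$methylated > out$coverage | out$methylated < 0 |
                 out$coverage < 0)
  if (length(bad))
    stop("line ", bad[1] + header_offset, " in ", path,
         ": methylated count exceeds coverage or is negative")
  out
}

#' Write a per-sample cytosine report
#'
#' @param counts a [count_matrix()].
#' @param sample sample id to export.
#' @param path output path (`.gz` for gzip).
#' @param dialect see [read_cytosine_report()].
#' @export
write_cytosine_report <- function(counts, sample, path,
                                  dialect = c("cytosine_report",
                                              "bismark_coverage")) {
  dialect <- match.arg(dialect)
  j <- match(sample, counts$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  keep <- !is.na(counts$coverage[, j])
  s <- counts$sites[keep, ]
  cov <- counts$coverage[keep, j]
  met <- counts$methylated[keep, j]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (dialect == "cytosine_report") {
    writeLines("chrBase\tchr\tbase\tstrand\tcoverage\tfreqC\tfreqT", con)
    freqC <- 100 * met / cov
    writeLines(sprintf("%s\t%s\t%d\t%s\t%g\t%.6f\t%.6f",
                       paste0(s$chrom, ".", s$pos), s$chrom, s$pos, s$strand,
                       cov, freqC, 100 - freqC), con)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%.6f\t%g\t%g", s$chrom, s$pos, s$pos,
                       100 * met / cov, met, cov - met), con)
  }
  invisible(path)
}

#' Read a BED file into an annotation category
#'
#' BED3+ with 0-based half-open intervals; columns beyond the third are
#' ignored. Intervals may overlap within a category.
#'
#' @param path BED file path.
#' @param name category name; defaults to the file name without extension.
#' @return An `AnnotationCategory`: list with `name` and `intervals`
#'   (data.frame `chrom`, `start`, `end`).
#' @export
read_bed <- function(path, name = NULL) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(annotation_category(name %||% basename(path),
                               data.frame(chrom = character(),
                                          start = integer(),
                                          end = integer())))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], " in ", path,
         ": fewer than 3 columns")
  m <- t(vapply(fields, function(f) f[1:3], character(3)))
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("malformed BED line ", bad[1], " in ", path,
         ": start must be < end")
  annotation_category(name %||% sub("\\.(bed|bed\\.gz)$", "", basename(path)),
                      data.frame(chrom = m[, 1], start = start, end = end,
                                 stringsAsFactors = FALSE))
}

#' Construct an annotation category
#'
#' @param name category name.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return An `AnnotationCategory`.
#' @export
annotation_category <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("interval start must be < end")
  structure(list(name = name,
                 intervals = intervals[c("chrom", "start", "end")]),
            class = "AnnotationCategory")
}

#' Write an annotation category (or DMRs) as BED
#'
#' @param x an `AnnotationCategory` or a data.frame with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  iv <- if (inherits(x, "AnnotationCategory")) x$intervals else x
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(iv) > 0)
    writeLines(sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start),
                       as.integer(iv$end)), con)
  else writeLines(character(0), con)
  invisible(path)
}

#' Read / write a sample sheet (CSV)
#'
#' Columns `sample_id`, `diagnosis` (`case`/`control`), `age`, `sex`
#' (`M`/`F`), `bank`.
#'
#' @param path CSV path.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "diagnosis", "age", "sex", "bank")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(sheet[need])) stop("sample sheet has missing values")
  if (!all(sheet$diagnosis %in% c("case", "control")))
    stop("diagnosis must be 'case' or 'control'")
  sheet
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read ground truth as JSON
#'
#' Lossless round trip of the generator's `GroundTruth` record.
#'
#' @param truth GroundTruth list from [simulate_dataset()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  for (f in c("confounder_loadings", "confounder_scores"))
    if (!is.null(out[[f]]))
      out[[f]] <- list(rownames = rownames(out[[f]]),
                       colnames = colnames(out[[f]]),
                       values = unname(out[[f]]))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("confounder_loadings", "confounder_scores"))
    if (!is.null(x[[f]])) {
      m <- as.matrix(x[[f]]$values)
      dimnames(m) <- list(x[[f]]$rownames, x[[f]]$colnames)
      x[[f]] <- m
    }
  for (f in c("effect_sites", "planted_dmrs", "outlier_samples"))
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  x
}

#' Write analysis result tables
#'
#' Per-site fit results and enrichment results as TSV with header; DMRs as
#' BED3 plus a TSV sidecar carrying `value`, `n_sites`, `length_bp`, `fwer`.
#'
#' @param site_fits per-site results data.frame (or NULL).
#' @param dmrs DMR data.frame (or NULL).
#' @param enrichment enrichment data.frame (or NULL).
#' @param out_dir output directory, created if needed.
#' @return invisible character vector of files written.
#' @export
write_results <- function(site_fits = NULL, dmrs = NULL, enrichment = NULL,
                          out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  tsv <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(site_fits)) written <- c(written, tsv(site_fits, "site_fits.tsv"))
  if (!is.null(dmrs)) {
    bed <- file.path(out_dir, "dmrs.bed")
    write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                         end = dmrs$end), bed)
    written <- c(written, bed, tsv(dmrs, "dmrs.tsv"))
  }
  if (!is.null(enrichment))
    written <- c(written, tsv(enrichment, "enrichment.tsv"))
  invisible(written)
}

#' Read a TSV written by [write_results()]
#' @param path TSV path.
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Assemble a CountMatrix from per-sample cytosine reports
#'
#' Sites absent from a sample's report are masked (`NA`) for that sample.
#'
#' @param paths named character vector (names = sample ids) of report paths.
#' @param dialect see [read_cytosine_report()].
#' @param context context label to assign to all sites (the two contexts are
#'   analyzed separately, one file set per context).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(paths, dialect = "cytosine_report",
                              context = "CpG") {
  stopifnot(!is.null(names(paths)))
  per <- lapply(paths, read_cytosine_report, dialect = dialect)
  key <- unique(do.call(rbind, lapply(per, function(d)
    d[c("chrom", "pos", "strand")])))
  key <- key[order(key$chrom, key$pos, key$strand), ]
  id <- paste0(key$chrom, ".", key$pos)
  cov <- met <- matrix(NA_real_, nrow(key), length(paths),
                       dimnames = list(id, names(paths)))
  for (j in seq_along(per)) {
    d <- per[[j]]
    i <- match(paste(d$chrom, d$pos, d$strand),
               paste(key$chrom, key$pos, key$strand))
    cov[i, j] <- d$coverage
    met[i, j] <- d$methylated
  }
  sites <- data.frame(site_id = id, chrom = key$chrom, pos = key$pos,
                      strand = key$strand, context = context,
                      stringsAsFactors = FALSE)
  count_matrix(sites, names(paths), cov, met)
}
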