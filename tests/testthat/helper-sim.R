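# Shared fixtures, all generated in code. `small_sim()` is memoized so test
# files reuse one dataset where the exact configuration does not matter.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

small_config <- function(...) {
  defaults <- list(n_cpg_sites = 300, n_cph_sites = 900, effect_fraction = 0,
                   n_confounders = 0, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

small_sim <- function() memo("small_sim", simulate_dataset(small_config()))

small_meth <- function() memo("small_meth", {
  sim <- small_sim()
  percent_methylation(unite_sites(filter_coverage(sim$counts),
                                  sim$sample_sheet))
})

# hand-built toy containers for exact-arithmetic tests
toy_counts <- function(coverage, methylated, contexts = NULL,
                       chrom = NULL, pos = NULL) {
  m <- nrow(coverage); n <- ncol(coverage)
  chrom <- chrom %||% rep("chr1", m)
  pos <- pos %||% seq(100, by = 100, length.out = m)
  sites <- data.frame(site_id = paste0(chrom, ".", pos), chrom = chrom,
                      pos = pos, strand = "+",
                      context = contexts %||% rep("CpG", m),
                      stringsAsFactors = FALSE)
  count_matrix(sites, sprintf("S%02d", seq_len(n)), coverage, methylated)
}

toy_meth <- function(meth_pct, coverage = NULL, contexts = NULL) {
  m <- nrow(meth_pct); n <- ncol(meth_pct)
  coverage <- coverage %||% matrix(100, m, n)
  coverage[is.na(meth_pct)] <- NA
  sites <- data.frame(site_id = paste0("chr1.", seq(100, by = 100,
                                                    length.out = m)),
                      chrom = "chr1", pos = seq(100, by = 100,
                                                length.out = m),
                      strand = "+", context = contexts %||% rep("CpG", m),
                      stringsAsFactors = FALSE)
  meth_matrix(sites, sprintf("S%02d", seq_len(n)), meth_pct, coverage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_null_fits <- function() memo("small_null_fits", {
  fit_site_models(small_meth(), build_design(small_sim()$sample_sheet))
})

# design with named diagnosis column from a bare case indicator
toy_design <- function(case, covars = NULL) {
  X <- cbind(`(Intercept)` = 1, diagnosis = as.numeric(case))
  if (!is.null(covars)) X <- cbind(X, covars)
  X
}
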