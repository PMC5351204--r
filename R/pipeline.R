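# End-to-end orchestration: simulate (or ingest) -> library QC -> coverage
# filters and normalization -> SV outlier removal -> per-site fits ->
# residual bootstrap -> global shift test -> DMRs -> enrichment, with one
# seed feeding every stage and a run log mirroring the bookkeeping of a real
# study (samples in -> QC-removed -> analyzed).

#' Pipeline configuration
#'
#' All thresholds default to the values the analysis is designed around:
#' coverage >= 10x with a 99.9th-percentile upper filter, sites united
#' across >= 20 cases and >= 20 controls (>= 5 reads and 20/20 for the DMR
#' branch), the 25% least variable sites dropped, 3-SD site outlier masking,
#' 4-SD iterative SV outlier removal with k = 10 SVs, B = 1000 bootstraps,
#' global-test cutoffs 0.05 / 5e-3 / 5e-4, DMR maxgap 300 with 24-test
#' correction, alpha 0.05.
#'
#' @param sim a [simulation_config()], or NULL when `counts` are supplied to
#'   [run_pipeline()] directly.
#' @param min_cov,upper_pctile coverage filters.
#' @param min_cases,min_controls site-level group coverage thresholds.
#' @param dmr_min_cov,dmr_min_cases,dmr_min_controls relaxed DMR-branch
#'   thresholds.
#' @param drop_fraction least-variable site filter.
#' @param site_z,sv_z outlier SD multiples.
#' @param k number of surrogate variables.
#' @param B bootstraps.
#' @param cutoffs global-test p-value cutoffs.
#' @param maxgap,dmr_quantile,dmr_window,dmr_min_sites DMR parameters.
#' @param n_tests,alpha DMR correction and level.
#' @param run_dmr,run_sva logical stage switches.
#' @param seed integer seed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            min_cov = 10, upper_pctile = 99.9,
                            min_cases = 20, min_controls = 20,
                            dmr_min_cov = 5, dmr_min_cases = 20,
                            dmr_min_controls = 20,
                            drop_fraction = 0.25, site_z = 3, sv_z = 4,
                            k = 10, B = 1000,
                            cutoffs = c(0.05, 5e-3, 5e-4),
                            maxgap = 300, dmr_quantile = 0.99,
                            dmr_window = 5, dmr_min_sites = 7,
                            n_tests = 24, alpha = 0.05,
                            run_dmr = TRUE, run_sva = TRUE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(min_cov >= 1, upper_pctile > 0, upper_pctile <= 100,
            min_cases >= 0, min_controls >= 0, drop_fraction >= 0,
            drop_fraction < 1, site_z > 0, sv_z > 0, k >= 1, B >= 1,
            all(cutoffs > 0), maxgap >= 0, n_tests >= 1, alpha > 0,
            alpha < 1)
  structure(cfg, class = "PipelineConfig")
}

log_line <- function(log, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  c(log, msg)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param counts optional [count_matrix()] (skips simulation).
#' @param sheet sample sheet, required with `counts`.
#' @param categories optional list of [annotation_category()] for the
#'   enrichment stage.
#' @param out_dir optional output directory for result files.
#' @return list with `fits` (per context), `global` (global shift results),
#'   `significance`, `dmr`, `enrichment`, `svs`, `qc`, `log`, `truth` (when
#'   simulated).
#' @export
run_pipeline <- function(config, counts = NULL, sheet = NULL,
                         categories = NULL, out_dir = NULL) {
  log <- character()
  truth <- NULL
  if (is.null(counts)) {
    sim <- simulate_dataset(config$sim)
    counts <- sim$counts; sheet <- sim$sample_sheet; truth <- sim$truth
    log <- log_line(log, "simulated %d sites x %d samples (seed %d)",
                    nrow(counts$sites), length(counts$samples),
                    config$sim$seed)
  }
  stopifnot(!is.null(sheet))
  n_in <- length(counts$samples)

  # --- sample-level library QC -------------------------------------------
  qc <- sample_qc(counts)
  keep <- qc$sample_id[!qc$flagged]
  log <- log_line(log, "library QC: %d samples in, %d flagged, %d kept",
                  n_in, sum(qc$flagged), length(keep))
  counts <- subset_samples(counts, keep)
  sheet1 <- sheet[match(keep, sheet$sample_id), ]

  # --- coverage filtering / normalization / uniting ----------------------
  filt <- filter_coverage(counts, config$min_cov, config$upper_pctile)
  norm <- normalize_coverage(filt)
  united <- unite_sites(norm, sheet1, config$min_cases, config$min_controls)
  log <- log_line(log, "site filter: %d sites in, %d united (>=%dx, %d/%d)",
                  nrow(counts$sites), nrow(united$sites), config$min_cov,
                  config$min_cases, config$min_controls)
  meth_all <- percent_methylation(united)

  # --- iterative SV outlier removal --------------------------------------
  if (config$run_sva) {
    svout <- detect_sv_outliers(meth_all, sheet1, z_thresh = config$sv_z,
                                k = config$k)
    log <- log_line(log, "SV outlier removal: %d removed over %d round(s)",
                    nrow(svout$log), max(c(0, svout$log$round)))
    meth_all <- subset_samples(meth_all, svout$kept)
    sheet1 <- sheet1[match(svout$kept, sheet1$sample_id), ]
  } else svout <- list(kept = sheet1$sample_id,
                       log = data.frame(round = integer(),
                                        sample_id = character()))
  log <- log_line(log, "analyzed samples: %d (%d cases / %d controls)",
                  nrow(sheet1), sum(sheet1$diagnosis == "case"),
                  sum(sheet1$diagnosis == "control"))

  # --- per-context single-site analysis ----------------------------------
  contexts <- intersect(c("CpG", "CpH"), unique(meth_all$sites$context))
  fits <- list(); nulls <- list(); global <- list(); signif <- list()
  svs <- NULL
  for (ctx in contexts) {
    meth <- subset_sites(meth_all, which(meth_all$sites$context == ctx))
    meth <- drop_invariant_sites(meth, config$drop_fraction)
    meth <- mask_site_outliers(meth, config$site_z)
    if (config$run_sva) {
      sv <- estimate_svs(meth, build_design(sheet1), k = config$k)
      if (ctx == contexts[1]) svs <- sv
      design <- build_design(sheet1, svs = sv$sv)
    } else design <- build_design(sheet1)
    fits[[ctx]] <- fit_site_models(meth, design)
    nulls[[ctx]] <- residual_bootstrap(meth, design, B = config$B,
                                       seed = config$seed + match(ctx, contexts))
    signif[[ctx]] <- empirical_significance(fits[[ctx]], nulls[[ctx]],
                                            config$alpha)
    global[[ctx]] <- global_shift_test(fits[[ctx]], nulls[[ctx]],
                                       config$cutoffs)
    log <- log_line(log,
                    "%s: %d sites fit; %d study-wide significant; prop_hyper@0.05 = %.3f (emp p = %.4g)",
                    ctx, nrow(fits[[ctx]]),
                    sum(signif[[ctx]]$table$significant),
                    global[[ctx]]$prop_hyper[1],
                    global[[ctx]]$empirical_p[1])
  }

  # --- DMR branch (relaxed coverage) --------------------------------------
  dmr <- NULL
  if (config$run_dmr) {
    dfilt <- filter_coverage(counts, config$dmr_min_cov, config$upper_pctile)
    dfilt <- subset_samples(dfilt, sheet1$sample_id)
    dun <- unite_sites(dfilt, sheet1, config$dmr_min_cases,
                       config$dmr_min_controls)
    dmeth <- percent_methylation(dun)
    design <- if (config$run_sva && !is.null(svs))
      build_design(sheet1, svs = svs$sv) else build_design(sheet1)
    dmr <- run_dmr(dmeth, design, maxgap = config$maxgap,
                   window = config$dmr_window,
                   min_sites = config$dmr_min_sites,
                   quantile = config$dmr_quantile, B = config$B,
                   seed = config$seed + 100L)
    dmr$regions <- dmr_significance(dmr$regions, config$n_tests,
                                    config$alpha)
    log <- log_line(log, "DMR: %d candidate regions, %d significant (fwer < %.4g)",
                    nrow(dmr$regions), sum(dmr$regions$significant),
                    attr(dmr$regions, "threshold"))
  }

  # --- enrichment ---------------------------------------------------------
  enr <- NULL
  if (!is.null(categories) && "CpH" %in% names(fits)) {
    ctx_sites <- subset_sites(meth_all,
                              which(meth_all$sites$context == "CpH"))$sites
    ctx_sites <- ctx_sites[match(fits$CpH$site_id, ctx_sites$site_id), ]
    enr <- enrichment_scan(fits$CpH, ctx_sites, categories, config$cutoffs)
    log <- log_line(log, "enrichment: %d categories x %d cutoffs",
                    length(categories), length(config$cutoffs))
  }

  bundle <- list(fits = fits, nulls = nulls, significance = signif,
                 global = global, dmr = dmr, enrichment = enr, svs = svs,
                 qc = qc, sv_outliers = svout, sheet = sheet1, log = log,
                 truth = truth)
  if (!is.null(out_dir)) {
    allfits <- do.call(rbind, Map(function(f, ctx)
      cbind(context = ctx, f), fits, names(fits)))
    gl <- do.call(rbind, Map(function(g, ctx) cbind(context = ctx,
                                                    as.data.frame(g)),
                             global, names(global)))
    write_results(site_fits = allfits,
                  dmrs = if (!is.null(dmr)) dmr$regions,
                  enrichment = enr, out_dir = out_dir)
    utils::write.table(gl, file.path(out_dir, "global_shift.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  bundle
}
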