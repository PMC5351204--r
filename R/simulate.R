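# Synthetic RRBS generator. The defaults are the conditions of the study the
# pipeline is designed for, scaled down ~500x in site count: 29 cases / 34
# controls, bimodal CpG methylation averaging ~21.2%, CpH methylation
# averaging ~1.7%, negative-binomial coverage (variance ~3x mean), and
# case-only CpH hypermethylation with a median shift of ~1.8 percentage
# points at 30% of CpH sites.

#' Configuration for the synthetic RRBS generator
#'
#' @param n_cases,n_controls group sizes (default 29 / 34).
#' @param n_cpg_sites,n_cph_sites site counts (defaults 2000 / 6600 keep the
#'   ~1:3.3 CpG:CpH ratio of a genome-scale RRBS run at 1/500 scale).
#' @param coverage_mean mean read coverage per site and sample.
#' @param coverage_dispersion variance-to-mean ratio of coverage (negative
#'   binomial; 3 means variance = 3 x mean).
#' @param cpg_bimodal_params list with `w_low` (mixture weight on the
#'   low-methylation mode) and `low`/`high` beta parameter pairs. Defaults
#'   give a marginal mean of ~21.2% methylation.
#' @param cph_baseline_params beta parameters for CpH baselines; default mean
#'   ~1.7%.
#' @param effect_fraction fraction of CpH sites given a case-only
#'   hypermethylation effect.
#' @param effect_median_shift median planted shift in percentage points.
#' @param n_confounders number of latent sample-level confounders.
#' @param confounder_sd scale of confounder loadings on the logit scale.
#' @param qc_failure_modes named list mapping mode
#'   (`hypermethylated`, `non_bimodal`, `coverage_aberrant`) to the number of
#'   control samples to corrupt; applied by [inject_qc_failures()].
#' @param chrom_layout named numeric vector of chromosome lengths (bp).
#' @param n_dmrs,dmr_n_sites,dmr_shift planted DMRs: count, CpH sites per
#'   region (placed within ~1 kb), and shift in percentage points.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_cases = 29, n_controls = 34,
                              n_cpg_sites = 2000, n_cph_sites = 6600,
                              coverage_mean = 30, coverage_dispersion = 3,
                              cpg_bimodal_params = list(
                                w_low = 0.7, low = c(0.9, 29.1),
                                high = c(6.37, 3.63)),
                              cph_baseline_params = c(0.6, 34.7),
                              effect_fraction = 0.3,
                              effect_median_shift = 1.8,
                              n_confounders = 2, confounder_sd = 0.5,
                              qc_failure_modes = list(),
                              chrom_layout = c(chr1 = 3e6, chr2 = 3e6),
                              n_dmrs = 0, dmr_n_sites = 10, dmr_shift = 10,
                              seed = 1) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_cpg_sites = n_cpg_sites, n_cph_sites = n_cph_sites,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              cpg_bimodal_params = cpg_bimodal_params,
              cph_baseline_params = cph_baseline_params,
              effect_fraction = effect_fraction,
              effect_median_shift = effect_median_shift,
              n_confounders = n_confounders, confounder_sd = confounder_sd,
              qc_failure_modes = qc_failure_modes,
              chrom_layout = chrom_layout,
              n_dmrs = n_dmrs, dmr_n_sites = dmr_n_sites,
              dmr_shift = dmr_shift, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_cases > 0, n_controls > 0, n_cpg_sites > 0, n_cph_sites > 0,
              coverage_mean > 0, coverage_dispersion > 1,
              effect_fraction >= 0, effect_fraction <= 1,
              effect_median_shift >= 0,
              n_confounders >= 0, confounder_sd >= 0,
              all(cph_baseline_params > 0),
              all(cpg_bimodal_params$low > 0),
              all(cpg_bimodal_params$high > 0),
              cpg_bimodal_params$w_low >= 0, cpg_bimodal_params$w_low <= 1,
              all(chrom_layout > 0), length(names(chrom_layout)) > 0)
    if (effect_median_shift > 0 && effect_fraction > 0 &&
        floor(effect_fraction * n_cph_sites) < 1)
      stop("effect_fraction * n_cph_sites < 1: no room to plant effects")
    if (n_dmrs > 0 && dmr_n_sites < 3)
      stop("planted DMRs must contain at least 3 sites")
  })
  invisible(cfg)
}

# Expand one master seed into named per-stage substreams so stages are
# independently reproducible.
stage_seeds <- function(seed, stages) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Simulate an RRBS case-control dataset
#'
#' Coverage is negative binomial; methylated reads are binomial with a
#' per-site, per-sample success probability built on the logit scale:
#' `logit(pi) = logit(baseline) + case * effect + covariate effects +
#' confounder loadings`. Effects are planted on the logit scale so `pi`
#' stays in (0, 1) at any baseline; planted shift sizes are recorded in
#' percentage points in the returned ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a [count_matrix()]), `sample_sheet`
#'   (data.frame), and `truth` (GroundTruth: `effect_sites`, `planted_dmrs`,
#'   `confounder_loadings`, `outlier_samples`).
#' @export
simulate_dataset <- function(config) {
  validate_simulation_config(config)
  seeds <- stage_seeds(config$seed,
                       c("layout", "baseline", "covariates", "effects",
                         "counts", "qc"))

  # --- site layout -------------------------------------------------------
  set.seed(seeds[["layout"]])
  n_sites <- config$n_cpg_sites + config$n_cph_sites
  chroms <- names(config$chrom_layout)
  n_per <- as.vector(stats::rmultinom(1, n_sites,
                                      config$chrom_layout /
                                        sum(config$chrom_layout)))
  chrom <- rep(chroms, n_per)
  # RRBS sites are clumped: size-selected MspI fragments (~105-185 bp) carry
  # runs of cytosines, so positions are drawn per fragment, not uniformly
  pos <- unlist(lapply(seq_along(chroms), function(i) {
    p <- integer(0)
    while (length(p) < n_per[i]) {
      anchor <- sample.int(config$chrom_layout[i] - 2000L, 1L) + 1000L
      k <- min(3L + stats::rpois(1, 9), 150L)
      p <- c(p, anchor + sort(sample.int(180L, k)))
    }
    p <- unique(p)
    while (length(p) < n_per[i]) {
      anchor <- sample.int(config$chrom_layout[i] - 2000L, 1L) + 1000L
      p <- unique(c(p, anchor + sort(sample.int(180L, 10L))))
    }
    sort(sample(p, n_per[i]))
  }), use.names = FALSE)
  context <- rep("CpH", n_sites)
  context[sample.int(n_sites, config$n_cpg_sites)] <- "CpG"
  strand <- sample(c("+", "-"), n_sites, replace = TRUE)

  # planted DMRs: carve a ~1 kb window on the first chromosome and relocate
  # a run of CpH sites into it
  planted_dmrs <- data.frame(chrom = character(), start = integer(),
                             end = integer(), shift = numeric())
  dmr_site_idx <- integer()
  if (config$n_dmrs > 0) {
    cph_idx <- which(context == "CpH" & chrom == chroms[1])
    anchor <- seq(0.1, 0.9, length.out = config$n_dmrs) *
      config$chrom_layout[1]
    for (d in seq_len(config$n_dmrs)) {
      take <- cph_idx[seq_len(config$dmr_n_sites) +
                        (d - 1L) * config$dmr_n_sites]
      # tightly spaced sites (gaps 40-180 bp, ~1 kb span for 10 sites), as
      # in the CpG-dense regions RRBS enriches for
      new_pos <- as.integer(anchor[d]) +
        cumsum(c(0L, sample(40:180, config$dmr_n_sites - 1, replace = TRUE)))
      ord <- order(pos[take])
      pos[take[ord]] <- new_pos
      dmr_site_idx <- c(dmr_site_idx, take)
      planted_dmrs <- rbind(planted_dmrs,
                            data.frame(chrom = chroms[1],
                                       start = min(new_pos),
                                       end = max(new_pos),
                                       shift = config$dmr_shift))
    }
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; context <- context[ord]
  strand <- strand[ord]
  # relocated DMR sites can (rarely) collide with existing positions
  while (anyDuplicated(paste(chrom, pos, strand))) {
    dup <- duplicated(paste(chrom, pos, strand))
    pos[dup] <- pos[dup] + 1L
    o2 <- order(chrom, pos)
    chrom <- chrom[o2]; pos <- pos[o2]; context <- context[o2]
    strand <- strand[o2]; ord <- ord[o2]
  }
  dmr_site_idx <- match(dmr_site_idx, ord)
  sites <- data.frame(site_id = paste0(chrom, ".", pos), chrom = chrom,
                      pos = pos, strand = strand, context = context,
                      stringsAsFactors = FALSE)

  # --- baselines ---------------------------------------------------------
  set.seed(seeds[["baseline"]])
  base <- numeric(n_sites)
  is_cpg <- context == "CpG"
  bp <- config$cpg_bimodal_params
  lowmode <- runif(sum(is_cpg)) < bp$w_low
  base[is_cpg] <- ifelse(lowmode,
                         rbeta(sum(is_cpg), bp$low[1], bp$low[2]),
                         rbeta(sum(is_cpg), bp$high[1], bp$high[2]))
  base[!is_cpg] <- rbeta(sum(!is_cpg), config$cph_baseline_params[1],
                         config$cph_baseline_params[2])
  base <- pmin(pmax(base, 1e-4), 1 - 1e-4)

  # --- samples & covariates ---------------------------------------------
  set.seed(seeds[["covariates"]])
  n <- config$n_cases + config$n_controls
  sheet <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    diagnosis = rep(c("case", "control"),
                    c(config$n_cases, config$n_controls)),
    age = round(pmin(pmax(rnorm(n, 22, 13), 3), 65), 1),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25)),
    bank = sample(c("bankA", "bankB"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  # mild fixed covariate effects on the logit scale
  cov_eff <- 0.003 * (sheet$age - mean(sheet$age)) +
    0.05 * (sheet$sex == "M") + 0.08 * (sheet$bank == "bankB")
  conf_scores <- matrix(0, n, max(config$n_confounders, 1))
  loadings <- matrix(0, n_sites, max(config$n_confounders, 1))
  if (config$n_confounders > 0) {
    conf_scores <- matrix(rnorm(n * config$n_confounders), n)
    # each confounder loads on ~40% of sites
    loadings <- matrix(0, n_sites, config$n_confounders)
    for (k in seq_len(config$n_confounders)) {
      hit <- runif(n_sites) < 0.4
      loadings[hit, k] <- rnorm(sum(hit), 0, config$confounder_sd)
    }
  }

  # --- planted effects (case-only CpH hypermethylation) ------------------
  set.seed(seeds[["effects"]])
  shift_pp <- numeric(n_sites)
  cph_pool <- setdiff(which(!is_cpg), dmr_site_idx)
  n_eff <- floor(config$effect_fraction * config$n_cph_sites)
  eff_idx <- integer()
  if (n_eff >= 1 && config$effect_median_shift > 0) {
    eff_idx <- sort(sample(cph_pool, min(n_eff, length(cph_pool))))
    raw <- rgamma(length(eff_idx), shape = 4, rate = 4)
    shift_pp[eff_idx] <- config$effect_median_shift * raw /
      qgamma(0.5, shape = 4, rate = 4)
  }
  if (length(dmr_site_idx))
    shift_pp[dmr_site_idx] <- config$dmr_shift
  delta <- ifelse(shift_pp > 0,
                  qlogis(pmin(base + shift_pp / 100, 1 - 1e-4)) - qlogis(base),
                  0)

  # --- counts ------------------------------------------------------------
  set.seed(seeds[["counts"]])
  size <- config$coverage_mean / (config$coverage_dispersion - 1)
  coverage <- matrix(rnbinom(n_sites * n, mu = config$coverage_mean,
                             size = size), n_sites, n)
  is_case <- as.numeric(sheet$diagnosis == "case")
  eta <- outer(qlogis(base), rep(1, n)) + outer(delta, is_case) +
    outer(rep(1, n_sites), cov_eff) + loadings %*% t(conf_scores)
  pii <- plogis(eta)
  methylated <- matrix(rbinom(n_sites * n, size = coverage, prob = pii),
                       n_sites, n)

  counts <- count_matrix(sites, sheet$sample_id, coverage, methylated)

  truth <- list(
    effect_sites = data.frame(site_id = sites$site_id[eff_idx],
                              shift = shift_pp[eff_idx],
                              stringsAsFactors = FALSE),
    planted_dmrs = planted_dmrs,
    confounder_loadings = if (config$n_confounders > 0) {
      m <- loadings
      dimnames(m) <- list(sites$site_id,
                          paste0("conf", seq_len(ncol(m))))
      m
    } else NULL,
    confounder_scores = if (config$n_confounders > 0) {
      s <- conf_scores
      dimnames(s) <- list(sheet$sample_id, paste0("conf", seq_len(ncol(s))))
      s
    } else NULL,
    outlier_samples = data.frame(sample_id = character(),
                                 mode = character(),
                                 stringsAsFactors = FALSE))

  # QC failures requested in the config are applied to control samples at
  # the end of the sheet, and logged in the truth
  if (length(config$qc_failure_modes) > 0) {
    modes <- list()
    pool <- rev(sheet$sample_id[sheet$diagnosis == "control"])
    i <- 1
    for (mode in names(config$qc_failure_modes)) {
      k <- config$qc_failure_modes[[mode]]
      if (k > 0) {
        modes[[mode]] <- pool[seq(i, i + k - 1)]
        i <- i + k
      }
    }
    counts <- inject_qc_failures(counts, modes, seed = seeds[["qc"]])
    truth$outlier_samples <- data.frame(
      sample_id = unlist(modes, use.names = FALSE),
      mode = rep(names(modes), lengths(modes)),
      stringsAsFactors = FALSE)
  }

  list(counts = counts, sample_sheet = sheet, truth = truth)
}

#' Inject sample-level QC failure modes into a count matrix
#'
#' Emulates failed libraries: `hypermethylated` sets essentially all
#' cytosines of a sample to fully methylated (>99% of sites at methylated
#' fraction >= 0.99); `non_bimodal` replaces the sample's CpG methylation
#' with unimodal mid-range values; `coverage_aberrant` rescales the sample's
#' coverage to a heavy-tailed distribution.
#'
#' @param counts a [count_matrix()].
#' @param modes named list mapping mode name to a character vector of sample
#'   ids. Unknown mode names are an error.
#' @param seed integer seed.
#' @return The modified `CountMatrix`.
#' @export
inject_qc_failures <- function(counts, modes, seed = 1) {
  known <- c("hypermethylated", "non_bimodal", "coverage_aberrant")
  if (length(modes) == 0) return(counts)
  bad <- setdiff(names(modes), known)
  if (length(bad)) stop("unknown QC failure mode(s): ",
                        paste(bad, collapse = ", "))
  miss <- setdiff(unlist(modes), counts$samples)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  set.seed(seed)
  cov <- counts$coverage; met <- counts$methylated
  for (s in modes$hypermethylated %||% character()) {
    j <- match(s, counts$samples)
    ok <- which(!is.na(cov[, j]))
    hit <- ok[runif(length(ok)) < 0.998]  # >99% of sites fully methylated
    met[hit, j] <- cov[hit, j]
  }
  for (s in modes$non_bimodal %||% character()) {
    j <- match(s, counts$samples)
    i <- which(counts$sites$context == "CpG" & !is.na(cov[, j]))
    met[i, j] <- rbinom(length(i), size = cov[i, j],
                        prob = rbeta(length(i), 5, 5))
  }
  for (s in modes$coverage_aberrant %||% character()) {
    j <- match(s, counts$samples)
    ok <- which(!is.na(cov[, j]))
    frac <- met[ok, j] / pmax(cov[ok, j], 1)
    newcov <- pmax(1, round(cov[ok, j] * rlnorm(length(ok), 1.2, 1)))
    cov[ok, j] <- newcov
    met[ok, j] <- pmin(round(frac * newcov), newcov)
  }
  count_matrix(counts$sites, counts$samples, cov, met)
}

#' Simulate genotype dosages with planted cis-meQTLs
#'
#' Dosages are drawn under Hardy-Weinberg equilibrium at allele frequencies
#' uniform in \[0.05, 0.5\]. Each planted meQTL links a SNP (placed within
#' 1 Mb of its site) to a CpG/CpH site whose methylated fraction is shifted
#' additively per alternate allele.
#'
#' @param counts a [count_matrix()]; returned with meQTL shifts applied.
#' @param n_snps total SNPs to simulate.
#' @param meqtl_pairs number of planted SNP-site pairs (<= `n_snps`).
#' @param shift_pp additive methylation shift per allele, percentage points.
#' @param seed integer seed.
#' @return list with `genotypes` (samples x SNPs dosage matrix), `snp_info`
#'   (data.frame `snp_id`, `chrom`, `pos`), `known_meqtls` (data.frame
#'   `snp_id`, `site_id`, `shift`), and the modified `counts`.
#' @export
simulate_genotypes <- function(counts, n_snps, meqtl_pairs, shift_pp = 10,
                               seed = 1) {
  stopifnot(n_snps >= meqtl_pairs, meqtl_pairs >= 0)
  set.seed(seed)
  n <- length(counts$samples)
  maf <- runif(n_snps, 0.05, 0.5)
  G <- vapply(maf, function(f) rbinom(n, 2, f), numeric(n))
  dimnames(G) <- list(counts$samples, sprintf("snp%04d", seq_len(n_snps)))

  sites <- counts$sites
  snp_chrom <- sample(sites$chrom, n_snps, replace = TRUE)
  snp_pos <- vapply(snp_chrom, function(ch)
    sample(sites$pos[sites$chrom == ch], 1) +
      sample(-5e5:5e5, 1), numeric(1))
  snp_pos <- pmax(1, round(snp_pos))

  known <- data.frame(snp_id = character(), site_id = character(),
                      shift = numeric(), stringsAsFactors = FALSE)
  if (meqtl_pairs > 0) {
    link_site <- sample.int(nrow(sites), meqtl_pairs)
    for (k in seq_len(meqtl_pairs)) {
      i <- link_site[k]
      snp_chrom[k] <- sites$chrom[i]
      snp_pos[k] <- max(1, sites$pos[i] + sample(-8e5:8e5, 1))
      dos <- G[, k]
      frac <- counts$methylated[i, ] / pmax(counts$coverage[i, ], 1)
      frac <- pmin(pmax(frac + dos * shift_pp / 100, 0), 1)
      counts$methylated[i, ] <- ifelse(
        is.na(counts$coverage[i, ]), NA,
        pmin(round(frac * counts$coverage[i, ]), counts$coverage[i, ]))
      known <- rbind(known, data.frame(snp_id = colnames(G)[k],
                                       site_id = sites$site_id[i],
                                       shift = shift_pp,
                                       stringsAsFactors = FALSE))
    }
  }
  snp_info <- data.frame(snp_id = colnames(G), chrom = snp_chrom,
                         pos = as.integer(snp_pos), maf = maf,
                         stringsAsFactors = FALSE)
  list(genotypes = G, snp_info = snp_info, known_meqtls = known,
       counts = counts)
}
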