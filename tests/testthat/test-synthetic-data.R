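test_that("null configuration produces only sampling noise", {
  sim <- small_sim()
  meth <- small_meth()
  dx <- sim$sample_sheet$diagnosis == "case"
  p <- apply(meth$meth_pct, 1, function(y) {
    if (sum(!is.na(y[dx])) < 3 || sum(!is.na(y[!dx])) < 3) return(NA)
    stats::t.test(y[dx], y[!dx])$p.value
  })
  p <- p[!is.na(p)]
  expect_gt(length(p), 1000)
  # ~5% below 0.05, binomial tolerance
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)) + 0.01)
})

test_that("generator hits the configured methylation means at scale", {
  cfg <- simulation_config(n_cases = 10, n_controls = 10,
                           n_cpg_sites = 50000, n_cph_sites = 50000,
                           effect_fraction = 0, n_confounders = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  frac <- 100 * sim$counts$methylated / sim$counts$coverage
  cph <- rowMeans(frac[sim$counts$sites$context == "CpH", ], na.rm = TRUE)
  cpg <- rowMeans(frac[sim$counts$sites$context == "CpG", ], na.rm = TRUE)
  expect_lt(abs(mean(cph, na.rm = TRUE) - 1.7), 0.5)
  expect_lt(abs(mean(cpg, na.rm = TRUE) - 21.2), 2)
})

test_that("generated counts respect coverage bounds and determinism", {
  cfg <- small_config(effect_fraction = 0.3, n_confounders = 2, n_dmrs = 1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  ok <- !is.na(a$counts$coverage)
  expect_true(all(a$counts$methylated[ok] <= a$counts$coverage[ok]))
  expect_true(all(a$counts$coverage[ok] >= 0))
  # ground truth indexes every planted signal
  expect_true(all(a$truth$effect_sites$site_id %in% a$counts$sites$site_id))
  expect_true(all(a$truth$effect_sites$site_id %in%
                    a$counts$sites$site_id[a$counts$sites$context == "CpH"]))
  expect_equal(nrow(a$truth$planted_dmrs), 1)
  expect_gte(sum(a$counts$sites$chrom == a$truth$planted_dmrs$chrom &
                   a$counts$sites$pos >= a$truth$planted_dmrs$start &
                   a$counts$sites$pos <= a$truth$planted_dmrs$end), 3)
})

test_that("impossible effect configurations are rejected", {
  expect_error(simulation_config(n_cph_sites = 10, effect_fraction = 0.05,
                                 effect_median_shift = 2),
               "no room")
  expect_error(simulation_config(effect_fraction = 1.5))
  expect_error(simulation_config(n_dmrs = 1, dmr_n_sites = 2), "3 sites")
})

test_that("planted effects land near the configured median shift", {
  cfg <- simulation_config(n_cases = 40, n_controls = 40,
                           n_cpg_sites = 100, n_cph_sites = 4000,
                           effect_fraction = 0.3, effect_median_shift = 1.8,
                           n_confounders = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  expect_equal(median(sim$truth$effect_sites$shift), 1.8, tolerance = 0.15)
  # empirical case-control difference at effect sites tracks the plant
  frac <- 100 * sim$counts$methylated / sim$counts$coverage
  dx <- sim$sample_sheet$diagnosis == "case"
  idx <- match(sim$truth$effect_sites$site_id, sim$counts$sites$site_id)
  obs <- rowMeans(frac[idx, dx], na.rm = TRUE) -
    rowMeans(frac[idx, !dx], na.rm = TRUE)
  expect_equal(median(obs), 1.8, tolerance = 0.4)
})

test_that("inject_qc_failures implements the three failure modes", {
  sim <- small_sim()
  expect_identical(inject_qc_failures(sim$counts, list()), sim$counts)
  expect_error(inject_qc_failures(sim$counts, list(bogus = "S01")),
               "unknown QC failure mode")
  expect_error(inject_qc_failures(sim$counts,
                                  list(hypermethylated = "nope")),
               "unknown sample")

  inj <- inject_qc_failures(sim$counts,
                            list(hypermethylated = "S05",
                                 non_bimodal = "S06",
                                 coverage_aberrant = "S07"), seed = 2)
  frac <- inj$methylated[, "S05"] / inj$coverage[, "S05"]
  expect_gt(mean(frac > 0.5, na.rm = TRUE), 0.99)
  # untouched samples identical
  others <- setdiff(sim$counts$samples, c("S05", "S06", "S07"))
  expect_identical(inj$methylated[, others], sim$counts$methylated[, others])
  # injected failures cross the sample_qc thresholds
  qc <- sample_qc(inj)
  expect_true(qc$flag_hypermethylated[qc$sample_id == "S05"])
  expect_true(qc$flag_non_bimodal[qc$sample_id == "S06"])
  expect_true(qc$flag_coverage[qc$sample_id == "S07"])
})

test_that("simulated genotypes follow Hardy-Weinberg and plant meQTLs", {
  # dosage means: one site, 1000 samples, many SNPs
  cov <- matrix(30, 3, 1000)
  met <- matrix(1, 3, 1000)
  counts <- toy_counts(cov, met)
  gen <- simulate_genotypes(counts, n_snps = 200, meqtl_pairs = 0, seed = 5)
  # dosage mean per SNP ~ 2 * maf (binomial 3-sigma envelope at n = 1000)
  se <- sqrt(2 * gen$snp_info$maf * (1 - gen$snp_info$maf) / 1000)
  expect_true(all(abs(colMeans(gen$genotypes) - 2 * gen$snp_info$maf) <
                    4 * se + 0.02))
  expect_equal(nrow(gen$known_meqtls), 0)

  # planted pair: 10-point per-allele shift, n = 60 -> p < 1e-6
  sim <- simulate_dataset(small_config(n_cases = 30, n_controls = 30,
                                       seed = 8))
  gen2 <- simulate_genotypes(sim$counts, n_snps = 5, meqtl_pairs = 2,
                             shift_pp = 10, seed = 6)
  meth <- percent_methylation(gen2$counts)
  pair <- gen2$known_meqtls[1, ]
  y <- meth$meth_pct[match(pair$site_id, meth$sites$site_id), ]
  dos <- gen2$genotypes[, pair$snp_id]
  fit <- summary(stats::lm(y ~ dos))
  expect_lt(fit$coefficients["dos", 4], 1e-6)
  # SNP within 1 Mb of its linked site
  info <- gen2$snp_info[match(pair$snp_id, gen2$snp_info$snp_id), ]
  site <- sim$counts$sites[match(pair$site_id, sim$counts$sites$site_id), ]
  expect_equal(info$chrom, site$chrom)
  expect_lte(abs(info$pos - site$pos), 1e6)
})

test_that("ground truth round-trips through JSON losslessly", {
  cfg <- small_config(effect_fraction = 0.2, n_confounders = 2, n_dmrs = 1,
                      qc_failure_modes = list(hypermethylated = 1))
  sim <- simulate_dataset(cfg)
  path <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$effect_sites, sim$truth$effect_sites)
  expect_equal(back$planted_dmrs, sim$truth$planted_dmrs)
  expect_equal(back$outlier_samples, sim$truth$outlier_samples)
  expect_equal(back$confounder_loadings, sim$truth$confounder_loadings)
})
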