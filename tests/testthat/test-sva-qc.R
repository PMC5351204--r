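make_conf_sim <- function(n_conf, seed, n = 60, n_sites = 5000,
                          conf_sd = 0.8) {
  cfg <- simulation_config(n_cases = n / 2, n_controls = n / 2,
                           n_cpg_sites = n_sites, n_cph_sites = 100,
                           effect_fraction = 0, n_confounders = n_conf,
                           confounder_sd = conf_sd, seed = seed)
  simulate_dataset(cfg)
}

test_that("SVs are orthonormal and protect diagnosis under the null", {
  sim <- memo("conf_sim0", make_conf_sim(0, seed = 31, n_sites = 2000))
  meth <- complete_sites(percent_methylation(
    unite_sites(filter_coverage(sim$counts), sim$sample_sheet, 20, 20)))
  sv <- estimate_svs(meth, build_design(sim$sample_sheet), k = 10)
  expect_lt(max(abs(crossprod(sv$sv) - diag(10))), 1e-8)
  dx <- as.numeric(sim$sample_sheet$diagnosis == "case")
  expect_lt(max(abs(stats::cor(sv$sv, dx))), 0.3)
  # no planted structure: leading SV explains ~1/n of residual variance
  expect_equal(sv$method, "irw")
})

test_that("a planted confounder is recovered by SV1", {
  sim <- memo("conf_sim1", make_conf_sim(1, seed = 32))
  meth <- complete_sites(percent_methylation(
    unite_sites(filter_coverage(sim$counts), sim$sample_sheet, 20, 20)))
  sv <- estimate_svs(meth, build_design(sim$sample_sheet), k = 10)
  r <- stats::cor(sv$sv[, 1], sim$truth$confounder_scores[, 1])
  expect_gte(abs(r), 0.9)
})

test_that("two orthogonal confounders are spanned by SV1-SV2", {
  sim <- memo("conf_sim2", make_conf_sim(2, seed = 33))
  meth <- complete_sites(percent_methylation(
    unite_sites(filter_coverage(sim$counts), sim$sample_sheet, 20, 20)))
  sv <- estimate_svs(meth, build_design(sim$sample_sheet), k = 10)
  cc <- stats::cancor(sv$sv[, 1:2], sim$truth$confounder_scores)
  expect_gte(min(cc$cor), 0.9)
})

test_that("k is truncated to the available rank with a warning", {
  meth <- complete_sites(small_meth())
  meth <- subset_samples(meth, meth$samples[1:12])
  design <- toy_design(rep(c(0, 1), 6))
  expect_warning(sv <- estimate_svs(meth, design, k = 11), "truncated")
  expect_lte(ncol(sv$sv), 12 - qr(design)$rank)
})

test_that("iterative SV outlier removal flags injected failures only", {
  sim <- small_sim()
  meth <- small_meth()
  clean <- detect_sv_outliers(meth, sim$sample_sheet, k = 5)
  expect_equal(nrow(clean$log), 0)
  expect_equal(clean$kept, meth$samples)

  inj <- inject_qc_failures(sim$counts, list(hypermethylated = "S10"),
                            seed = 4)
  meth2 <- percent_methylation(unite_sites(filter_coverage(inj),
                                           sim$sample_sheet))
  out <- detect_sv_outliers(meth2, sim$sample_sheet, k = 5)
  expect_true("S10" %in% out$log$sample_id)
  expect_equal(out$log$round[out$log$sample_id == "S10"], 1)
  # reproducible
  out2 <- detect_sv_outliers(meth2, sim$sample_sheet, k = 5)
  expect_identical(out, out2)
})

test_that("sample_qc raises no flags on clean data", {
  qc <- sample_qc(small_sim()$counts)
  expect_false(any(qc$flagged))
})

test_that("meQTL model matches the normal-equations oracle on a toy", {
  # 5 samples, one site, one SNP
  meth <- toy_meth(matrix(c(10, 20, 35, 42, 60), 1))
  dos <- c(0, 1, 1, 2, 2)
  G <- matrix(dos, 5, 1, dimnames = list(meth$samples, "snp0001"))
  info <- data.frame(snp_id = "snp0001", chrom = "chr1", pos = 120)
  det <- detect_meqtls(meth, G, info, cis_window = 1e6, alpha = 1)
  X <- cbind(1, dos)
  beta_oracle <- solve(crossprod(X), crossprod(X, meth$meth_pct[1, ]))
  expect_equal(det$beta, beta_oracle[2], tolerance = 1e-8)
})

test_that("meQTL detection respects the cis window and monomorphism", {
  meth <- toy_meth(matrix(rnorm(10, 50, 5), 1))
  # site at pos 100; snpA at 1 Mb exactly, snpB at 1 Mb + 1 bp
  G <- cbind(snpA = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0),
             snpB = c(2, 1, 0, 2, 1, 0, 2, 1, 0, 2),
             snpC = rep(1, 10))
  rownames(G) <- meth$samples
  info <- data.frame(snp_id = c("snpA", "snpB", "snpC"),
                     chrom = "chr1", pos = c(100 + 1e6, 100 + 1e6 + 1, 200))
  det <- detect_meqtls(meth, G, info, cis_window = 1e6, alpha = 1)
  expect_true("snpA" %in% det$snp_id)
  expect_false("snpB" %in% det$snp_id)
  expect_equal(attr(det, "skipped"), "snpC")
})

test_that("planted meQTLs are detected and recovery behaves as a QC signal", {
  sim <- simulate_dataset(small_config(n_cases = 30, n_controls = 30,
                                       seed = 35))
  gen <- simulate_genotypes(sim$counts, n_snps = 10, meqtl_pairs = 5,
                            shift_pp = 10, seed = 36)
  meth <- percent_methylation(unite_sites(filter_coverage(gen$counts),
                                          sim$sample_sheet, 20, 20))
  det <- detect_meqtls(meth, gen$genotypes, gen$snp_info, alpha = 1e-4)
  rec <- known_meqtl_recovery(det, gen$known_meqtls,
                              snps_present = colnames(gen$genotypes),
                              sites_present = meth$sites$site_id)
  expect_gte(rec, 0.8)

  # trivial arithmetic of the recovery fraction
  known <- data.frame(snp_id = c("a", "b", "c"), site_id = c("x", "y", "z"))
  detected <- data.frame(snp_id = c("a", "b"), site_id = c("x", "y"))
  expect_equal(known_meqtl_recovery(detected, known, c("a", "b", "c"),
                                    c("x", "y", "z")), 2 / 3)
  expect_equal(known_meqtl_recovery(known, known, c("a", "b", "c"),
                                    c("x", "y", "z")), 1)
  expect_error(known_meqtl_recovery(detected, known, "q", "x"),
               "no assayable")

  # recovery is non-decreasing after dropping an injected QC failure
  bad <- gen$counts
  bad <- inject_qc_failures(bad, list(hypermethylated = "S55"), seed = 37)
  meth_bad <- percent_methylation(unite_sites(filter_coverage(bad),
                                              sim$sample_sheet, 20, 20))
  det_bad <- detect_meqtls(meth_bad, gen$genotypes, gen$snp_info,
                           alpha = 1e-4)
  rec_bad <- known_meqtl_recovery(det_bad, gen$known_meqtls,
                                  colnames(gen$genotypes),
                                  meth_bad$sites$site_id)
  meth_fix <- subset_samples(meth_bad, setdiff(meth_bad$samples, "S55"))
  det_fix <- detect_meqtls(meth_fix, gen$genotypes, gen$snp_info,
                           alpha = 1e-4)
  rec_fix <- known_meqtl_recovery(det_fix, gen$known_meqtls,
                                  colnames(gen$genotypes),
                                  meth_fix$sites$site_id)
  expect_gte(rec_fix, rec_bad)
})

test_that("null dosages are detected at about the nominal rate", {
  set.seed(38)
  meth <- toy_meth(matrix(rnorm(50 * 40, 50, 8), 50, 40))
  G <- matrix(rbinom(40 * 20, 2, 0.3), 40, 20,
              dimnames = list(meth$samples, sprintf("snp%04d", 1:20)))
  info <- data.frame(snp_id = colnames(G), chrom = "chr1",
                     pos = seq(100, by = 100, length.out = 20))
  det <- detect_meqtls(meth, G, info, cis_window = 1e6, alpha = 0.05)
  n_pairs <- 50 * 20
  rate <- nrow(det) / n_pairs
  expect_lt(abs(rate - 0.05), 0.03)
})
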