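test_that("cluster_sites joins by gap with transitive closure", {
  cl <- cluster_sites(rep("chr1", 3), c(100, 200, 600), maxgap = 300)
  expect_equal(cl, c(1, 1, 2))
  # maxgap 0: singletons unless identical positions
  expect_equal(cluster_sites(rep("chr1", 3), c(100, 200, 600), 0),
               c(1, 2, 3))
  expect_equal(cluster_sites(rep("chr1", 2), c(100, 100), 0), c(1, 1))
  # chromosome boundaries always break clusters
  expect_equal(cluster_sites(c("chr1", "chr2"), c(100, 150), 300), c(1, 2))

  # union-find oracle on 500 random positions
  set.seed(81)
  pos <- sort(sample.int(2e5, 500))
  chrom <- rep(c("chr1", "chr2"), c(250, 250))
  pos <- c(sort(pos[1:250]), sort(pos[251:500]))
  labels <- cluster_sites(chrom, pos, 300)
  parent <- seq_along(pos)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 2:length(pos))
    if (chrom[i] == chrom[i - 1] && pos[i] - pos[i - 1] <= 300)
      parent[find(i)] <- find(i - 1)
  roots <- vapply(seq_along(pos), find, numeric(1))
  expect_equal(as.integer(factor(labels, levels = unique(labels))),
               as.integer(factor(roots, levels = unique(roots))))
})

test_that("smooth_coefficients is a truncated running mean within clusters", {
  # constants pass through
  expect_equal(smooth_coefficients(rep(2, 9), rep(1, 9), window = 5,
                                   min_sites = 7), rep(2, 9))
  # single-site / small clusters unchanged
  beta <- c(1, 5, 9)
  expect_equal(smooth_coefficients(beta, c(1, 2, 3)), beta)
  # 9-site cluster, window 3: hand-computed running mean
  beta <- as.numeric(1:9)
  sm <- smooth_coefficients(beta, rep(1, 9), window = 3, min_sites = 7)
  expect_equal(sm, c(mean(1:2), 2:8, mean(8:9)))
})

test_that("pick_cutoff is the linear-interpolation quantile of |smoothed|", {
  v <- 1:100
  expect_equal(suppressWarnings(pick_cutoff(v, 0.99)),
               quantile(1:100, 0.99, names = FALSE))
  expect_equal(quantile(1:100, 0.99, names = FALSE), 99.01)
  expect_equal(pick_cutoff(rep(3, 150)), 3)
  # monotone in the quantile parameter
  set.seed(82)
  x <- rnorm(500)
  qs <- vapply(c(0.9, 0.95, 0.99), function(q) pick_cutoff(x, q), 1)
  expect_true(all(diff(qs) >= 0))
  expect_warning(pick_cutoff(1:10), "fewer than 100")
})

test_that("find_candidate_regions calls maximal runs within clusters", {
  sites <- data.frame(chrom = "chr1", pos = seq(100, by = 50,
                                                length.out = 12))
  clusters <- rep(c(1, 2), each = 6)
  beta <- c(0, 5, 6, 7, 0, 0, 6, 6, 0, -6, -7, 0)
  reg <- find_candidate_regions(sites, beta, beta, clusters, cutoff = 4)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$n_sites, c(3, 2, 2))
  expect_equal(reg$value[1], mean(c(5, 6, 7)))
  expect_equal(reg$direction, c(1, 1, -1))
  expect_equal(reg$length_bp[1], sites$pos[4] - sites$pos[2] + 1)
  # regions never span cluster boundaries
  expect_true(all(reg$start >= 100 & reg$end <= 650) ||
                all(reg$n_sites <= 6))
  # no site above cutoff: empty
  expect_equal(nrow(find_candidate_regions(sites, beta, beta, clusters,
                                           cutoff = 10)), 0)

  # runs crossing a cluster boundary split into two regions
  beta2 <- rep(6, 12)
  reg2 <- find_candidate_regions(sites, beta2, beta2, clusters, cutoff = 4)
  expect_equal(nrow(reg2), 2)
})

test_that("compute_fwer counts strict dominance on both axes", {
  obs <- data.frame(chrom = "chr1", start = 1, end = 1000, n_sites = 5,
                    value = 8, length_bp = 1000, direction = 1)
  mk <- function(len, val) data.frame(chrom = "chr1", start = 1, end = len,
                                      n_sites = 3, value = val,
                                      length_bp = len, direction = 1)
  # dominated in none of 4 bootstraps
  boots <- list(mk(500, 9), mk(2000, 7), mk(1000, 8), mk(10, 1))
  expect_equal(compute_fwer(obs, boots)$fwer, 0)
  # exactly 1 of 4 strictly dominating
  boots[[2]] <- mk(2000, 9)
  expect_equal(compute_fwer(obs, boots)$fwer, 0.25)
  # dominance uses |value|
  boots[[2]] <- mk(2000, -9)
  expect_equal(compute_fwer(obs, boots)$fwer, 0.25)
  expect_error(compute_fwer(obs, list()), "B = 0")

  # brute-force double-loop oracle on random regions
  set.seed(83)
  obs <- do.call(rbind, lapply(1:6, function(i) mk(sample(100:2000, 1),
                                                   rnorm(1, 0, 5))))
  boots <- lapply(1:20, function(b)
    do.call(rbind, lapply(1:3, function(i) mk(sample(100:2000, 1),
                                              rnorm(1, 0, 5)))))
  got <- compute_fwer(obs, boots)$fwer
  oracle <- sapply(seq_len(nrow(obs)), function(r)
    mean(sapply(boots, function(q)
      any(q$length_bp > obs$length_bp[r] &
            abs(q$value) > abs(obs$value[r])))))
  expect_equal(got, oracle)
})

test_that("dmr_significance applies the corrected threshold strictly", {
  reg <- data.frame(fwer = c(0.001, 0.002, 0.1))
  out <- dmr_significance(reg, n_tests = 24, alpha = 0.05)
  expect_equal(attr(out, "threshold"), 0.002)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  out1 <- dmr_significance(reg, n_tests = 1)
  expect_equal(attr(out1, "threshold"), 0.05)
})

test_that("run_dmr recovers a planted region and is deterministic", {
  cfg <- simulation_config(n_cases = 30, n_controls = 30, n_cpg_sites = 100,
                           n_cph_sites = 1200, effect_fraction = 0,
                           n_confounders = 0, n_dmrs = 1, dmr_shift = 10,
                           seed = 84)
  sim <- simulate_dataset(cfg)
  dmeth <- percent_methylation(unite_sites(
    filter_coverage(sim$counts, min_cov = 5), sim$sample_sheet, 20, 20))
  res <- run_dmr(dmeth, build_design(sim$sample_sheet), B = 30, seed = 85)
  tr <- sim$truth$planted_dmrs
  jac <- mapply(function(s, e) {
    i <- max(0, min(e, tr$end) - max(s, tr$start))
    i / ((e - s) + (tr$end - tr$start) - i)
  }, res$regions$start, res$regions$end)
  best <- which.max(jac)
  expect_gte(jac[best], 0.5)
  expect_equal(res$regions$fwer[best], min(res$regions$fwer))

  res2 <- run_dmr(dmeth, build_design(sim$sample_sheet), B = 30, seed = 85)
  expect_identical(res$regions, res2$regions)

  # null simulation: no spurious confidence
  cfg0 <- small_config(n_cph_sites = 1200, seed = 86)
  sim0 <- simulate_dataset(cfg0)
  dmeth0 <- percent_methylation(unite_sites(
    filter_coverage(sim0$counts, min_cov = 5), sim0$sample_sheet, 20, 20))
  res0 <- run_dmr(dmeth0, build_design(sim0$sample_sheet), B = 30,
                  seed = 87)
  expect_gt(median(res0$regions$fwer), 0.5)
})
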