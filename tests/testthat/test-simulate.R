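# Generator invariants and parameter-recovery checks (the generators are
# first-class code: every planted effect must be recoverable downstream).

test_that("generators are pure functions of (config, seed)", {
  cfg <- methylome_sim_config(n_cpgs = 300, n_true_dmrs = 5,
                              genome = genome_layout("chr1", 30000), seed = 3)
  a <- simulate_methylome(cfg); b <- simulate_methylome(cfg)
  expect_identical(a$meth, b$meth)
  expect_identical(a$truth$dmrs, b$truth$dmrs)
  co <- cohort_sim_config(n_subjects = 100, seed = 5)
  expect_identical(simulate_cohort(co)$cohort, simulate_cohort(co)$cohort)
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_methylome(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("simulated counts respect bounds and the null has no group signal", {
  cfg <- methylome_sim_config(n_cpgs = 1000, dmr_effect = 0, n_true_dmrs = 0,
                              mean_coverage = 30,
                              genome = genome_layout("chr1", 100000), seed = 8)
  sim <- simulate_methylome(cfg)
  expect_true(all(sim$meth$meth >= 0 & sim$meth$meth <= sim$meth$total))
  expect_true(all(sim$meth$total >= 1))
  # group mean methylation difference ~ 0: |mean diff| < 3 SE overall
  prop <- sim$meth$meth / sim$meth$total
  lo <- rowMeans(prop[, sim$meth$groups == "low"])
  hi <- rowMeans(prop[, sim$meth$groups == "high"])
  se <- sd(hi - lo) / sqrt(length(lo))
  expect_lt(abs(mean(hi - lo)), 3 * se)
})

test_that("degenerate all-methylated option gives M = N everywhere", {
  cfg <- methylome_sim_config(n_cpgs = 200, pi_range = c(1, 1),
                              n_true_dmrs = 0, dmr_effect = 0,
                              genome = genome_layout("chr1", 20000), seed = 2)
  sim <- simulate_methylome(cfg)
  expect_identical(unname(sim$meth$meth), unname(sim$meth$total))
})

test_that("planted methylation shift is recovered at large n", {
  # delta = 0.3 over planted regions, 50 samples per group: raw group
  # difference inside regions approximates the planted shift
  cfg <- methylome_sim_config(n_cpgs = 500, n_per_group = 50,
                              mean_coverage = 30, n_true_dmrs = 10,
                              dmr_effect = 0.3,
                              genome = genome_layout("chr1", 50000), seed = 13)
  sim <- simulate_methylome(cfg)
  prop <- sim$meth$meth / sim$meth$total
  d <- rowMeans(prop[, sim$meth$groups == "high"]) -
    rowMeans(prop[, sim$meth$groups == "low"])
  for (k in seq_len(nrow(sim$truth$dmrs))) {
    idx <- sim$truth$dmrs$first_idx[k]:sim$truth$dmrs$last_idx[k]
    expect_equal(mean(d[idx]), sim$truth$dmrs$sign[k] * 0.3, tolerance = 0.05)
  }
  # planted regions are disjoint
  tr <- sim$truth$dmrs
  expect_true(all(tr$start[-1] >= head(tr$end, -1)))
})

test_that("planted meQTL slope is recovered by regression at n = 100", {
  cfg <- methylome_sim_config(n_cpgs = 400, n_per_group = 50,
                              mean_coverage = 30, n_true_dmrs = 6,
                              dmr_effect = 0,
                              genome = genome_layout("chr1", 40000), seed = 21)
  sim <- simulate_methylome(cfg)
  g <- simulate_genotypes(sim$meth, sim$truth, n_meqtls = 6, beta_meqtl = 0.2,
                          maf = 0.3, seed = 22)
  for (k in seq_len(nrow(g$truth$meqtls))) {
    d <- g$truth$dmrs[g$truth$dmrs$dmr_id == g$truth$meqtls$dmr_id[k], ]
    rm_ <- regional_methylation(g$meth, d)
    dos <- g$geno$dosage[g$truth$meqtls$variant_id[k], ]
    fit <- lm(rm_ ~ dos)
    ci <- confint(fit)["dos", ]
    expect_gt(0.2, ci[1] - 0.02)
    expect_lt(0.2, ci[2] + 0.02)
  }
  # beta = 0: regional methylation uncorrelated with dosage
  g0 <- simulate_genotypes(sim$meth, sim$truth, n_meqtls = 6, beta_meqtl = 0,
                           maf = 0.3, seed = 23)
  r <- sapply(seq_len(nrow(g0$truth$meqtls)), function(k) {
    d <- g0$truth$dmrs[g0$truth$dmrs$dmr_id == g0$truth$meqtls$dmr_id[k], ]
    cor(regional_methylation(g0$meth, d),
        g0$geno$dosage[g0$truth$meqtls$variant_id[k], ])
  })
  expect_lt(max(abs(r)), 0.35)
  # maf = 0 gives monomorphic dosages
  gz <- simulate_genotypes(sim$meth, sim$truth, n_meqtls = 2, beta_meqtl = 0.2,
                           maf = 0, seed = 24)
  expect_true(all(gz$geno$dosage == 0))
})

test_that("annotation generator hits every planted DMR at frac = 1", {
  cfg <- methylome_sim_config(n_cpgs = 400, n_true_dmrs = 8,
                              genome = genome_layout("chr1", 40000), seed = 31)
  sim <- simulate_methylome(cfg)
  ann <- simulate_annotations(cfg$genome, sim$truth, n_intervals = 20,
                              frac_near_dmrs = 1, interval_len = 300, seed = 32)
  tr <- sim$truth$dmrs
  hit <- sapply(seq_len(nrow(tr)), function(i)
    overlap_count(tr[i, ], ann) > 0)
  expect_true(all(hit))
  expect_equal(nrow(simulate_annotations(cfg$genome, sim$truth, 0, 0.5,
                                         seed = 33)), 0)
})

test_that("cohort generator produces valid scores and null odds ratios near 1", {
  sim <- simulate_cohort(cohort_sim_config(n_subjects = 443, seed = 6))
  items <- attr(sim$cohort, "psq_items")
  expect_true(all(items %in% 1:4))
  expect_equal(dim(items), c(443L, 20L))
  expect_equal(sim$cohort$stress_score, rowMeans(items))
  expect_true(all(sim$cohort$stress_score >= 1 & sim$cohort$stress_score <= 4))
  expect_true(all(sim$cohort$biomarker > 0))

  # null: planted ORs of 1 recovered near 1 at n = 20000
  null <- simulate_cohort(cohort_sim_config(n_subjects = 20000, or_high = 1,
                                            or_medium = 1, confounders = list(),
                                            seed = 7))
  ors <- cohort_or(null$cohort, "persistent_wheeze", "stress_category",
                   reference = "low")
  expect_equal(ors$high$odds_ratio, 1, tolerance = 0.15)
  expect_equal(ors$medium$odds_ratio, 1, tolerance = 0.15)
})
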