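# Shuffle-null enrichment, array overlap, gene assignment, gene sets.

test_that("overlap counting follows the 1-bp rule and matches the double loop", {
  dmr <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(overlap_count(dmr, interval_set("chr1", 300, 400)), 0)
  expect_equal(overlap_count(dmr, interval_set("chr1", 199, 300)), 1)
  expect_equal(overlap_count(dmr, interval_set("chr1", 0, 100)), 0)  # abutting
  expect_equal(overlap_count(dmr, interval_set("chr2", 100, 200)), 0)

  for (seed in 1:4) {
    set.seed(seed)
    n <- 50; m <- 30
    ds <- sort(sample.int(5000, n))
    dmrs <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                       start = ds, end = ds + sample(20:200, n, TRUE))
    ts <- sort(sample.int(5000, m))
    track <- interval_set(sample(c("chr1", "chr2"), m, TRUE), ts,
                          ts + sample(10:300, m, TRUE))
    expect_equal(overlap_count(dmrs, track), overlap_count_oracle(dmrs, track))
  }

  # depends only on covered bases: merging adjacent intervals changes nothing
  split_track <- interval_set(c("chr1", "chr1"), c(150, 175), c(175, 220))
  merged <- interval_set("chr1", 150, 220)
  expect_equal(overlap_count(dmr, split_track), overlap_count(dmr, merged))
})

test_that("shuffling preserves lengths and chromosomes, and is uniform", {
  set.seed(7)
  n <- 12
  st <- sort(sample.int(50000, n))
  dmrs <- data.frame(chrom = rep(c("chr1", "chr2"), each = 6), start = st,
                     end = st + sample(100:1000, n, TRUE),
                     id = paste0("d", 1:n))
  g <- genome_layout(c("chr1", "chr2"), c(60000, 60000))
  sh <- shuffle_dmrs(dmrs, g, shuffle_params())
  expect_equal(sort(sh$end - sh$start), sort(dmrs$end - dmrs$start))
  expect_equal(table(sh$chrom), table(dmrs$chrom))

  # uniform placement: a 100-bp interval on a 1000-bp chromosome has start
  # uniform on [0, 900]; chi-square over 10 bins at alpha = 0.01
  one <- data.frame(chrom = "c", start = 0, end = 100, id = "d")
  g1 <- genome_layout("c", 1000)
  set.seed(8)
  starts <- replicate(10000, shuffle_dmrs(one, g1, shuffle_params())$start)
  expect_true(all(starts >= 0 & starts <= 900))
  obs <- table(cut(starts, breaks = seq(-0.5, 900.5, length.out = 11)))
  chi <- sum((obs - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.99, df = 9))

  # exclusion forces the only remaining slot
  excl <- interval_set("c", 150, 1000)
  set.seed(9)
  forced <- replicate(20, shuffle_dmrs(one, g1,
                                       shuffle_params(exclude = excl))$start)
  expect_true(all(forced >= 0 & forced <= 50))

  big <- data.frame(chrom = "c", start = 0, end = 2000, id = "huge")
  expect_error(shuffle_dmrs(big, g1, shuffle_params()), "exceeds chromosome")
})

test_that("degenerate tracks are flagged instead of producing fake z-scores", {
  dmrs <- data.frame(chrom = "chr1", start = c(10, 500), end = c(60, 700),
                     id = c("a", "b"))
  g <- genome_layout("chr1", 1000)
  whole <- interval_set("chr1", 0, 1000)
  r <- enrichment_z(dmrs, whole, g, shuffle_params(50, seed = 1))
  expect_true(r$degenerate_null)
  expect_true(is.na(r$z))
  expect_equal(r$observed_overlap, 2)
  expect_equal(r$empirical_p, 1)

  none <- interval_set(character(), numeric(), numeric())
  r0 <- enrichment_z(dmrs, none, g, shuffle_params(50, seed = 1))
  expect_equal(r0$observed_overlap, 0)
  expect_true(r0$degenerate_null)
  expect_error(enrichment_z(dmrs, whole, g, shuffle_params(10)), ">= 30")
})

test_that("shuffle-null moments match exact enumeration on a tiny genome", {
  # 3 regions (lengths 10, 20, 30) on a 100-bp chromosome, 2 track
  # intervals; every placement is enumerable, so the null mean and sd of
  # the overlap count have closed forms to compare against
  dmrs <- data.frame(chrom = "c", start = c(0, 40, 60), end = c(10, 60, 90),
                     id = c("d1", "d2", "d3"))
  g <- genome_layout("c", 100)
  track <- interval_set(c("c", "c"), c(15, 70), c(25, 80))
  len <- dmrs$end - dmrs$start
  p_hit <- vapply(len, function(L) {
    starts <- 0:(100 - L)
    mean(vapply(starts, function(s)
      any(s < track$end & track$start < s + L), TRUE))
  }, numeric(1))
  exact_mean <- sum(p_hit)
  exact_sd <- sqrt(sum(p_hit * (1 - p_hit)))

  r <- enrichment_z(dmrs, track, g, shuffle_params(20000, seed = 11))
  expect_equal(r$null_mean, exact_mean, tolerance = 0.02)
  expect_equal(r$null_sd, exact_sd, tolerance = 0.05)
})

test_that("z and empirical p agree in rank across tracks", {
  sim <- simulate_methylome(methylome_sim_config(
    n_cpgs = 600, n_true_dmrs = 10, genome = genome_layout("chr1", 60000),
    seed = 51))
  g <- sim$truth$config$genome
  dmrs <- sim$truth$dmrs
  res <- lapply(c(0, 0.5, 1), function(f) {
    ann <- simulate_annotations(g, sim$truth, 30, f, 400, seed = 52)
    enrichment_z(dmrs, ann, g, shuffle_params(200, seed = 53))
  })
  z <- vapply(res, `[[`, numeric(1), "z")
  p <- vapply(res, `[[`, numeric(1), "empirical_p")
  expect_equal(order(z), order(-p))
  expect_gt(z[3], qnorm(0.95))  # strongly enriched track clears the 5% tail
})

test_that("array overlap fractions reproduce the printed arithmetic", {
  expect_equal(round(100 * 130 / 2495, 1), 5.2)
  expect_equal(round(100 * 114 / 2306, 1), 4.9)

  dmrs <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                     end = c(50, 150, 250), id = letters[1:3])
  cpgs <- data.frame(chrom = "chr1", pos = c(25, 125))  # 1-based positions
  ao <- array_overlap(dmrs, cpgs)
  expect_equal(ao$count, 2)
  expect_equal(ao$percent, 66.7)
  none <- array_overlap(dmrs, interval_set(character(), numeric(), numeric()))
  expect_equal(none$count, 0)
  expect_equal(none$fraction, 0)
  zero <- array_overlap(dmrs[0, ], cpgs)
  expect_true(is.na(zero$fraction))
})

test_that("gene assignment matches an independent overlap route", {
  genes <- interval_set(rep("chr1", 3), c(100, 150, 1000),
                        c(500, 250, 1500), name = c("outer", "nested", "far"))
  dmrs <- data.frame(chrom = "chr1", start = c(160, 600, 1400),
                     end = c(200, 700, 1600), id = c("in", "between", "edge"))
  got <- assign_genes(dmrs, genes, flank_bp = 0)
  expect_equal(got$`in`, c("outer", "nested"))
  expect_equal(got$between, character(0))
  expect_equal(got$edge, "far")
  # flank pulls the intergenic DMR into range
  withf <- assign_genes(dmrs, genes, flank_bp = 150)
  expect_true("outer" %in% withf$between)

  set.seed(10)
  n <- 25
  gs <- sort(sample.int(10000, 15))
  genes2 <- interval_set(rep("chr1", 15), gs, gs + sample(100:2000, 15, TRUE),
                         name = paste0("g", 1:15))
  ds <- sort(sample.int(10000, n))
  dmrs2 <- data.frame(chrom = "chr1", start = ds,
                      end = ds + sample(50:500, n, TRUE),
                      id = paste0("d", 1:n))
  got2 <- assign_genes(dmrs2, genes2)
  for (i in seq_len(n)) {
    q <- IRanges::IRanges(dmrs2$start[i] + 1, dmrs2$end[i])
    s <- IRanges::IRanges(genes2$start + 1, genes2$end)
    expect_equal(got2[[i]], genes2$name[IRanges::countOverlaps(s, q) > 0])
  }
})

test_that("gene-set enrichment equals the hypergeometric tail sum", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), miss = paste0("g", 16:18))
  dmr_genes <- c("g1", "g2", "g3", "g10", "g11")
  res <- geneset_enrichment(dmr_genes, sets, universe)
  p_hit <- res$p_value[res$set_name == "hit"]
  expect_equal(p_hit, hyper_tail_oracle(3, 5, 20, 5), tolerance = 1e-12)
  expect_true(all(res$p_value <= 1 & res$p_value > 0))
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # degenerate: dmr genes = set = universe forces full overlap, p = 1
  res2 <- geneset_enrichment(universe, list(all = universe), universe)
  expect_equal(res2$p_value, 1)
  expect_error(geneset_enrichment("g1", sets, character()), "empty")
  expect_error(geneset_enrichment("zzz", sets, universe), "outside")

  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg4"), gmt)
  expect_equal(read_gmt(gmt), list(setA = c("g1", "g2", "g3"), setB = "g4"))
})
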