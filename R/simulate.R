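# Synthetic WGBS / genotype / annotation / cohort generators with planted
# effects. Every generator is a pure function of (config, seed): the RNG
# state is localized, so identical inputs give identical outputs and the
# caller's stream is untouched.

#' Configuration for the synthetic methylome generator
#'
#' Defaults describe the package's standard desk-scale study: two groups of
#' five samples (the discovery design of a 5-vs-5 WGBS comparison), 15x mean
#' coverage, a 200 kb toy genome with ~100 bp mean CpG spacing, and 50
#' planted DMRs of 5-10 CpGs with a methylation shift of 0.3.
#'
#' @param genome a [genome_layout()].
#' @param n_cpgs total CpG count across the genome.
#' @param n_per_group samples per exposure group (>= 2).
#' @param mean_coverage mean reads per CpG (Poisson, truncated >= 1).
#' @param baseline_dispersion beta-binomial overdispersion rho in [0, 1);
#'   0 gives pure binomial counts.
#' @param n_true_dmrs number of planted DMRs (disjoint).
#' @param dmr_n_cpgs_range integer pair: CpGs per planted DMR.
#' @param dmr_effect planted between-group methylation difference (delta,
#'   fraction in (0, 1)); applied as +/- delta/2 around the baseline.
#' @param cpg_spacing_mean mean gap between CpGs in bp (geometric model).
#' @param pi_range range the smooth baseline methylation is squashed into;
#'   `c(1, 1)` forces all-methylated (degenerate option).
#' @param rw_sd step size of the latent baseline random walk.
#' @param seed integer seed.
#' @return list of class `methylome_sim_config`.
#' @export
methylome_sim_config <- function(genome = genome_layout("chr1", 200000),
                                 n_cpgs = 2000, n_per_group = 5,
                                 mean_coverage = 15,
                                 baseline_dispersion = 0.02,
                                 n_true_dmrs = 50,
                                 dmr_n_cpgs_range = c(5L, 10L),
                                 dmr_effect = 0.3,
                                 cpg_spacing_mean = 100,
                                 pi_range = c(0.2, 0.8),
                                 rw_sd = 0.1, seed = 1L) {
  stopifnot(n_per_group >= 2, mean_coverage > 0,
            baseline_dispersion >= 0, baseline_dispersion < 1,
            dmr_effect >= 0, dmr_effect < 1,
            length(dmr_n_cpgs_range) == 2,
            dmr_n_cpgs_range[1] >= 1,
            dmr_n_cpgs_range[1] <= dmr_n_cpgs_range[2])
  structure(as.list(environment()), class = "methylome_sim_config")
}

rbetabinom <- function(n, size, prob, rho) {
  prob <- pmin(pmax(prob, 0), 1)
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  shape <- 1 / rho - 1
  theta <- stats::rbeta(n, prob * shape, (1 - prob) * shape)
  # rbeta returns NaN/degenerate at prob 0 or 1; those CpGs are deterministic
  theta[prob == 0] <- 0; theta[prob == 1] <- 1
  stats::rbinom(n, size, theta)
}

rpois_trunc1 <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

#' Simulate a per-CpG bisulfite count table with planted DMRs
#'
#' CpG positions follow a geometric-gap model along each chromosome. A
#' latent baseline methylation pi is a random walk squashed into
#' `pi_range`. Inside each planted DMR the two groups are shifted by
#' +/- delta/2 with a random sign (balanced hyper/hypo in expectation).
#' Coverage is truncated Poisson; methylated counts are beta-binomial.
#'
#' @param config a [methylome_sim_config()].
#' @return list with `meth` (a [methylation_table()]) and `truth` (a
#'   `truth_set`: planted DMR table, baseline pi, CpG row indices).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "methylome_sim_config"))
  with_seed(config$seed, {
    g <- config$genome
    # CpG grid: allocate CpGs to chromosomes proportional to length
    alloc <- round(config$n_cpgs * as.numeric(g) / sum(as.numeric(g)))
    alloc[length(alloc)] <- config$n_cpgs - sum(alloc[-length(alloc)])
    chrom <- character(0); pos <- integer(0)
    for (i in seq_along(g)) {
      gaps <- 1L + stats::rgeom(alloc[i], 1 / config$cpg_spacing_mean)
      p <- cumsum(gaps)
      p <- p[p <= as.numeric(g)[i]]
      chrom <- c(chrom, rep(names(g)[i], length(p)))
      pos <- c(pos, p)
    }
    n <- length(pos)
    # latent baseline: random walk, squashed into pi_range
    z <- stats::rnorm(1)
    steps <- stats::rnorm(n - 1, 0, config$rw_sd)
    zz <- cumsum(c(z, steps))
    lo <- config$pi_range[1]; hi <- config$pi_range[2]
    pi_base <- lo + (hi - lo) * stats::plogis(zz)

    # plant disjoint DMRs (by CpG index, with a 2-CpG separation buffer)
    truth_dmrs <- plant_dmrs(chrom, pos, config)

    n_samp <- 2 * config$n_per_group
    groups <- rep(c("low", "high"), each = config$n_per_group)
    samples <- paste0(rep(c("low", "high"), each = config$n_per_group),
                      rep(seq_len(config$n_per_group), 2))
    dir_s <- ifelse(groups == "high", 1, -1)

    effect <- numeric(n)  # signed delta per CpG (0 outside planted DMRs)
    for (k in seq_len(nrow(truth_dmrs))) {
      idx <- truth_dmrs$first_idx[k]:truth_dmrs$last_idx[k]
      effect[idx] <- truth_dmrs$sign[k] * config$dmr_effect
    }
    total <- matrix(rpois_trunc1(n * n_samp, config$mean_coverage), n, n_samp)
    meth <- matrix(0L, n, n_samp)
    for (s in seq_len(n_samp)) {
      p_s <- pmin(pmax(pi_base + dir_s[s] * effect / 2, 0), 1)
      meth[, s] <- rbetabinom(n, total[, s], p_s, config$baseline_dispersion)
    }
    mt <- methylation_table(chrom, pos, meth, total, samples, groups)
    truth <- structure(list(dmrs = truth_dmrs, pi_baseline = pi_base,
                            effect = effect, config = config,
                            meqtls = NULL, cohort = NULL),
                       class = "truth_set")
    list(meth = mt, truth = truth)
  })
}

plant_dmrs <- function(chrom, pos, config) {
  n <- length(pos)
  k <- config$n_true_dmrs
  if (k == 0)
    return(data.frame(dmr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), first_idx = integer(),
                      last_idx = integer(), n_cpgs = integer(), sign = numeric(),
                      effect = numeric(), stringsAsFactors = FALSE))
  lens <- sample(seq(config$dmr_n_cpgs_range[1], config$dmr_n_cpgs_range[2]),
                 k, replace = TRUE)
  taken <- rep(FALSE, n)
  first <- integer(k); last <- integer(k)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      st <- sample.int(n - lens[i] + 1, 1)
      en <- st + lens[i] - 1
      buf <- max(1, st - 2):min(n, en + 2)
      if (chrom[st] == chrom[en] && !any(taken[buf])) {
        taken[st:en] <- TRUE
        first[i] <- st; last[i] <- en
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_input("cannot place %d disjoint DMRs of %d-%d CpGs on this grid",
                 k, config$dmr_n_cpgs_range[1], config$dmr_n_cpgs_range[2])
  }
  ord <- order(first)
  first <- first[ord]; last <- last[ord]; lens <- lens[ord]
  signs <- sample(rep(c(-1, 1), length.out = k))
  data.frame(dmr_id = sprintf("true_dmr_%03d", seq_len(k)),
             chrom = chrom[first],
             start = pos[first] - 1, end = as.numeric(pos[last]),
             first_idx = first, last_idx = last, n_cpgs = lens,
             sign = signs, effect = signs * config$dmr_effect,
             stringsAsFactors = FALSE)
}

#' Simulate genotypes with cis meQTLs for planted DMRs
#'
#' Background SNPs are placed uniformly (about one per 10 kb, so a typical
#' DMR cis window holds ~2 SNPs including the planted one) with
#' Hardy-Weinberg dosages at the given minor-allele frequency. For each of
#' `n_meqtls` planted DMRs, one SNP is placed within +/- `window_bp` of the
#' DMR and that SNP's dosage shifts the carrier's methylation inside the DMR
#' by `beta_meqtl` per allele (clipped to [0, 1]); methylated counts at the
#' affected CpGs are redrawn accordingly, so the returned methylation table
#' supersedes the input one.
#'
#' @param methylome a [methylation_table()] from [simulate_methylome()].
#' @param truth the matching `truth_set`.
#' @param n_meqtls number of planted DMRs to attach a meQTL to
#'   (<= number of planted DMRs).
#' @param beta_meqtl methylation shift per alternate allele.
#' @param maf minor-allele frequency of all SNPs.
#' @param seed integer seed.
#' @param window_bp cis window for meQTL placement (default 5000).
#' @param background_per_bp density of background SNPs (default 1/10000).
#' @return list with `geno` (a [genotype_table()]), `meth` (adjusted
#'   [methylation_table()]) and `truth` (updated, with a `meqtls` table).
#' @export
simulate_genotypes <- function(methylome, truth, n_meqtls, beta_meqtl, maf,
                               seed = 1L, window_bp = 5000,
                               background_per_bp = 1 / 10000) {
  stopifnot(inherits(methylome, "methylation_table"),
            inherits(truth, "truth_set"),
            n_meqtls <= nrow(truth$dmrs), maf >= 0, maf <= 1)
  with_seed(seed, {
    g <- truth$config$genome
    n_samp <- length(methylome$samples)
    # background SNPs, uniform over the genome
    n_bg <- round(sum(as.numeric(g)) * background_per_bp)
    bg_chrom <- sample(names(g), n_bg, replace = TRUE,
                       prob = as.numeric(g) / sum(as.numeric(g)))
    bg_pos <- vapply(bg_chrom, function(ch) sample.int(as.numeric(g[ch]), 1), 1)
    chrom <- bg_chrom; pos <- bg_pos
    ids <- sprintf("snp_bg_%04d", seq_len(n_bg))

    target <- if (n_meqtls > 0) sample.int(nrow(truth$dmrs), n_meqtls) else integer(0)
    target <- sort(target)
    meqtl_rows <- list()
    dos <- matrix(stats::rbinom(n_bg * n_samp, 2, maf), n_bg, n_samp)
    meth <- methylome$meth
    dir_s <- ifelse(methylome$groups == "high", 1, -1)
    for (k in target) {
      d <- truth$dmrs[k, ]
      win_lo <- max(1, d$start + 1 - window_bp)
      win_hi <- min(as.numeric(g[d$chrom]), d$end + window_bp)
      if (win_lo > win_hi)
        stop_input("no placement space within +/- %d bp of %s", window_bp, d$dmr_id)
      snp_pos <- sample(seq(win_lo, win_hi), 1)
      snp_dos <- stats::rbinom(n_samp, 2, maf)
      chrom <- c(chrom, d$chrom); pos <- c(pos, snp_pos)
      ids <- c(ids, sprintf("snp_meqtl_%s", d$dmr_id))
      dos <- rbind(dos, snp_dos)
      # redraw methylated counts inside the DMR with the dosage shift
      idx <- d$first_idx:d$last_idx
      # shift centered at dosage 1 so the per-allele slope is beta_meqtl
      # while heterozygote-mean methylation stays at the baseline (keeps
      # typical regions away from the [0, 1] clip)
      for (s in seq_len(n_samp)) {
        p <- truth$pi_baseline[idx] + dir_s[s] * d$effect / 2 +
          beta_meqtl * (snp_dos[s] - 1)
        p <- pmin(pmax(p, 0), 1)
        meth[idx, s] <- rbetabinom(length(idx), methylome$total[idx, s], p,
                                   truth$config$baseline_dispersion)
      }
      meqtl_rows[[length(meqtl_rows) + 1]] <-
        data.frame(variant_id = sprintf("snp_meqtl_%s", d$dmr_id),
                   dmr_id = d$dmr_id, chrom = d$chrom, pos = snp_pos,
                   beta = beta_meqtl, stringsAsFactors = FALSE)
    }
    geno <- genotype_table(chrom, pos, ids, dos, methylome$samples)
    meth_tab <- methylation_table(methylome$chrom, methylome$pos, meth,
                                  methylome$total, methylome$samples,
                                  methylome$groups)
    truth$meqtls <- if (length(meqtl_rows)) do.call(rbind, meqtl_rows) else
      data.frame(variant_id = character(), dmr_id = character(),
                 chrom = character(), pos = integer(), beta = numeric())
    list(geno = geno, meth = meth_tab, truth = truth)
  })
}

#' Simulate an annotation track enriched (or not) near planted DMRs
#'
#' A fraction `frac_near_dmrs` of intervals is centered on planted DMRs
#' (cycling through all of them); the remainder is placed uniformly on the
#' genome, length-preserving.
#'
#' @param genome a [genome_layout()].
#' @param truth a `truth_set` with planted DMRs.
#' @param n_intervals number of intervals to draw.
#' @param frac_near_dmrs fraction in [0, 1] centered on planted DMRs.
#' @param interval_len interval length in bp.
#' @param seed integer seed.
#' @return an [interval_set()].
#' @export
simulate_annotations <- function(genome, truth, n_intervals, frac_near_dmrs,
                                 interval_len = 500, seed = 1L) {
  stopifnot(frac_near_dmrs >= 0, frac_near_dmrs <= 1)
  if (n_intervals == 0)
    return(interval_set(character(), numeric(), numeric()))
  with_seed(seed, {
    n_near <- round(frac_near_dmrs * n_intervals)
    chrom <- character(0); start <- numeric(0)
    if (n_near > 0) {
      pick <- rep(seq_len(nrow(truth$dmrs)), length.out = n_near)
      ctr <- (truth$dmrs$start + truth$dmrs$end) / 2
      st <- pmax(0, round(ctr[pick] - interval_len / 2))
      st <- pmin(st, as.numeric(genome[truth$dmrs$chrom[pick]]) - interval_len)
      chrom <- c(chrom, truth$dmrs$chrom[pick]); start <- c(start, st)
    }
    n_unif <- n_intervals - n_near
    if (n_unif > 0) {
      ch <- sample(names(genome), n_unif, replace = TRUE,
                   prob = as.numeric(genome) / sum(as.numeric(genome)))
      st <- vapply(ch, function(c1)
        sample.int(as.numeric(genome[c1]) - interval_len + 1, 1) - 1, 1)
      chrom <- c(chrom, ch); start <- c(start, st)
    }
    interval_set(chrom, start, start + interval_len,
                 name = sprintf("ann_%04d", seq_len(n_intervals)),
                 genome = genome)
  })
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the package's reference perinatal study: 443 subjects, a
#' 20-item perceived-stress questionnaire scored 1-4, planted odds ratios of
#' 2.44 (high vs low stress) and 1.39 (medium vs low) on a binary wheeze
#' endpoint with ~9% baseline prevalence, and a positive biomarker with a
#' planted high-vs-low geometric-mean ratio of 1.5.
#'
#' @param n_subjects number of subjects.
#' @param stress_item_count questionnaire items (scored 1-4).
#' @param or_high,or_medium planted odds ratios vs the low-stress category.
#' @param baseline_wheeze_prob outcome probability in the low category at
#'   reference covariate values.
#' @param confounders named list of covariate specs; each element is a list
#'   with `type` ("binary" or "continuous"), `prob` (binary prevalence) or
#'   `mean`/`sd`, and `log_or` (effect on the outcome's log-odds).
#' @param biomarker_mr planted geometric-mean ratio (high vs low; medium
#'   gets the half-log step).
#' @param item_probs marginal distribution of a single item score 1-4.
#' @param item_loading correlation loading of items on the subject's latent
#'   stress (0-1).
#' @param seed integer seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 443, stress_item_count = 20,
                              or_high = 2.44, or_medium = 1.39,
                              baseline_wheeze_prob = 0.091,
                              confounders = list(
                                gender = list(type = "binary", prob = 0.51,
                                              log_or = 0.2)),
                              biomarker_mr = 1.5,
                              item_probs = c(0.45, 0.35, 0.15, 0.05),
                              item_loading = 0.7, seed = 1L) {
  stopifnot(or_high > 0, or_medium > 0,
            baseline_wheeze_prob > 0, baseline_wheeze_prob < 1,
            length(item_probs) == 4, abs(sum(item_probs) - 1) < 1e-8,
            biomarker_mr > 0)
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a subject-level cohort table with planted stress effects
#'
#' Each subject gets a latent stress level; questionnaire items load on it
#' and are thresholded to scores 1-4 with the configured marginal
#' distribution. The stress score is the mean item score; quartile
#' categories come from [categorize_stress()]. The binary wheeze outcome
#' follows a logistic model with the planted category log-odds plus
#' confounder terms; the biomarker is log-normal with the planted
#' multiplicative category effect.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (a data.frame of class `cohort_table`) and
#'   `truth` (planted effect sizes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    u <- stats::rnorm(n)
    lam <- config$item_loading
    cuts <- stats::qnorm(cumsum(config$item_probs))[1:3]
    items <- matrix(0L, n, config$stress_item_count)
    for (j in seq_len(config$stress_item_count)) {
      lat <- lam * u + sqrt(1 - lam^2) * stats::rnorm(n)
      items[, j] <- 1L + findInterval(lat, cuts)
    }
    score <- rowMeans(items)
    cat_res <- categorize_stress(score)
    stress_category <- cat_res$category

    lp <- stats::qlogis(config$baseline_wheeze_prob) +
      log(config$or_medium) * (stress_category == "medium") +
      log(config$or_high) * (stress_category == "high")
    cohort <- data.frame(subject_id = sprintf("subj_%05d", seq_len(n)),
                         stress_score = score,
                         stress_category = stress_category,
                         stringsAsFactors = FALSE)
    for (nm in names(config$confounders)) {
      sp <- config$confounders[[nm]]
      x <- if (identical(sp$type, "binary"))
        stats::rbinom(n, 1, sp$prob %||% 0.5)
      else stats::rnorm(n, sp$mean %||% 0, sp$sd %||% 1)
      cohort[[nm]] <- x
      lp <- lp + (sp$log_or %||% 0) * x
    }
    cohort$persistent_wheeze <- stats::rbinom(n, 1, stats::plogis(lp))
    step <- log(config$biomarker_mr) *
      c(low = 0, medium = 0.5, high = 1)[stress_category]
    cohort$biomarker <- exp(log(100) + step + stats::rnorm(n, 0, 0.5))
    attr(cohort, "psq_items") <- items
    class(cohort) <- c("cohort_table", "data.frame")
    truth <- structure(list(dmrs = NULL, meqtls = NULL,
                            cohort = list(or_high = config$or_high,
                                          or_medium = config$or_medium,
                                          biomarker_mr = config$biomarker_mr,
                                          cutpoints = cat_res$cutpoints)),
                       class = "truth_set")
    list(cohort = cohort, truth = truth)
  })
}
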