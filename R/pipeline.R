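# End-to-end orchestration: simulate -> dmr -> meqtl -> enrich -> cohort,
# driven by one config, with a machine-readable run manifest.

#' Write / read a cohort table as CSV
#' @param cohort a `cohort_table` data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a pipeline run configuration from YAML
#'
#' Validates the minimal schema before any compute: `outdir` is required;
#' every stage block must be a mapping; referenced input files (if any)
#' must exist.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$outdir)) stop_input("config error: 'outdir' is required")
  for (blk in c("methylome", "genotypes", "annotations", "cohort", "smooth",
                "call", "fdr", "meqtl", "enrichment"))
    if (!is.null(cfg[[blk]]) && !is.list(cfg[[blk]]))
      stop_input("config error: '%s' must be a mapping", blk)
  for (p in cfg$inputs)
    if (!file.exists(p)) stop_input("config error: input file missing: %s", p)
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages, in dependency order: simulate the methylome (+ genotypes,
#' annotation track, cohort), fit the DMR model, estimate the permutation
#' FDR, classify DMRs as gDMR/ngDMR, run shuffle-null enrichment, and
#' compute cohort statistics. All intermediate artifacts are written to
#' `outdir` in their standard formats; a JSON manifest records the package
#' version, seeds, parameters, file checksums and headline results.
#' Per-module seeds are derived deterministically from the global seed, so
#' the run is reproducible end to end and each module can be re-run
#' standalone.
#'
#' @param config list (see [read_run_config()]) or path to a YAML file.
#' @return the manifest (invisibly); also written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  paths <- list()

  sim <- stage("simulate_methylome", {
    args <- config$methylome %||% list()
    if (!is.null(args$genome))
      args$genome <- genome_layout(names(unlist(args$genome)),
                                   unlist(args$genome))
    args$seed <- derive_seed(seed, "methylome")
    simulate_methylome(do.call(methylome_sim_config, args))
  })
  gen <- stage("simulate_genotypes", {
    g <- config$genotypes %||% list()
    g$n_meqtls <- g$n_meqtls %||% min(10, nrow(sim$truth$dmrs))
    g$beta_meqtl <- g$beta_meqtl %||% 0.25
    g$maf <- g$maf %||% 0.3
    simulate_genotypes(sim$meth, sim$truth, n_meqtls = g$n_meqtls,
                       beta_meqtl = g$beta_meqtl, maf = g$maf,
                       seed = derive_seed(seed, "genotypes"))
  })
  ann <- stage("simulate_annotations", {
    a <- config$annotations %||% list(n_intervals = 100, frac_near_dmrs = 0.5,
                                      interval_len = 500)
    simulate_annotations(sim$truth$config$genome, gen$truth,
                         n_intervals = a$n_intervals,
                         frac_near_dmrs = a$frac_near_dmrs,
                         interval_len = a$interval_len %||% 500,
                         seed = derive_seed(seed, "annotations"))
  })
  coh <- stage("simulate_cohort", {
    args <- config$cohort %||% list()
    args$seed <- derive_seed(seed, "cohort")
    simulate_cohort(do.call(cohort_sim_config, args))
  })
  stage("write_inputs", {
    paths$methylation <- write_methylation(gen$meth,
                                            file.path(outdir, "methylation.tsv"))
    paths$genotypes <- write_genotypes(gen$geno, file.path(outdir, "snps.vcf"))
    paths$annotations <- write_intervals(ann, file.path(outdir, "annotations.bed"))
    paths$cohort <- write_cohort(coh$cohort, file.path(outdir, "cohort.csv"))
    paths$genome <- write_genome_layout(sim$truth$config$genome,
                                         file.path(outdir, "genome.tsv"))
  })

  fit <- stage("dmr", {
    sp <- do.call(smooth_params, config$smooth %||% list())
    cp <- do.call(dmr_call_params, config$call %||% list())
    fit_dmrs(gen$meth, smooth = sp, call = cp)
  })
  fdr <- stage("fdr", {
    estimate_fdr(fit, n_perms = (config$fdr %||% list())$n_perms %||% 20L,
                 seed = derive_seed(seed, "fdr"))
  })
  cls <- stage("meqtl", {
    mp <- do.call(meqtl_params, config$meqtl %||% list())
    classify_dmrs(fit$dmrs, gen$meth, gen$geno, mp)
  })
  stage("write_dmrs", {
    out <- cls$dmrs
    if (nrow(out) > 0) out$fdr <- fdr$fdr
    paths$dmrs <- write_dmrs(out, file.path(outdir, "dmrs.bed"))
  })
  enr <- stage("enrichment", {
    e <- config$enrichment %||% list()
    enrichment_z(cls$dmrs, ann, sim$truth$config$genome,
                 shuffle_params(n_shuffles = e$n_shuffles %||% 200L,
                                seed = derive_seed(seed, "enrichment")),
                 track_name = "annotations")
  })
  stats_out <- stage("cohort_stats", {
    raw <- cohort_or(coh$cohort, "persistent_wheeze", "stress_category",
                     reference = "low")
    adj <- logistic_adjusted_or(coh$cohort, "persistent_wheeze",
                                "stress_category",
                                covariates = intersect("gender",
                                                       names(coh$cohort)),
                                reference = "low")
    mr <- adjusted_mean_ratio(coh$cohort, "biomarker", "stress_category",
                              reference = "low")
    list(raw = raw, adjusted = adj, mean_ratio = mr)
  })
  stage("write_stats", {
    lines <- c("comparison\traw_or\tadjusted_or\tmean_ratio")
    for (lev in names(stats_out$raw))
      lines <- c(lines, sprintf("%s\t%.4f\t%.4f\t%.4f",
                                stats_out$raw[[lev]]$comparison,
                                stats_out$raw[[lev]]$odds_ratio,
                                stats_out$adjusted[[lev]]$odds_ratio,
                                stats_out$mean_ratio[[lev]]$mean_ratio))
    paths$stats <- file.path(outdir, "stats.tsv")
    writeLines(lines, paths$stats)
  })

  manifest <- list(
    package = "stresswgbs",
    version = as.character(utils::packageVersion("stresswgbs")),
    seed = seed,
    parameters = config[setdiff(names(config), "outdir")],
    checksums = as.list(tools::md5sum(unlist(paths))),
    results = list(
      n_dmrs = nrow(cls$dmrs),
      n_gdmr = cls$summary$n_gdmr,
      n_ngdmr = cls$summary$n_ngdmr,
      ngdmr_fraction = cls$summary$ngdmr_fraction,
      fdr = fdr$fdr,
      enrichment = list(track = enr$track_name, observed = enr$observed_overlap,
                        null_mean = enr$null_mean, null_sd = enr$null_sd,
                        z = enr$z, empirical_p = enr$empirical_p),
      odds_ratios = lapply(stats_out$raw, function(r)
        list(comparison = r$comparison, raw_or = r$odds_ratio)),
      mean_ratios = lapply(stats_out$mean_ratio, function(r) r$mean_ratio)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
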