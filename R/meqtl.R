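# gDMR / ngDMR classification: test correlation between cis SNP dosages and
# per-sample regional methylation.

#' meQTL testing parameters
#'
#' @param window_bp cis window on each side of the DMR (boundary inclusive
#'   at exactly `window_bp`).
#' @param alpha per-SNP significance level (no multiple-testing correction
#'   by default: the classification deliberately over-calls gDMRs; set
#'   `adjust = "BH"` for a corrected mode).
#' @param test `"pearson"`, `"spearman"`, or `"permutation"` (exact
#'   enumeration of the Pearson statistic, for small n).
#' @param min_called_samples minimum paired non-missing samples per test.
#' @param adjust `"none"` (default) or `"BH"` across SNPs within a DMR.
#' @return list of class `meqtl_params`.
#' @export
meqtl_params <- function(window_bp = 5000, alpha = 0.05, test = "pearson",
                         min_called_samples = 3L, adjust = "none") {
  stopifnot(window_bp >= 0, alpha > 0, alpha < 1,
            test %in% c("pearson", "spearman", "permutation"),
            adjust %in% c("none", "BH"))
  structure(list(window_bp = window_bp, alpha = alpha, test = test,
                 min_called_samples = as.integer(min_called_samples),
                 adjust = adjust),
            class = "meqtl_params")
}

#' Per-sample regional methylation of a DMR
#'
#' Coverage-weighted mean of raw methylation over the member CpGs:
#' sum(meth) / sum(total) per sample. Raw (not smoothed) counts are used so
#' no information leaks across the region boundary. A sample with zero
#' total coverage in the region gets NA.
#'
#' @param meth a [methylation_table()].
#' @param dmr one DMR record (a 1-row data.frame with chrom/start/end).
#' @return named numeric vector, one value per sample.
#' @export
regional_methylation <- function(meth, dmr) {
  sel <- meth$chrom == dmr$chrom & meth$pos >= dmr$start + 1 &
    meth$pos <= dmr$end
  if (!any(sel)) stop_input("DMR %s contains no covered CpG",
                            dmr$id %||% "<unnamed>")
  m <- colSums(meth$meth[sel, , drop = FALSE])
  n <- colSums(meth$total[sel, , drop = FALSE])
  out <- ifelse(n > 0, m / n, NA_real_)
  stats::setNames(out, meth$samples)
}

#' Variants within the cis window of a DMR
#'
#' Returns ids of variants with 1-based position in
#' `[start + 1 - window_bp, end + window_bp]` on the DMR's chromosome
#' (both boundaries inclusive).
#'
#' @param dmr one DMR record.
#' @param geno a [genotype_table()].
#' @param window_bp window size in bp.
#' @return character vector of variant ids.
#' @export
snps_near <- function(dmr, geno, window_bp = 5000) {
  sel <- geno$chrom == dmr$chrom &
    geno$pos >= dmr$start + 1 - window_bp &
    geno$pos <= dmr$end + window_bp
  geno$variant_id[sel]
}

# exact two-sided permutation p for the Pearson correlation (all n! orders)
perm_cor_pvalue <- function(x, y) {
  n <- length(x)
  perms <- all_permutations(n)
  r_obs <- stats::cor(x, y)
  r_perm <- vapply(perms, function(p) stats::cor(x, y[p]), numeric(1))
  mean(abs(r_perm) >= abs(r_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (i in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = i)
  out
}

#' Test one DMR-SNP pair for a methylation QTL
#'
#' Default: Pearson correlation with a two-sided p from the t distribution
#' on n - 2 df. A constant dosage vector or fewer than
#' `min_called_samples` complete pairs makes the pair untestable (never
#' significant).
#'
#' @param regional_meth per-sample regional methylation vector.
#' @param dosages per-sample dosage vector (0/1/2 or NA).
#' @param params a [meqtl_params()].
#' @return list of class `meqtl_result`: `statistic`, `p_value`,
#'   `significant`, `testable`, `n_used`.
#' @export
test_meqtl <- function(regional_meth, dosages, params = meqtl_params()) {
  ok <- !is.na(regional_meth) & !is.na(dosages)
  x <- regional_meth[ok]; y <- dosages[ok]
  untestable <- list(statistic = NA_real_, p_value = NA_real_,
                     significant = FALSE, testable = FALSE, n_used = sum(ok))
  class(untestable) <- "meqtl_result"
  if (sum(ok) < max(3L, params$min_called_samples)) return(untestable)
  if (stats::sd(y) == 0 || stats::sd(x) == 0) return(untestable)
  if (params$test == "permutation") {
    r <- stats::cor(x, y)
    p <- perm_cor_pvalue(x, y)
  } else {
    ct <- stats::cor.test(x, y, method = params$test, exact = FALSE)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(statistic = r, p_value = p,
                 significant = is.finite(p) && p < params$alpha,
                 testable = TRUE, n_used = sum(ok)),
            class = "meqtl_result")
}

#' Classify DMRs as genetically influenced (gDMR) or not (ngDMR)
#'
#' A DMR is a gDMR when at least one SNP within the cis window is
#' significantly correlated with its regional methylation; otherwise (or
#' when no SNP is testable) it is an ngDMR. The two labels partition the
#' input.
#'
#' @param dmrs DMR data.frame from [call_dmrs()].
#' @param meth a [methylation_table()].
#' @param geno a [genotype_table()].
#' @param params a [meqtl_params()].
#' @return list with `dmrs` (input with `class_label` and `meqtl_ids`
#'   filled), `tests` (per-pair results table) and `summary` (counts and
#'   ngDMR fraction).
#' @export
classify_dmrs <- function(dmrs, meth, geno, params = meqtl_params()) {
  tests <- list()
  labels <- character(nrow(dmrs))
  meqtl_ids <- character(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    d <- dmrs[i, ]
    rm_ <- regional_methylation(meth, d)
    ids <- snps_near(d, geno, params$window_bp)
    hits <- character(0)
    if (length(ids) > 0) {
      res <- lapply(ids, function(v) {
        dos <- geno$dosage[match(v, geno$variant_id), ]
        test_meqtl(rm_, dos, params)
      })
      pvals <- vapply(res, `[[`, numeric(1), "p_value")
      if (params$adjust == "BH") {
        padj <- stats::p.adjust(pvals, "BH")
        for (k in seq_along(res))
          res[[k]]$significant <- res[[k]]$testable && !is.na(padj[k]) &&
            padj[k] < params$alpha
      }
      sig <- vapply(res, `[[`, logical(1), "significant")
      hits <- ids[sig]
      tests[[length(tests) + 1]] <- data.frame(
        dmr_id = d$id, variant_id = ids,
        statistic = vapply(res, `[[`, numeric(1), "statistic"),
        p_value = pvals,
        significant = sig,
        testable = vapply(res, `[[`, logical(1), "testable"),
        stringsAsFactors = FALSE)
    }
    labels[i] <- if (length(hits) > 0) "gDMR" else "ngDMR"
    meqtl_ids[i] <- paste(hits, collapse = ",")
  }
  dmrs$class_label <- labels
  dmrs$meqtl_ids <- meqtl_ids
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(dmr_id = character(), variant_id = character(),
               statistic = numeric(), p_value = numeric(),
               significant = logical(), testable = logical())
  n_g <- sum(labels == "gDMR"); n_ng <- sum(labels == "ngDMR")
  list(dmrs = dmrs, tests = tests,
       summary = list(n_dmrs = nrow(dmrs), n_gdmr = n_g, n_ngdmr = n_ng,
                      ngdmr_fraction = if (nrow(dmrs)) n_ng / nrow(dmrs)
                      else NA_real_))
}
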