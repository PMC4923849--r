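# DMR detection from a t-statistic track, the dmr_fit model object, and
# permutation FDR estimation.

#' DMR calling parameters
#'
#' Defaults follow the reference thresholds: |t| > 4.5 over >= 3 consecutive
#' CpGs with a mean methylation difference above 10%. "Consecutive" is made
#' operational by `max_gap_bp`: neighboring member CpGs may be at most this
#' far apart.
#'
#' @param t_cutoff threshold on |t| per member CpG.
#' @param min_cpgs minimum member CpGs per region.
#' @param min_diff minimum |mean d| over member CpGs (fraction).
#' @param max_gap_bp maximum gap between neighboring member CpGs.
#' @return list of class `dmr_call_params`.
#' @export
dmr_call_params <- function(t_cutoff = 4.5, min_cpgs = 3L, min_diff = 0.10,
                            max_gap_bp = 300L) {
  stopifnot(t_cutoff > 0, min_cpgs >= 1, min_diff >= 0, max_gap_bp > 0)
  structure(list(t_cutoff = t_cutoff, min_cpgs = as.integer(min_cpgs),
                 min_diff = min_diff, max_gap_bp = as.integer(max_gap_bp)),
            class = "dmr_call_params")
}

#' Call DMRs from a t-statistic track
#'
#' Scans each chromosome for maximal runs of adjacent CpGs with
#' `|t| > t_cutoff`, constant sign, and neighboring positions at most
#' `max_gap_bp` apart; keeps runs with at least `min_cpgs` CpGs and
#' `|mean(d)| > min_diff`. Region bounds span first to last member CpG in
#' 0-based half-open coordinates. Direction is `hyper` when the high-stress
#' group is more methylated (`d > 0`), `hypo` otherwise.
#'
#' @param track a `tstat_track` from [compute_tstat()].
#' @param params a [dmr_call_params()].
#' @return data.frame of DMR records (possibly 0 rows): `chrom`, `start`,
#'   `end`, `id`, `area_stat`, `strand`, `n_cpgs`, `mean_diff`, `direction`,
#'   `class_label`, `fdr`.
#' @export
call_dmrs <- function(track, params = dmr_call_params()) {
  if (any(!is.finite(track$t))) stop_input("t track contains non-finite values")
  rows <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    n <- nrow(tr)
    pass <- abs(tr$t) > params$t_cutoff
    sgn <- sign(tr$t)
    # break between i and i+1 unless both pass with equal sign and small gap
    link <- pass[-n] & pass[-1] & sgn[-n] == sgn[-1] &
      diff(tr$pos) <= params$max_gap_bp
    run_id <- cumsum(c(TRUE, !link))
    for (r in split(seq_len(n), run_id)) {
      r <- r[pass[r]]
      if (length(r) < params$min_cpgs) next
      md <- mean(tr$d[r])
      if (abs(md) <= params$min_diff) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = tr$pos[r[1]] - 1, end = as.numeric(tr$pos[r[length(r)]]),
        id = NA_character_, area_stat = sum(tr$t[r]), strand = ".",
        n_cpgs = length(r), mean_diff = md,
        direction = if (md > 0) "hyper" else "hypo",
        class_label = "unclassified", fdr = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_dmr_table())
  out <- do.call(rbind, rows)
  out <- out[order(factor(out$chrom, levels = unique(track$chrom)), out$start), ]
  out$id <- sprintf("dmr_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Fit the DMR model: smooth, score, and call regions
#'
#' The package's central estimator. Smooths every sample's methylation
#' profile, computes the variance-floored t track between the high- and
#' low-exposure groups, and calls DMRs at the configured thresholds.
#'
#' @param meth a [methylation_table()].
#' @param smooth a [smooth_params()].
#' @param call a [dmr_call_params()].
#' @param floor_quantile variance-floor quantile (see [compute_tstat()]).
#' @return object of class `dmr_fit` with components `meth`, `smoothed`,
#'   `track`, `dmrs`, `params`. Methods: `print`, `summary`, `plot`,
#'   [estimate_fdr()].
#' @examples
#' sim <- simulate_methylome(methylome_sim_config(n_cpgs = 300, n_true_dmrs = 4,
#'   genome = genome_layout("chr1", 30000), seed = 7))
#' fit <- fit_dmrs(sim$meth, smooth = smooth_params(600, 7))
#' fit
#' @export
fit_dmrs <- function(meth, smooth = smooth_params(), call = dmr_call_params(),
                     floor_quantile = 0.75) {
  stopifnot(inherits(meth, "methylation_table"))
  smoothed <- smooth_all(meth, smooth)
  track <- compute_tstat(smoothed, meth$groups, meth$chrom, meth$pos,
                         floor_quantile)
  dmrs <- call_dmrs(track, call)
  structure(list(meth = meth, smoothed = smoothed, track = track, dmrs = dmrs,
                 params = list(smooth = smooth, call = call,
                               floor_quantile = floor_quantile)),
            class = "dmr_fit")
}

#' @export
print.dmr_fit <- function(x, ...) {
  cat(sprintf("dmr_fit: %d CpGs, %d samples; %d DMRs called (|t| > %g, >= %d CpGs, |d| > %g)\n",
              length(x$meth$pos), length(x$meth$samples), nrow(x$dmrs),
              x$params$call$t_cutoff, x$params$call$min_cpgs,
              x$params$call$min_diff))
  invisible(x)
}

#' @export
summary.dmr_fit <- function(object, ...) {
  d <- object$dmrs
  out <- list(n_cpgs = length(object$meth$pos),
              n_samples = length(object$meth$samples),
              n_dmrs = nrow(d),
              n_hyper = sum(d$direction == "hyper"),
              n_hypo = sum(d$direction == "hypo"),
              median_width = if (nrow(d)) stats::median(d$end - d$start) else NA,
              median_n_cpgs = if (nrow(d)) stats::median(d$n_cpgs) else NA,
              params = object$params)
  class(out) <- "summary.dmr_fit"
  out
}

#' @export
print.summary.dmr_fit <- function(x, ...) {
  cat(sprintf("DMR model fit on %d CpGs x %d samples\n", x$n_cpgs, x$n_samples))
  cat(sprintf("  DMRs: %d (%d hyper / %d hypo)\n", x$n_dmrs, x$n_hyper, x$n_hypo))
  if (x$n_dmrs > 0)
    cat(sprintf("  median width %g bp, median %g CpGs\n",
                x$median_width, x$median_n_cpgs))
  invisible(x)
}

#' Plot smoothed methylation around a DMR
#'
#' Raw per-sample methylation proportions (points, sized by coverage) and
#' smoothed curves, colored by exposure group, for the region around one
#' called DMR (shaded).
#'
#' @param x a `dmr_fit`.
#' @param dmr index or id of the DMR to show.
#' @param flank_bp flanking context on each side.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dmr_fit <- function(x, dmr = 1L, flank_bp = 2000, ...) {
  d <- if (is.character(dmr)) x$dmrs[x$dmrs$id == dmr, ] else x$dmrs[dmr, ]
  if (nrow(d) != 1) stop_input("no such DMR")
  sel <- x$meth$chrom == d$chrom & x$meth$pos >= d$start + 1 - flank_bp &
    x$meth$pos <= d$end + flank_bp
  pos <- x$meth$pos[sel]
  cols <- ifelse(x$meth$groups == "high", "firebrick", "steelblue")
  graphics::plot(NA, xlim = range(pos), ylim = c(0, 1),
                 xlab = sprintf("%s position (bp)", d$chrom),
                 ylab = "methylation", ...)
  graphics::rect(d$start + 1, 0, d$end, 1, col = "grey90", border = NA)
  for (s in seq_along(x$meth$samples)) {
    prop <- x$meth$meth[sel, s] / pmax(x$meth$total[sel, s], 1)
    graphics::points(pos, prop, col = grDevices::adjustcolor(cols[s], 0.4),
                     pch = 16, cex = 0.5)
    graphics::lines(pos, x$smoothed[sel, s], col = cols[s])
  }
  graphics::legend("topright", legend = c("high", "low"), bty = "n",
                   col = c("firebrick", "steelblue"), lty = 1)
  invisible(x)
}

#' Balanced group-label permutations
#'
#' Enumerates distinct balanced relabelings of the samples (identity
#' excluded). For equal group sizes, a relabeling and its complement give
#' identical DMR calls up to sign and are counted once (e.g. 5-vs-5 yields
#' choose(10,5)/2 - 1 = 125).
#'
#' @param groups character vector of `"low"`/`"high"` labels.
#' @param n_perms maximum number to return; sampled without replacement
#'   when fewer than the number available.
#' @param seed integer seed for the subsample.
#' @return list of label vectors.
#' @export
balanced_permutations <- function(groups, n_perms, seed = 1L) {
  n <- length(groups)
  n_lo <- sum(groups == "low")
  combs <- utils::combn(n, n_lo, simplify = FALSE)
  if (n_lo == n - n_lo)  # complement-equivalent: keep those containing sample 1
    combs <- Filter(function(s) 1L %in% s, combs)
  labs <- lapply(combs, function(s) ifelse(seq_len(n) %in% s, "low", "high"))
  labs <- Filter(function(l) !identical(l, unname(groups)) &&
                   !identical(l, ifelse(groups == "low", "high", "low")), labs)
  if (length(labs) > n_perms)
    labs <- with_seed(seed, labs[sample.int(length(labs), n_perms)])
  labs
}

#' Estimate the DMR false discovery rate by balanced permutation
#'
#' Re-runs the t-statistic computation and region calling under balanced
#' permutations of the group labels (smoothing is per-sample and does not
#' change). FDR = mean null DMR count / observed DMR count; when nothing is
#' observed the FDR is reported as 1 by convention.
#'
#' @param object a `dmr_fit`.
#' @param n_perms number of permutations (all distinct ones are used when
#'   fewer are available).
#' @param seed integer seed.
#' @param ... unused.
#' @return list of class `dmr_fdr`: `fdr`, `n_observed`, `null_counts`,
#'   `n_perms`.
#' @export
estimate_fdr <- function(object, ...) UseMethod("estimate_fdr")

#' @rdname estimate_fdr
#' @export
estimate_fdr.dmr_fit <- function(object, n_perms = 100L, seed = 1L, ...) {
  if (n_perms < 1) stop_input("n_perms must be >= 1")
  perms <- balanced_permutations(object$meth$groups, n_perms, seed)
  null_counts <- vapply(perms, function(labs) {
    tr <- compute_tstat(object$smoothed, labs, object$meth$chrom,
                        object$meth$pos, object$params$floor_quantile)
    nrow(call_dmrs(tr, object$params$call))
  }, integer(1))
  n_obs <- nrow(object$dmrs)
  fdr <- if (n_obs == 0) 1.0 else mean(null_counts) / n_obs
  structure(list(fdr = fdr, n_observed = n_obs, null_counts = null_counts,
                 n_perms = length(perms)), class = "dmr_fdr")
}

#' @export
print.dmr_fdr <- function(x, ...) {
  cat(sprintf("permutation FDR: %.3g (observed %d DMRs, null mean %.2f over %d permutations)\n",
              x$fdr, x$n_observed, mean(x$null_counts), x$n_perms))
  invisible(x)
}

#' Compare called DMRs against a planted truth set
#'
#' Sensitivity = fraction of planted DMRs overlapped (>= 1 bp) by a call;
#' precision = fraction of calls overlapping a planted DMR.
#'
#' @param dmrs called DMR data.frame.
#' @param truth a `truth_set` with a `dmrs` table.
#' @return list with `sensitivity`, `precision`, `n_called`, `n_true`.
#' @export
dmr_recovery <- function(dmrs, truth) {
  tr <- truth$dmrs
  ts <- interval_set(tr$chrom, tr$start, tr$end)
  if (nrow(dmrs) == 0)
    return(list(sensitivity = 0, precision = NA_real_, n_called = 0,
                n_true = nrow(tr)))
  cs <- interval_set(dmrs$chrom, dmrs$start, dmrs$end)
  list(sensitivity = overlap_count(ts, cs) / nrow(tr),
       precision = overlap_count(cs, ts) / nrow(dmrs),
       n_called = nrow(dmrs), n_true = nrow(tr))
}
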