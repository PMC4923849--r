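# Per-CpG signal-to-noise statistic on smoothed profiles: group mean
# difference over a variance-floored pooled standard error.

#' Compute the floored t-statistic track
#'
#' At each CpG, `d = mean(high) - mean(low)` of smoothed methylation; the
#' raw standard error uses equal-variance pooling with the two-sample t
#' denominator `sp * sqrt(1/n1 + 1/n2)`. Raw standard errors are floored at
#' a genome-wide quantile (default 75th) before dividing, which prevents
#' spurious t explosions at low-variance CpGs.
#'
#' @param smoothed matrix (CpG x sample) from [smooth_all()].
#' @param groups per-sample labels `"low"`/`"high"` (>= 2 each).
#' @param chrom,pos per-CpG coordinates (same order as `smoothed` rows).
#' @param floor_quantile quantile of raw standard errors used as the floor.
#' @return data.frame of class `tstat_track` with columns `chrom`, `pos`,
#'   `mean_low`, `mean_high`, `d`, `se_raw`, `se`, `t`.
#' @export
compute_tstat <- function(smoothed, groups, chrom, pos, floor_quantile = 0.75) {
  smoothed <- unclass(smoothed)
  if (length(groups) != ncol(smoothed))
    stop_input("one group label per sample column required")
  i_lo <- which(groups == "low"); i_hi <- which(groups == "high")
  n1 <- length(i_hi); n2 <- length(i_lo)
  if (n1 < 2 || n2 < 2)
    stop_input("need >= 2 samples per group for a variance estimate")
  m_lo <- rowMeans(smoothed[, i_lo, drop = FALSE])
  m_hi <- rowMeans(smoothed[, i_hi, drop = FALSE])
  v_lo <- apply(smoothed[, i_lo, drop = FALSE], 1, stats::var)
  v_hi <- apply(smoothed[, i_hi, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v_hi + (n2 - 1) * v_lo) / (n1 + n2 - 2)
  se_raw <- sqrt(sp2 * (1 / n1 + 1 / n2))
  floor <- stats::quantile(se_raw, floor_quantile, names = FALSE)
  se <- pmax(se_raw, floor)
  d <- m_hi - m_lo
  t <- ifelse(se > 0, d / se, 0)
  structure(data.frame(chrom = chrom, pos = pos, mean_low = m_lo,
                       mean_high = m_hi, d = d, se_raw = se_raw, se = se,
                       t = t, stringsAsFactors = FALSE),
            class = c("tstat_track", "data.frame"))
}
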