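# Local-likelihood smoothing of per-sample methylation along the genome.
#
# At every CpG a weighted second-degree polynomial in genomic position is
# fitted to the count-derived proportions over the smallest symmetric window
# satisfying both a bp and a CpG-count minimum; weights are
# total_count x tricube(distance / halfwidth). The smoothed value is the fit
# evaluated at the CpG, clipped to [0, 1].

#' Smoothing parameters
#'
#' Defaults (window >= 2 kb and >= 70 CpGs, tricube kernel, local quadratic)
#' are the established choices for genome-scale bisulfite data. For sparse or
#' short simulated genomes a bandwidth matched to the expected DMR span
#' (a few hundred bp / 5-15 CpGs) resolves short regions that the
#' genome-scale window would average away.
#'
#' @param min_window_bp minimum window span in bp.
#' @param min_window_cpgs minimum CpGs in the window.
#' @return list of class `smooth_params`.
#' @export
smooth_params <- function(min_window_bp = 2000, min_window_cpgs = 70) {
  stopifnot(min_window_bp >= 1, min_window_cpgs >= 1)
  structure(list(min_window_bp = min_window_bp,
                 min_window_cpgs = min_window_cpgs),
            class = "smooth_params")
}

tricube <- function(u) {
  w <- (1 - abs(u)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

# halfwidth per CpG: max(min_bp/2, distance needed to cover min_cpgs points)
window_halfwidths <- function(pos, min_bp, min_cpgs) {
  n <- length(pos)
  m <- min(min_cpgs, n)  # fewer CpGs than the minimum: whole chromosome
  h <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - m + 1L)
    hi <- min(i, n - m + 1L)
    best <- Inf
    for (w in lo:hi)
      best <- min(best, max(pos[i] - pos[w], pos[w + m - 1L] - pos[i]))
    h[i] <- max(min_bp / 2, best)
  }
  h
}

smooth_chromosome <- function(pos, M, N, params) {
  if (all(N == 0)) return(rep(NA_real_, length(pos)))
  h <- window_halfwidths(pos, params$min_window_bp, params$min_window_cpgs)
  prop <- ifelse(N > 0, M / N, NA_real_)
  out <- numeric(length(pos))
  for (i in seq_along(pos)) {
    # widen fractionally so window-edge CpGs keep nonzero tricube weight
    hi <- h[i] * (1 + 1e-9)
    idx <- which(abs(pos - pos[i]) <= h[i] & N > 0)
    if (length(idx) == 0) idx <- which(N > 0)  # fully uncovered window
    d <- pos[idx] - pos[i]
    w <- N[idx] * tricube(d / max(hi, max(abs(d)) * (1 + 1e-9)))
    if (sum(w > 0) < 3 || length(unique(d[w > 0])) < 3) {
      out[i] <- sum(w * prop[idx]) / sum(w)
      next
    }
    X <- cbind(1, d, d^2)
    fit <- stats::lm.wfit(X, prop[idx], w)
    out[i] <- fit$coefficients[1]
  }
  pmin(pmax(out, 0), 1)
}

#' Smooth one sample's methylation profile
#'
#' @param meth a [methylation_table()].
#' @param sample sample id (must be in `meth$samples`).
#' @param params a [smooth_params()].
#' @return numeric vector of smoothed methylation fractions in [0, 1],
#'   aligned with the rows of `meth`.
#' @export
smooth_sample <- function(meth, sample, params = smooth_params()) {
  stopifnot(inherits(meth, "methylation_table"))
  s <- match(sample, meth$samples)
  if (is.na(s)) stop_input("unknown sample: %s", sample)
  out <- numeric(length(meth$pos))
  for (ch in unique(meth$chrom)) {
    sel <- meth$chrom == ch
    v <- smooth_chromosome(meth$pos[sel], meth$meth[sel, s], meth$total[sel, s],
                           params)
    if (anyNA(v)) stop_input("chromosome %s has zero coverage everywhere", ch)
    out[sel] <- v
  }
  out
}

#' Smooth all samples
#'
#' @inheritParams smooth_sample
#' @return matrix (CpG x sample) of smoothed fractions, class
#'   `smoothed_profile`, with columns named by sample.
#' @export
smooth_all <- function(meth, params = smooth_params()) {
  out <- vapply(meth$samples, function(s) smooth_sample(meth, s, params),
                numeric(length(meth$pos)))
  structure(out, class = c("smoothed_profile", class(out)))
}
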