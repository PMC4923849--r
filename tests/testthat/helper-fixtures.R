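# Fixture builders and independent oracle implementations used across tests.
# Oracles deliberately take the brute-force route (double loops, exhaustive
# enumeration, explicit normal equations) so they share no code path with
# the package.

# small hand-specified methylation table
tiny_meth <- function(chrom = rep("chr1", 3), pos = c(100L, 200L, 300L),
                      meth = matrix(c(1, 2, 3, 4, 5, 6), 3, 2),
                      total = matrix(10, 3, 2),
                      samples = c("s1", "s2"),
                      groups = c("low", "high")) {
  methylation_table(chrom, pos, meth, total, samples, groups)
}

# methylation TSV fixture on disk; returns the path
write_meth_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# balanced two-group table with given per-group sample count and proportions
group_meth <- function(props_low, props_high, n_per_group = 5, coverage = 100,
                       pos = NULL) {
  n <- length(props_low)
  pos <- pos %||% seq(100, by = 100, length.out = n)
  meth <- cbind(matrix(rep(round(props_low * coverage), n_per_group), n),
                matrix(rep(round(props_high * coverage), n_per_group), n))
  methylation_table(rep("chr1", n), pos, meth,
                    matrix(coverage, n, 2 * n_per_group),
                    paste0("s", seq_len(2 * n_per_group)),
                    rep(c("low", "high"), each = n_per_group))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles ----------------------------------------------------------------

# weighted quadratic fit by explicit normal equations, evaluated at x0
wls_quadratic_oracle <- function(x, y, w, x0) {
  d <- x - x0
  X <- cbind(1, d, d^2)
  beta <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
  beta[1]
}

# exhaustive DMR scan: every (start, end) index pair is checked directly
call_dmrs_oracle <- function(track, t_cutoff = 4.5, min_cpgs = 3,
                             min_diff = 0.10, max_gap_bp = 300) {
  found <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    n <- nrow(tr)
    for (i in seq_len(n)) for (j in i:n) {
      idx <- i:j
      if (length(idx) < min_cpgs) next
      if (!all(abs(tr$t[idx]) > t_cutoff)) next
      if (length(unique(sign(tr$t[idx]))) != 1) next
      if (length(idx) > 1 && any(diff(tr$pos[idx]) > max_gap_bp)) next
      # maximality: not extendable left or right
      ext_l <- i > 1 && abs(tr$t[i - 1]) > t_cutoff &&
        sign(tr$t[i - 1]) == sign(tr$t[i]) && tr$pos[i] - tr$pos[i - 1] <= max_gap_bp
      ext_r <- j < n && abs(tr$t[j + 1]) > t_cutoff &&
        sign(tr$t[j + 1]) == sign(tr$t[j]) && tr$pos[j + 1] - tr$pos[j] <= max_gap_bp
      if (ext_l || ext_r) next
      if (abs(mean(tr$d[idx])) <= min_diff) next
      found[[length(found) + 1]] <- data.frame(
        chrom = ch, start = tr$pos[i] - 1, end = tr$pos[j],
        n_cpgs = length(idx), mean_diff = mean(tr$d[idx]))
    }
  }
  if (!length(found)) return(NULL)
  out <- do.call(rbind, found)
  out[order(out$chrom, out$start), ]
}

# quadratic double-loop overlap count
overlap_count_oracle <- function(dmrs, track) {
  hit <- 0L
  for (i in seq_len(nrow(dmrs))) {
    any_hit <- FALSE
    for (j in seq_len(nrow(track)))
      if (dmrs$chrom[i] == track$chrom[j] &&
          dmrs$start[i] < track$end[j] && track$start[j] < dmrs$end[i])
        any_hit <- TRUE
    hit <- hit + any_hit
  }
  hit
}

# hypergeometric upper tail by direct summation of the mass function
hyper_tail_oracle <- function(overlap, set_size, universe_size, draw) {
  sum(vapply(overlap:min(set_size, draw), function(k)
    choose(set_size, k) * choose(universe_size - set_size, draw - k) /
      choose(universe_size, draw), numeric(1)))
}

# all permutations of 1..n by iterative insertion (independent of the
# package's recursive generator)
perms_oracle <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out) for (pos in 0:(k - 1))
      nxt[[length(nxt) + 1]] <- append(p, k, after = pos)
    out <- nxt
  }
  out
}
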