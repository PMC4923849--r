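# Annotation-overlap enrichment against a length-preserving shuffle null,
# array-CpG overlap fractions, gene assignment and gene-set enrichment.

#' Shuffle-null parameters
#'
#' @param n_shuffles number of random repositionings.
#' @param within_chromosome keep each shuffled interval on its chromosome
#'   (default) or move it anywhere on the genome.
#' @param exclude optional [interval_set()] of forbidden regions
#'   (e.g. assembly gaps); placements intersecting it are redrawn.
#' @param seed integer seed.
#' @return list of class `shuffle_params`.
#' @export
shuffle_params <- function(n_shuffles = 1000L, within_chromosome = TRUE,
                           exclude = NULL, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  structure(list(n_shuffles = as.integer(n_shuffles),
                 within_chromosome = within_chromosome,
                 exclude = exclude, seed = seed),
            class = "shuffle_params")
}

#' Count DMRs overlapping an annotation track
#'
#' Number of query regions with at least 1 bp intersection with at least one
#' track interval (each region counted once). Depends only on the bases the
#' track covers, so merging adjacent track intervals does not change it.
#'
#' @param dmrs data.frame with chrom/start/end (0-based half-open), e.g.
#'   from [call_dmrs()] or an [interval_set()].
#' @param track an [interval_set()] (or any chrom/start/end data.frame).
#' @return integer count.
#' @export
overlap_count <- function(dmrs, track) {
  if (nrow(dmrs) == 0 || nrow(track) == 0) return(0L)
  n <- 0L
  track_by <- split(track, track$chrom)
  for (ch in unique(dmrs$chrom)) {
    tr <- track_by[[ch]]
    if (is.null(tr)) next
    q <- IRanges::IRanges(dmrs$start[dmrs$chrom == ch] + 1,
                          dmrs$end[dmrs$chrom == ch])
    s <- IRanges::IRanges(tr$start + 1, tr$end)
    n <- n + sum(IRanges::countOverlaps(q, s) > 0)
  }
  n
}

#' Randomly reposition DMRs, preserving lengths and chromosomes
#'
#' Each region is replaced by an interval of identical length placed
#' uniformly at random (on the same chromosome by default). Placements are
#' independent; overlaps among shuffled intervals are allowed. A placement
#' intersecting the exclude set is redrawn (up to 10000 attempts).
#'
#' @param dmrs data.frame with chrom/start/end.
#' @param genome a [genome_layout()].
#' @param params a [shuffle_params()] (only `within_chromosome` and
#'   `exclude` are used; seeding is the caller's job).
#' @return an [interval_set()] of shuffled placements.
#' @export
shuffle_dmrs <- function(dmrs, genome, params = shuffle_params()) {
  k <- nrow(dmrs)
  len <- dmrs$end - dmrs$start
  chrom <- character(k); start <- numeric(k)
  for (i in seq_len(k)) {
    for (attempt in seq_len(10000)) {
      ch <- if (params$within_chromosome) dmrs$chrom[i] else
        sample(names(genome), 1, prob = as.numeric(genome) / sum(as.numeric(genome)))
      space <- as.numeric(genome[ch]) - len[i]
      if (space < 0)
        stop_input("region %s (%d bp) exceeds chromosome %s",
                   dmrs$id[i] %||% i, len[i], ch)
      st <- sample.int(space + 1, 1) - 1
      if (!is.null(params$exclude)) {
        cand <- data.frame(chrom = ch, start = st, end = st + len[i])
        if (overlap_count(cand, params$exclude) > 0) next
      }
      chrom[i] <- ch; start[i] <- st
      break
    }
    if (chrom[i] == "")
      stop_input("cannot place region %s outside the exclude set",
                 dmrs$id[i] %||% i)
  }
  interval_set(chrom, start, start + len, genome = genome)
}

#' Overlap enrichment z-score against the shuffle null
#'
#' Observed = [overlap_count()] of the regions with the track; the null
#' distribution is the same count over `n_shuffles` random repositionings.
#' z = (observed - null mean) / null sd; the empirical p uses the add-one
#' estimator `(1 + #\{null >= observed\}) / (n_shuffles + 1)` and is never 0.
#' When the null is degenerate (sd = 0) the z is NA and flagged.
#'
#' @param dmrs data.frame with chrom/start/end.
#' @param track an [interval_set()].
#' @param genome a [genome_layout()].
#' @param params a [shuffle_params()].
#' @param track_name label carried into the result.
#' @return list of class `enrichment_result`: `track_name`,
#'   `observed_overlap`, `null_mean`, `null_sd`, `z`, `empirical_p`,
#'   `n_shuffles`, `degenerate_null`, `above_upper_5pct`, `shown`
#'   (reporting flag: z above the standard-normal 10% upper tail).
#' @export
enrichment_z <- function(dmrs, track, genome, params = shuffle_params(),
                         track_name = "track") {
  if (params$n_shuffles < 30)
    stop_input("need >= 30 shuffles for a z-score")
  observed <- overlap_count(dmrs, track)
  null <- with_seed(params$seed, vapply(seq_len(params$n_shuffles), function(i)
    overlap_count(shuffle_dmrs(dmrs, genome, params), track), integer(1)))
  mu <- mean(null); sdv <- stats::sd(null)
  z <- if (sdv > 0) (observed - mu) / sdv else NA_real_
  structure(list(track_name = track_name, observed_overlap = observed,
                 null_mean = mu, null_sd = sdv, z = z,
                 empirical_p = (1 + sum(null >= observed)) /
                   (params$n_shuffles + 1),
                 n_shuffles = params$n_shuffles,
                 degenerate_null = sdv == 0,
                 above_upper_5pct = !is.na(z) && z > stats::qnorm(0.95),
                 shown = !is.na(z) && z > stats::qnorm(0.90)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: observed %d, null %.2f +/- %.2f, z = %s, empirical p = %.4g%s\n",
              x$track_name, x$observed_overlap, x$null_mean, x$null_sd,
              if (is.na(x$z)) "NA (degenerate null)" else sprintf("%.2f", x$z),
              x$empirical_p,
              if (x$above_upper_5pct) " (above 5% upper tail)" else ""))
  invisible(x)
}

#' Fraction of DMRs containing an array CpG
#'
#' How many regions contain at least one CpG position from a fixed array
#' catalog (e.g. a 450K manifest), and the corresponding fraction.
#'
#' @param dmrs data.frame with chrom/start/end.
#' @param array_cpgs an [interval_set()] of single-base positions (BED:
#'   start = pos - 1, end = pos) or a data.frame with chrom/pos columns.
#' @return list with `count`, `fraction` (NA when there are no regions) and
#'   `percent` (rounded to 1 decimal).
#' @export
array_overlap <- function(dmrs, array_cpgs) {
  if (!is.null(array_cpgs$pos) && is.null(array_cpgs$start))
    array_cpgs <- interval_set(array_cpgs$chrom, array_cpgs$pos - 1,
                               array_cpgs$pos)
  if (nrow(dmrs) == 0)
    return(list(count = 0L, fraction = NA_real_, percent = NA_real_))
  cnt <- overlap_count(dmrs, array_cpgs)
  frac <- cnt / nrow(dmrs)
  list(count = cnt, fraction = frac, percent = round(100 * frac, 1))
}

#' Assign DMRs to genes by body (+ flank) overlap
#'
#' A region maps to every gene whose body extended by `flank_bp` on each
#' side it overlaps by >= 1 bp. Default flank is 0 (gene-body overlap only).
#'
#' @param dmrs data.frame with chrom/start/end and ids.
#' @param genes a named [interval_set()] (gene bodies).
#' @param flank_bp flank in bp added to each gene side.
#' @return named list: per DMR id, a character vector of gene names.
#' @export
assign_genes <- function(dmrs, genes, flank_bp = 0) {
  stopifnot(!any(is.na(genes$name)))
  out <- stats::setNames(vector("list", nrow(dmrs)),
                         dmrs$id %||% seq_len(nrow(dmrs)))
  gstart <- pmax(0, genes$start - flank_bp)
  gend <- genes$end + flank_bp
  for (i in seq_len(nrow(dmrs))) {
    hit <- genes$chrom == dmrs$chrom[i] & gstart < dmrs$end[i] &
      gend > dmrs$start[i]
    out[[i]] <- genes$name[hit]
  }
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated: name, description, then
#' member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1))
}

#' Hypergeometric gene-set enrichment for DMR-associated genes
#'
#' One-sided hypergeometric test per set: probability of the observed
#' overlap or greater when drawing `|dmr_genes|` genes from the universe.
#' Sets are intersected with the universe first; p-values are BH-adjusted
#' across sets.
#'
#' @param dmr_genes character vector of genes hit by DMRs (subset of
#'   `universe`).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of all assayable genes.
#' @return data.frame: `set_name`, `n_set_genes`, `n_dmr_genes`, `overlap`,
#'   `p_value`, `q_value`, sorted by p.
#' @export
geneset_enrichment <- function(dmr_genes, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_input("empty gene universe")
  dmr_genes <- unique(dmr_genes)
  if (!all(dmr_genes %in% universe))
    stop_input("dmr_genes outside the universe: %s",
               paste(utils::head(setdiff(dmr_genes, universe), 3), collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(set, dmr_genes))
    # P(X >= ov), X ~ Hypergeom(white = |set|, black = |universe| - |set|,
    # drawn = |dmr_genes|)
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(dmr_genes), lower.tail = FALSE)
    data.frame(set_name = nm, n_set_genes = length(set),
               n_dmr_genes = length(dmr_genes), overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value), ]
}
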