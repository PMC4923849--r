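# Shared genomic data model and file I/O.
#
# Coordinate discipline: CpG and SNP positions are 1-based (VCF convention);
# all intervals are 0-based half-open (BED convention). The two converters
# below own the +/- 1 arithmetic; nothing else in the package does it.

#' Describe a genome as named chromosome lengths
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of lengths in bp, all positive.
#' @return a `genome_layout` object (named integer vector of lengths).
#' @examples
#' g <- genome_layout(c("chr1", "chr2"), c(1e5, 5e4))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  if (length(chrom_names) != length(chrom_lengths))
    stop_input("chrom_names and chrom_lengths differ in length")
  if (anyDuplicated(chrom_names)) stop_input("chromosome names must be unique")
  if (any(chrom_lengths <= 0)) stop_input("chromosome lengths must be > 0")
  structure(stats::setNames(as.numeric(chrom_lengths), chrom_names),
            class = "genome_layout")
}

#' Read a genome layout from a two-column TSV (name, length)
#' @param path file path.
#' @return a [genome_layout()].
#' @export
read_genome_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' Write a genome layout as a two-column TSV
#' @param genome a [genome_layout()].
#' @param path file path.
#' @export
write_genome_layout <- function(genome, path) {
  utils::write.table(data.frame(names(genome), as.numeric(genome)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Convert a 1-based inclusive position range to 0-based half-open
#'
#' @param first,last 1-based positions (first <= last).
#' @return list with `start` and `end`, 0-based half-open.
#' @export
pos_to_interval <- function(first, last = first) {
  stopifnot(all(first <= last))
  list(start = first - 1, end = last)
}

#' Convert a 0-based half-open interval to 1-based inclusive positions
#' @param start,end 0-based half-open bounds (start < end).
#' @return list with `first` and `last`, 1-based inclusive.
#' @export
interval_to_pos <- function(start, end) {
  stopifnot(all(start < end))
  list(first = start + 1, last = end)
}

# ---- IntervalSet ------------------------------------------------------------

#' Construct a validated interval set (0-based half-open)
#'
#' @param chrom character vector.
#' @param start,end numeric vectors, 0-based half-open, start < end.
#' @param name optional character vector of interval names.
#' @param genome optional [genome_layout()] to bound-check against.
#' @return data.frame of class `interval_set` with columns chrom/start/end/name.
#' @export
interval_set <- function(chrom, start, end, name = NULL, genome = NULL) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop_input("chrom, start, end must have equal length")
  if (any(start >= end))
    stop_input("invalid interval: start >= end at row %d", which(start >= end)[1])
  if (any(start < 0)) stop_input("negative interval start")
  if (!is.null(genome)) {
    if (!all(chrom %in% names(genome)))
      stop_input("interval chromosome not in genome layout: %s",
                 setdiff(chrom, names(genome))[1])
    if (any(end > as.numeric(genome)[match(chrom, names(genome))]))
      stop_input("interval extends beyond chromosome end")
  }
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   name = if (is.null(name)) rep(NA_character_, n)
                          else as.character(name),
                   stringsAsFactors = FALSE)
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Read a BED3+ file as an interval set
#'
#' Columns beyond the third are kept only when a fourth (name) column exists.
#' Intervals are returned as stored: 0-based half-open, not merged, order
#' preserved.
#'
#' @param path BED file path.
#' @param genome optional [genome_layout()] for bound checks.
#' @return an [interval_set()].
#' @export
read_intervals <- function(path, genome = NULL) {
  if (file.size(path) == 0)
    return(interval_set(character(), numeric(), numeric()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop_input("BED file needs >= 3 columns: %s", path)
  interval_set(df[[1]], df[[2]], df[[3]],
               name = if (ncol(df) >= 4) df[[4]] else NULL, genome = genome)
}

#' Write an interval set as BED
#' @param x an [interval_set()].
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  out <- data.frame(x$chrom, format_bed_num(x$start), format_bed_num(x$end))
  if (!all(is.na(x$name))) out$name <- x$name
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bed_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

# ---- MethylationTable -------------------------------------------------------

#' Construct a validated per-CpG methylation count table
#'
#' Holds methylated and total read counts per CpG (rows) and sample
#' (columns) with an exposure label (`"low"`/`"high"`) per sample. Rows are
#' sorted by chromosome then position; positions are 1-based and strictly
#' increasing within a chromosome.
#'
#' @param chrom character vector per CpG.
#' @param pos integer vector of 1-based CpG positions.
#' @param meth,total integer matrices (CpG x sample), 0 <= meth <= total.
#' @param sample_ids character vector of column names.
#' @param groups per-sample labels, each `"low"` or `"high"`; at least one
#'   sample per group.
#' @return object of class `methylation_table`: a list with fields
#'   `chrom`, `pos`, `meth`, `total`, `samples`, `groups`.
#' @export
methylation_table <- function(chrom, pos, meth, total, sample_ids, groups) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  n <- length(chrom)
  if (length(pos) != n || nrow(meth) != n || nrow(total) != n)
    stop_input("row count mismatch between chrom/pos and count matrices")
  if (ncol(meth) != length(sample_ids) || ncol(total) != length(sample_ids))
    stop_input("column count mismatch with sample_ids")
  if (length(groups) != length(sample_ids))
    stop_input("groups must have one label per sample")
  if (!all(groups %in% c("low", "high")))
    stop_input("group labels must be 'low' or 'high'")
  if (!all(c("low", "high") %in% groups))
    stop_input("need at least one sample per group")
  bad <- which(meth > total | meth < 0 | total < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("invalid counts (meth > total or negative) at row %d, sample %s",
               bad[1, 1], sample_ids[bad[1, 2]])
  ord <- order(factor(chrom, levels = unique(chrom)), pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  meth <- meth[ord, , drop = FALSE]; total <- total[ord, , drop = FALSE]
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (anyDuplicated(p))
      stop_input("duplicated CpG position %d on %s", p[anyDuplicated(p)], ch)
  }
  colnames(meth) <- colnames(total) <- sample_ids
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 meth = meth, total = total,
                 samples = as.character(sample_ids),
                 groups = as.character(groups)),
            class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat(sprintf("methylation_table: %d CpGs on %d chromosome(s), %d samples (%d low / %d high)\n",
              length(x$pos), length(unique(x$chrom)), length(x$samples),
              sum(x$groups == "low"), sum(x$groups == "high")))
  invisible(x)
}

#' @export
dim.methylation_table <- function(x) c(length(x$pos), length(x$samples))

#' Read a methylation count TSV
#'
#' Expected layout: columns `chrom`, `pos`, then a `<sample>.meth` /
#' `<sample>.total` pair per sample (header required).
#'
#' @param path TSV path.
#' @param group_map named character vector or list mapping sample id to
#'   `"low"`/`"high"`.
#' @return a [methylation_table()].
#' @export
read_methylation <- function(path, group_map) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_input("cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(df) < 4 || !all(c("chrom", "pos") %in% names(df)))
    stop_input("%s: need chrom, pos and at least one meth/total pair", path)
  cn <- setdiff(names(df), c("chrom", "pos"))
  meth_cols <- grep("\\.meth$", cn, value = TRUE)
  samples <- sub("\\.meth$", "", meth_cols)
  total_cols <- paste0(samples, ".total")
  if (!all(total_cols %in% cn))
    stop_input("%s: missing .total column for sample(s) %s", path,
               paste(samples[!total_cols %in% cn], collapse = ", "))
  for (col in c(meth_cols, total_cols, "pos"))
    if (!is.numeric(df[[col]]))
      stop_input("%s: non-numeric values in column %s (line %d)", path, col,
                 which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1] + 1L)
  group_map <- unlist(group_map)
  if (!all(samples %in% names(group_map)))
    stop_input("group_map missing sample(s): %s",
               paste(setdiff(samples, names(group_map)), collapse = ", "))
  meth <- as.matrix(df[meth_cols]); total <- as.matrix(df[total_cols])
  bad <- which(meth > total, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("%s: meth > total at data row %d, sample %s", path,
               bad[1, 1], samples[bad[1, 2]])
  methylation_table(df$chrom, df$pos, meth, total, samples,
                    unname(group_map[samples]))
}

#' Write a methylation count TSV (inverse of [read_methylation()])
#' @param meth a [methylation_table()].
#' @param path output path.
#' @export
write_methylation <- function(meth, path) {
  out <- data.frame(chrom = meth$chrom, pos = meth$pos, check.names = FALSE)
  for (i in seq_along(meth$samples)) {
    out[[paste0(meth$samples[i], ".meth")]] <- meth$meth[, i]
    out[[paste0(meth$samples[i], ".total")]] <- meth$total[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample BedGraph-like count files into one table
#'
#' Convenience wrapper around [methylation_table()] for the common layout of
#' one 4-column file per sample: chrom, pos (1-based), meth, total. All files
#' must cover the same CpG grid.
#'
#' @param paths named character vector of file paths (names = sample ids).
#' @param group_map sample to `"low"`/`"high"` mapping.
#' @return a [methylation_table()].
#' @export
read_bedgraphs <- function(paths, group_map) {
  stopifnot(!is.null(names(paths)))
  tabs <- lapply(paths, utils::read.table, sep = "\t", header = FALSE,
                 col.names = c("chrom", "pos", "meth", "total"),
                 stringsAsFactors = FALSE)
  ref <- tabs[[1]]
  for (i in seq_along(tabs))
    if (!identical(tabs[[i]]$pos, ref$pos) || !identical(tabs[[i]]$chrom, ref$chrom))
      stop_input("sample %s is not on the same CpG grid", names(paths)[i])
  group_map <- unlist(group_map)
  methylation_table(ref$chrom, ref$pos,
                    sapply(tabs, `[[`, "meth"), sapply(tabs, `[[`, "total"),
                    names(paths), unname(group_map[names(paths)]))
}

# ---- GenotypeTable ----------------------------------------------------------

#' Construct a validated genotype dosage table
#'
#' @param chrom,pos per-variant chromosome and 1-based position.
#' @param variant_id character vector of variant ids.
#' @param dosage matrix (variant x sample) with values 0, 1, 2 or NA.
#' @param sample_ids character vector of sample ids.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(chrom, pos, variant_id, dosage, sample_ids) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop_input("dosages must be 0, 1, 2 or NA")
  chrom <- as.character(chrom)
  ord <- order(factor(chrom, levels = unique(chrom)), pos)
  dimnames(dosage) <- list(as.character(variant_id), sample_ids)
  structure(list(chrom = chrom[ord], pos = as.integer(pos)[ord],
                 variant_id = as.character(variant_id)[ord],
                 dosage = dosage[ord, , drop = FALSE],
                 samples = as.character(sample_ids)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d variants, %d samples\n",
              length(x$pos), length(x$samples)))
  invisible(x)
}

#' Read genotypes from a minimal VCF
#'
#' Parses CHROM, POS, ID and the GT field per sample. Only biallelic records
#' are kept; multi-allelic records are skipped with a warning. GT encoding:
#' 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA (phased separators
#' accepted).
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop_input("no biallelic records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(as.integer(alleles))
  })
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(id) | id == "."]
  genotype_table(fix[, "CHROM"], as.integer(fix[, "POS"]), id, dosage,
                 colnames(gt))
}

#' Write a genotype table as a minimal VCF
#'
#' Emits a VCF v4.2 with GT-only FORMAT; REF/ALT are placeholders (A/G) as
#' only dosages are modeled.
#'
#' @param geno a [genotype_table()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno$dosage + 1],
                   nrow = nrow(geno$dosage))
  gt_str[is.na(gt_str)] <- "./."
  lines <- apply(cbind(geno$chrom, geno$pos, geno$variant_id, "A", "G", ".",
                       "PASS", ".", "GT", gt_str), 1, paste, collapse = "\t")
  writeLines(lines, con)
  invisible(path)
}

# ---- DMR table I/O ----------------------------------------------------------

dmr_columns <- c("chrom", "start", "end", "id", "area_stat", "strand",
                 "n_cpgs", "mean_diff", "direction", "class_label", "fdr")

empty_dmr_table <- function() {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   id = character(), area_stat = numeric(), strand = character(),
                   n_cpgs = integer(), mean_diff = numeric(),
                   direction = character(), class_label = character(),
                   fdr = numeric(), stringsAsFactors = FALSE)
  df
}

#' Write called DMRs as a BED6+ table
#'
#' Columns: chrom, start, end, id, areaStat (score), strand ("."), then
#' n_cpgs, mean_diff, direction, class_label, fdr. A header line starting
#' with `#` records the column names so the file round-trips losslessly via
#' [read_dmrs()].
#'
#' @param dmrs DMR data.frame as returned by [call_dmrs()].
#' @param path output path.
#' @export
write_dmrs <- function(dmrs, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_input("cannot write %s", path))
  on.exit(close(con))
  writeLines(paste0("#", paste(dmr_columns, collapse = "\t")), con)
  if (nrow(dmrs) > 0) {
    out <- dmrs[, dmr_columns]
    out$start <- format_bed_num(out$start); out$end <- format_bed_num(out$end)
    utils::write.table(format(out, digits = 15, scientific = FALSE, trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a DMR BED6+ table written by [write_dmrs()]
#' @param path file path.
#' @return DMR data.frame.
#' @export
read_dmrs <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#"))
    stop_input("%s: missing DMR header line", path)
  if (length(lines) == 1) return(empty_dmr_table())
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = dmr_columns, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "character",
                                         "integer", "numeric", "character",
                                         "character", "numeric"))
  if (nrow(df) == 0) return(empty_dmr_table())
  df
}
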