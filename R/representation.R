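#' Count strand-resolved CpG cytosines in a reference genome
#'
#' Both cytosines of a CG dinucleotide are assayable (one per strand) and
#' the analysis keeps them as distinct sites, so the genomic total is
#' exactly twice the CG-dinucleotide count, case-insensitive. Ambiguity
#' codes never form a CpG; CpGs do not span contig boundaries.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @return integer count.
#' @export
count_genomic_cpg_cytosines <- function(genome) {
  genome <- .as_genome(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty reference genome")
  2L * sum(Biostrings::vcountPattern("CG", genome))
}

#' Percent of genomic CpG cytosines represented by a sample
#'
#' 100 x n_identified / n_genomic.
#'
#' @param n_identified distinct cytosines identified in the sample.
#' @param n_genomic genomic strand-resolved CpG cytosine total.
#' @return percent (full precision; round for reporting).
#' @export
representation_percent <- function(n_identified, n_genomic) {
  if (any(n_genomic <= 0)) stop("n_genomic must be positive")
  if (any(n_identified > n_genomic))
    stop("more identified cytosines than genomic cytosines")
  100 * n_identified / n_genomic
}

#' Union representation over several samples
#'
#' Distinct (chrom, pos, strand) site keys over all samples of one
#' condition, and the percent of the genomic total they represent.
#'
#' @param samples long methylome table (several samples) or a list of
#'   methylome tables.
#' @param n_genomic genomic strand-resolved CpG cytosine total.
#' @param allow_mixed allow samples from different conditions.
#' @return list(union_n, union_pct).
#' @export
union_representation <- function(samples, n_genomic, allow_mixed = FALSE) {
  dt <- if (is.data.frame(samples)) as.data.table(samples)
        else rbindlist(samples, fill = TRUE)
  if (nrow(dt) == 0L) stop("no samples given")
  if (!allow_mixed && "condition" %in% names(dt) &&
      length(unique(dt$condition)) > 1L)
    stop("samples span multiple conditions; set allow_mixed = TRUE")
  union_n <- nrow(unique(dt[, .(chrom, pos, strand)]))
  list(union_n = union_n,
       union_pct = representation_percent(union_n, n_genomic))
}

#' Maximum gap between consecutive sequenced cytosines
#'
#' Per chromosome, the largest positional difference between consecutive
#' distinct positions (strands merged: the homogeneity question is about
#' positions along the chromosome). Chromosomes with fewer than two
#' positions report gap 0 with `flagged = TRUE`.
#'
#' @param records methylome table (one sample or a union).
#' @return data.table: chrom, max_gap, flagged.
#' @export
max_consecutive_gap <- function(records) {
  dt <- unique(as.data.table(records)[, .(chrom, pos)])
  dt[order(pos),
     .(max_gap = if (.N < 2L) 0L else max(diff(pos)), flagged = .N < 2L),
     by = chrom]
}

#' Median sequencing depth of a sample
#'
#' Even-count medians are the mean of the central pair.
#'
#' @param records methylome table.
#' @return numeric median depth.
#' @export
median_depth <- function(records) {
  if (nrow(records) == 0L) stop("empty sample")
  median(records$n_meth + records$n_unmeth)
}

#' Genome-representation summary across all samples
#'
#' Per-sample identified-cytosine counts, representation percents and
#' median depths, plus per-condition union representation. The condition
#' percent column is reported both as the mean of per-sample percents and
#' as the percent of the per-condition mean count (they differ under
#' rounding of the printed means).
#'
#' @param counts long methylome table with male and condition columns.
#' @param n_genomic genomic strand-resolved CpG cytosine total.
#' @return list: `samples` (condition, male, n_identified, pct, median
#'   depth), `conditions` (per-condition means and union), `gaps`
#'   (per-condition union max gap per chromosome).
#' @export
representation_summary <- function(counts, n_genomic) {
  dt <- as.data.table(counts)
  samples <- dt[, .(n_identified = .N,
                    pct = representation_percent(.N, n_genomic),
                    median_depth = as.numeric(median(n_meth + n_unmeth))),
                by = .(condition, male)]
  conditions <- samples[, .(
    mean_identified = mean(n_identified),
    median_depth = median(median_depth),
    mean_of_pcts = mean(pct),
    pct_of_mean = representation_percent(mean(n_identified), n_genomic)),
    by = condition]
  uni <- dt[, {
    u <- union_representation(.SD, n_genomic)
    .(union_n = u$union_n, union_pct = u$union_pct)
  }, by = condition, .SDcols = c("chrom", "pos", "strand", "condition")]
  conditions <- merge(conditions, uni, by = "condition", sort = FALSE)
  gaps <- dt[, max_consecutive_gap(.SD), by = condition,
             .SDcols = c("chrom", "pos")]
  list(samples = samples[], conditions = conditions[], gaps = gaps[])
}
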