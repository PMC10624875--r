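#' @import data.table
#' @importFrom stats median prcomp kruskal.test wilcox.test pnorm rbeta
#'   rbinom rnbinom runif setNames complete.cases cor rnorm
#' @importFrom utils combn head tail
NULL

# Internal canonical column order for a methylome table.
.METH_COLS <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")

#' Build a methylome table from vectors
#'
#' A methylome table is the package's canonical container for per-cytosine
#' bisulfite counts: one row per strand-resolved CpG cytosine in one sample,
#' with 1-based reference coordinates. Depth-0 rows are disallowed.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions of the cytosine base.
#' @param strand "+", "-" or "." (unknown).
#' @param n_meth,n_unmeth non-negative read counts.
#' @param male,condition optional sample identity, attached as columns.
#' @return A `data.table` with columns chrom, pos, strand, n_meth, n_unmeth
#'   (plus male/condition when given) and a `ratio` accessor via
#'   [meth_ratio()].
#' @export
methylome <- function(chrom, pos, strand, n_meth, n_unmeth,
                      male = NULL, condition = NULL) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand),
                   n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth))
  if (any(dt$n_meth < 0L) || any(dt$n_unmeth < 0L))
    stop("negative counts are not a methylome")
  if (any(dt$n_meth + dt$n_unmeth == 0L))
    stop("depth-0 records are never stored")
  if (!all(dt$strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  if (!is.null(male)) dt[, male := as.integer(male)]
  if (!is.null(condition)) dt[, condition := as.character(condition)]
  dt[]
}

#' Per-cytosine methylation ratio
#'
#' Always recomputed from counts; the percent column of coverage files is
#' never trusted.
#'
#' @param records a methylome table.
#' @return numeric vector in `[0, 1]`.
#' @export
meth_ratio <- function(records) {
  records$n_meth / (records$n_meth + records$n_unmeth)
}

.fread_checked <- function(path, ncol, what) {
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", colClasses = "character"),
    error = function(e) stop(sprintf("malformed %s file '%s': %s",
                                     what, path, conditionMessage(e)))
  )
  if (nrow(dt) > 0L && ncol(dt) != ncol)
    stop(sprintf("%s file '%s' has %d columns, expected %d",
                 what, path, ncol(dt), ncol))
  dt
}

.bad_line <- function(path, bad_idx, what) {
  stop(sprintf("malformed %s line %d in '%s'", what, bad_idx[1L], path))
}

#' Read a Bismark coverage file
#'
#' Coverage dialect: 6 tab-separated columns (chrom, start, end, methylation
#' percent, count methylated, count unmethylated) with start = end = the
#' 1-based cytosine position. The dialect does not carry strand: records get
#' strand "." unless a reference genome is supplied, in which case strand is
#' resolved from the base at the position (C on the forward strand gives
#' "+", G gives "-").
#'
#' Depth-0 lines are skipped with a warning; the percent column is ignored
#' in favour of recomputation from the counts.
#'
#' @param path file path.
#' @param genome optional `DNAStringSet` (or FASTA path) used to resolve
#'   strand.
#' @param male,condition optional sample identity.
#' @return methylome table.
#' @export
read_bismark_coverage <- function(path, genome = NULL,
                                  male = NULL, condition = NULL) {
  dt <- .fread_checked(path, 6L, "Bismark coverage")
  if (nrow(dt) == 0L)
    return(methylome(character(), integer(), character(), integer(),
                     integer(), male, condition))
  setnames(dt, c("chrom", "start", "end", "pct", "n_meth", "n_unmeth"))
  pos <- suppressWarnings(as.integer(dt$start))
  nm <- suppressWarnings(as.integer(dt$n_meth))
  nu <- suppressWarnings(as.integer(dt$n_unmeth))
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu) | nm < 0L | nu < 0L |
                 dt$start != dt$end)
  if (length(bad)) .bad_line(path, bad, "Bismark coverage")
  keep <- nm + nu > 0L
  if (!all(keep))
    warning(sprintf("%d depth-0 record(s) skipped in '%s'",
                    sum(!keep), path))
  out <- methylome(dt$chrom[keep], pos[keep], ".", nm[keep], nu[keep],
                   male, condition)
  if (!is.null(genome) && nrow(out) > 0L)
    out[, strand := resolve_strand(genome, chrom, pos)]
  out[]
}

#' Write a Bismark coverage file
#'
#' @param records methylome table.
#' @param path output path.
#' @export
write_bismark_coverage <- function(records, path) {
  dt <- as.data.table(records)[order(chrom, pos)]
  out <- dt[, .(chrom, start = pos, end = pos,
                pct = round(100 * n_meth / (n_meth + n_unmeth), 6),
                n_meth, n_unmeth)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Resolve cytosine strand against a reference genome
#'
#' "+" when the reference base at `pos` is C (the CpG partner G must follow),
#' "-" when it is G (the cytosine sits on the reverse strand), "." otherwise.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param chrom,pos vectors of positions.
#' @return character vector of strands.
#' @export
resolve_strand <- function(genome, chrom, pos) {
  genome <- .as_genome(genome)
  strand <- rep(".", length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) next
    s <- as.character(genome[[ch]])
    i <- which(chrom == ch)
    base <- substring(s, pos[i], pos[i])
    strand[i][base == "C"] <- "+"
    strand[i][base == "G"] <- "-"
  }
  strand
}

.as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome)))
    stop("reference genome sequences must be named")
  # FASTA headers may carry descriptions after the first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a Bismark CX / cytosine report
#'
#' 7 columns: chrom, pos, strand, count methylated, count unmethylated,
#' context, trinucleotide. Only CG-context rows are retained (the analysis
#' is CpG-only); depth-0 rows are dropped silently (every genomic cytosine
#' is listed in this dialect, so zeros are the norm, not an anomaly).
#'
#' @inheritParams read_bismark_coverage
#' @return methylome table with explicit strand.
#' @export
read_cx_report <- function(path, male = NULL, condition = NULL) {
  dt <- .fread_checked(path, 7L, "CX report")
  if (nrow(dt) == 0L)
    return(methylome(character(), integer(), character(), integer(),
                     integer(), male, condition))
  setnames(dt, c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                 "context", "tri"))
  dt <- dt[context == "CG"]
  if (nrow(dt) == 0L)
    return(methylome(character(), integer(), character(), integer(),
                     integer(), male, condition))
  if (!all(dt$strand %in% c("+", "-")))
    stop(sprintf("unknown strand symbol in CX report '%s'", path))
  pos <- suppressWarnings(as.integer(dt$pos))
  nm <- suppressWarnings(as.integer(dt$n_meth))
  nu <- suppressWarnings(as.integer(dt$n_unmeth))
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu))
  if (length(bad)) .bad_line(path, bad, "CX report")
  keep <- nm + nu > 0L
  methylome(dt$chrom[keep], pos[keep], dt$strand[keep], nm[keep], nu[keep],
            male, condition)
}

#' Write a Bismark CX report
#'
#' Emits only the rows present in `records` (all CG context). The
#' trinucleotide column is written as "CGN".
#'
#' @param records methylome table with resolved strand.
#' @param path output path.
#' @export
write_cx_report <- function(records, path) {
  dt <- as.data.table(records)[order(chrom, pos, strand)]
  out <- dt[, .(chrom, pos, strand, n_meth, n_unmeth,
                context = "CG", tri = "CGN")]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' One gene model per gene, using the exon chain of its longest-span
#' transcript. The TSS is the 5' end respecting strand (for a minus-strand
#' gene the TSS is the highest coordinate). Genes without any transcript or
#' exon children use the gene body as a single exon, with a warning.
#'
#' @param path GFF3 file.
#' @return A `gene_models` object: a list with `genes` (gene_id, chrom,
#'   strand, start, end, tss, tes) and `exons` (gene_id, exon_rank, start,
#'   end) data.tables. Exon rank 1 is the 5'-most exon in transcription
#'   order.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.table(S4Vectors::mcols(gr)[, intersect(
    c("type", "ID", "Parent"), names(S4Vectors::mcols(gr))), drop = FALSE])
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  dt <- cbind(dt, meta)
  if (!"Parent" %in% names(dt)) dt[, Parent := list(list(character()))]
  dt[, parent := vapply(Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))]
  genes <- dt[type == "gene"]
  if (nrow(genes) == 0L) stop(sprintf("no gene features in '%s'", path))
  tx <- dt[type %in% c("mRNA", "transcript")]
  ex <- dt[type == "exon"]
  gene_rows <- vector("list", nrow(genes))
  exon_rows <- vector("list", nrow(genes))
  n_orphan <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    gtx <- tx[parent == g$ID]
    chain <- NULL
    if (nrow(gtx) > 0L) {
      span <- gtx$end - gtx$start
      best <- gtx[which.max(span)]
      chain <- ex[parent == best$ID, .(start, end)]
    }
    if (is.null(chain) || nrow(chain) == 0L) {
      # exons may hang directly off the gene
      chain <- ex[parent == g$ID, .(start, end)]
    }
    if (nrow(chain) == 0L) {
      n_orphan <- n_orphan + 1L
      chain <- data.table(start = g$start, end = g$end)
    }
    setorder(chain, start)
    if (g$strand == "-") chain <- chain[rev(seq_len(nrow(chain)))]
    gene_rows[[i]] <- data.table(
      gene_id = g$ID, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end,
      tss = if (g$strand == "-") g$end else g$start,
      tes = if (g$strand == "-") g$start else g$end)
    exon_rows[[i]] <- data.table(gene_id = g$ID,
                                 exon_rank = seq_len(nrow(chain)),
                                 start = chain$start, end = chain$end)
  }
  if (n_orphan > 0L)
    warning(sprintf("%d gene(s) without exons: gene body used as one exon",
                    n_orphan))
  structure(list(genes = rbindlist(gene_rows), exons = rbindlist(exon_rows)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write intervals as BED
#'
#' Internal coordinates are 1-based closed; BED is 0-based half-open, so a
#' single cytosine at position p becomes the line `start = p - 1, end = p`.
#' Input is sorted on write.
#'
#' @param intervals data.frame with chrom, start, end (1-based closed) or
#'   chrom, pos for single cytosines.
#' @param path output path.
#' @param track optional track name written as a comment header.
#' @export
write_bed <- function(intervals, path, track = "cryomethyl") {
  dt <- as.data.table(intervals)
  if (!"start" %in% names(dt) && "pos" %in% names(dt))
    dt[, `:=`(start = pos, end = pos)]
  header <- sprintf("# track name=%s (BED: 0-based half-open)", track)
  body <- if (nrow(dt) > 0L) {
    out <- dt[order(chrom, start)]
    sprintf("%s\t%d\t%d", out$chrom, out$start - 1L, out$end)
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write per-cytosine methylation ratios as bedGraph
#'
#' @param records methylome table.
#' @param path output path.
#' @export
write_bedgraph <- function(records, path) {
  dt <- as.data.table(records)
  body <- if (nrow(dt) > 0L) {
    out <- dt[order(chrom, pos)]
    sprintf("%s\t%d\t%d\t%g", out$chrom, out$pos - 1L, out$pos,
            round(out$n_meth / (out$n_meth + out$n_unmeth), 6))
  } else character()
  writeLines(c("# bedGraph: methylation ratio per cytosine", body), path)
  invisible(path)
}

#' Read or write the sperm-quality table
#'
#' 6-column CSV with header: male_id, condition, membrane, mito, motility,
#' fert_norm. Percentages 0-100 (fert_norm may exceed 100 after
#' normalization against the fresh-control mean); missing values allowed.
#'
#' @param path CSV path.
#' @return data.table, one row per male x condition.
#' @export
read_quality_table <- function(path) {
  dt <- fread(path)
  need <- c("male_id", "condition", "membrane", "mito", "motility",
            "fert_norm")
  if (!all(need %in% names(dt)))
    stop(sprintf("quality table '%s' must have columns: %s",
                 path, paste(need, collapse = ", ")))
  if (anyDuplicated(dt[, .(male_id, condition)]))
    stop("quality table has duplicated male x condition rows")
  dt[]
}

#' @rdname read_quality_table
#' @param quality data.frame to write.
#' @export
write_quality_table <- function(quality, path) {
  fwrite(as.data.table(quality), path)
  invisible(path)
}
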