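#' Detect differentially methylated regions by the sliding-window rule
#'
#' A qualifying window is anchored at a CpG and spans `window` bases; it
#' must contain at least `min_cpg` CpGs of which at least `min_frac` are
#' DMCs (p < alpha). Overlapping qualifying windows are merged into one
#' DMR spanning their union; the reported CpG/DMC counts are recomputed
#' over the merged span.
#'
#' @param sites data.table with chrom, pos and p_value for every tested
#'   CpG (strand-resolved sites count individually).
#' @param window window length in bases (default 50).
#' @param min_cpg minimum CpGs per window (default 5).
#' @param min_frac minimum DMC fraction (default 0.75).
#' @param alpha DMC p-value threshold (default 0.001).
#' @return data.table: chrom, start, end, n_cpg, n_dmc, dmc_fraction.
#' @export
detect_dmrs <- function(sites, window = 50L, min_cpg = 5L,
                        min_frac = 0.75, alpha = 0.001) {
  dt <- as.data.table(sites)[order(chrom, pos)]
  dt[, is_dmc := p_value < alpha]
  out <- list()
  for (ch in unique(dt$chrom)) {
    d <- dt[chrom == ch]
    p <- d$pos
    n <- length(p)
    # members of the window anchored at each CpG: positions in
    # [p_i, p_i + window - 1]
    hi <- findInterval(p + window - 1L, p)
    n_in <- hi - seq_len(n) + 1L
    cum_dmc <- cumsum(d$is_dmc)
    dmc_in <- cum_dmc[hi] - cum_dmc + d$is_dmc
    qual <- n_in >= min_cpg & dmc_in / n_in >= min_frac
    if (!any(qual)) next
    w_start <- p[qual]
    w_end <- p[qual] + window - 1L
    # merge overlapping qualifying windows
    merged_start <- integer(); merged_end <- integer()
    cur_s <- w_start[1L]; cur_e <- w_end[1L]
    for (i in seq_along(w_start)[-1L]) {
      if (w_start[i] <= cur_e) {
        cur_e <- max(cur_e, w_end[i])
      } else {
        merged_start <- c(merged_start, cur_s)
        merged_end <- c(merged_end, cur_e)
        cur_s <- w_start[i]; cur_e <- w_end[i]
      }
    }
    merged_start <- c(merged_start, cur_s)
    merged_end <- c(merged_end, cur_e)
    reg <- data.table(chrom = ch, start = merged_start, end = merged_end)
    reg[, `:=`(
      n_cpg = vapply(seq_len(.N), function(i)
        sum(p >= start[i] & p <= end[i]), integer(1)),
      n_dmc = vapply(seq_len(.N), function(i)
        sum(d$is_dmc[p >= start[i] & p <= end[i]]), integer(1)))]
    reg[, dmc_fraction := n_dmc / n_cpg]
    out[[length(out) + 1L]] <- reg
  }
  if (!length(out))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(),
                      n_dmc = integer(), dmc_fraction = numeric()))
  rbindlist(out)
}

#' Detect regions potentially sensitive to cryopreservation
#'
#' Single-linkage chaining of DMC positions: consecutive DMCs no more than
#' `max_gap` bases apart join one cluster (the gap rule is applied
#' transitively, so a chain of close DMCs forms one region). Clusters with
#' at least two DMCs become regions spanning first to last member DMC.
#' A region is sensitive to a cryoprotectant when it holds at least two of
#' that comparison's DMCs.
#'
#' @param dmcs data.table with chrom, pos, strand and a condition column
#'   naming the cryoprotectant of each DMC (DMC sets of several
#'   cryoprotectants may be concatenated).
#' @param max_gap maximum distance between consecutive member DMCs
#'   (default 100, the read length).
#' @return data.table: chrom, start, end, n_dmc (distinct member sites),
#'   one `n_dmc_<condition>` column per cryoprotectant, and `sensitive_to`
#'   (comma-joined cryoprotectants with >= 2 member DMCs).
#' @export
detect_sensitive_regions <- function(dmcs, max_gap = 100L) {
  dt <- unique(as.data.table(dmcs)[, .(chrom, pos, strand, condition)])
  conds <- sort(unique(dt$condition))
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), n_dmc = integer())
  if (nrow(dt) == 0L) return(empty)
  setorder(dt, chrom, pos)
  dt[, new_cluster := {
    d <- c(Inf, diff(pos))
    d > max_gap
  }, by = chrom]
  dt[, cluster := cumsum(new_cluster), by = chrom]
  reg <- dt[, {
    res <- .(start = min(pos), end = max(pos),
             n_dmc = uniqueN(paste(pos, strand)))
    res
  }, by = .(chrom, cluster)]
  percond <- dt[, .(n = uniqueN(paste(pos, strand))),
                by = .(chrom, cluster, condition)]
  percond <- dcast(percond, chrom + cluster ~ condition, value.var = "n",
                   fill = 0L)
  reg <- merge(reg, percond, by = c("chrom", "cluster"), sort = FALSE)
  reg <- reg[n_dmc >= 2L]
  if (nrow(reg) == 0L) return(empty)
  reg[, sensitive_to := apply(.SD, 1L, function(x)
    paste(conds[x >= 2L], collapse = ",")), .SDcols = conds]
  setnames(reg, conds, paste0("n_dmc_", conds))
  reg[, cluster := NULL]
  setorder(reg, chrom, start)
  reg[]
}

#' Build strand-aware gene feature intervals
#'
#' Per gene: promoter (`promoter_len` bases upstream of the TSS), exon 1,
#' other exons, intron 1, other introns, and the downstream window
#' (`downstream_len` bases past the TES), all 1-based closed, clipped at
#' the chromosome start. Exon/intron ranks follow transcription order.
#'
#' @param gene_models a `gene_models` object from [read_gff3_genes()] or
#'   a compatible list.
#' @param promoter_len promoter window length (default 5000).
#' @param downstream_len downstream window length (default 1000).
#' @return data.table: gene_id, chrom, feature, start, end with feature in
#'   promoter5kb, exon1, exons, intron1, introns, downstream1kb.
#' @export
build_gene_features <- function(gene_models, promoter_len = 5000L,
                                downstream_len = 1000L) {
  genes <- as.data.table(gene_models$genes)
  exons <- as.data.table(gene_models$exons)
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    ex <- exons[gene_id == g$gene_id][order(exon_rank)]
    minus <- g$strand == "-"
    prom <- if (minus) c(g$tss + 1L, g$tss + promoter_len)
            else c(g$tss - promoter_len, g$tss - 1L)
    down <- if (minus) c(g$tes - downstream_len, g$tes - 1L)
            else c(g$tes + 1L, g$tes + downstream_len)
    rows <- list(
      data.table(feature = "promoter5kb", start = max(1L, prom[1L]),
                 end = prom[2L]),
      data.table(feature = "downstream1kb", start = max(1L, down[1L]),
                 end = down[2L]),
      data.table(feature = ifelse(ex$exon_rank == 1L, "exon1", "exons"),
                 start = ex$start, end = ex$end))
    if (nrow(ex) > 1L) {
      # introns in transcription order between consecutive exons
      up <- ex[-nrow(ex)]; dn <- ex[-1L]
      istart <- ifelse(rep(minus, nrow(up)), dn$end + 1L, up$end + 1L)
      iend <- ifelse(rep(minus, nrow(up)), up$start - 1L, dn$start - 1L)
      ok <- istart <= iend
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.table(
          feature = ifelse(seq_len(nrow(up)) == 1L, "intron1",
                           "introns")[ok],
          start = istart[ok], end = iend[ok])
    }
    f <- rbindlist(rows)
    f <- f[end >= start]
    f[, `:=`(gene_id = g$gene_id, chrom = g$chrom)]
    feats[[i]] <- f
  }
  rbindlist(feats)[, .(gene_id, chrom, feature, start, end)]
}

#' Annotate regions against gene features
#'
#' A region is labeled with every feature it overlaps (multi-labeling; no
#' precedence), over all genes; a region overlapping no feature is
#' intergenic.
#'
#' @param regions data.table with chrom, start, end (1-based closed); a
#'   single-position region may use a `pos` column instead.
#' @param gene_models a `gene_models` object.
#' @param promoter_len,downstream_len window lengths passed to
#'   [build_gene_features()].
#' @return `regions` with `features` (comma-joined sorted labels, or
#'   "intergenic") and `gene_ids` (comma-joined) columns added.
#' @export
annotate_region <- function(regions, gene_models, promoter_len = 5000L,
                            downstream_len = 1000L) {
  reg <- as.data.table(regions)
  if (!"start" %in% names(reg) && "pos" %in% names(reg))
    reg[, `:=`(start = pos, end = pos)]
  feats <- build_gene_features(gene_models, promoter_len, downstream_len)
  reg_gr <- GenomicRanges::GRanges(reg$chrom,
                                   IRanges::IRanges(reg$start, reg$end))
  feat_gr <- GenomicRanges::GRanges(feats$chrom,
                                    IRanges::IRanges(feats$start,
                                                     feats$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, feat_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- copy(reg)
  out[, features := "intergenic"]
  out[, gene_ids := NA_character_]
  if (length(qh) > 0L) {
    ann <- data.table(q = qh, feature = feats$feature[sh],
                      gene_id = feats$gene_id[sh])
    lab <- ann[, .(features = paste(sort(unique(feature)), collapse = ","),
                   gene_ids = paste(sort(unique(gene_id)),
                                    collapse = ",")),
               by = q]
    out[lab$q, `:=`(features = lab$features, gene_ids = lab$gene_ids)]
  }
  out[]
}
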