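library(data.table)

# Small methylome table from parallel vectors, defaulting chrom/strand.
mk_meth <- function(pos, n_meth, n_unmeth, chrom = "chr1", strand = "+",
                    male = NULL, condition = NULL) {
  methylome(chrom = rep_len(chrom, length(pos)), pos = pos,
            strand = rep_len(strand, length(pos)),
            n_meth = n_meth, n_unmeth = n_unmeth,
            male = male, condition = condition)
}

# A paired table for one site across males, from fresh/treated count pairs.
mk_paired <- function(n_meth_f, n_unmeth_f, n_meth_t, n_unmeth_t,
                      pos = 100L, chrom = "chr1", strand = "+") {
  data.table(chrom = chrom, pos = pos, strand = strand,
             male = seq_along(n_meth_f),
             n_meth_f = as.integer(n_meth_f),
             n_unmeth_f = as.integer(n_unmeth_f),
             n_meth_t = as.integer(n_meth_t),
             n_unmeth_t = as.integer(n_unmeth_t))
}

# Shared medium simulation (fresh + DMSO, dropout on), built once per run.
.fixture_cache <- new.env(parent = emptyenv())
fixture_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(seed = 3L, conditions = c("fresh", "DMSO"),
                      n_chrom = 1L, chrom_length = 300000L,
                      n_dmc_true = 100L)
    .fixture_cache$sim <- simulate_rrbs(cfg)
  }
  .fixture_cache$sim
}

# Large fresh-only simulation at the default study scale (shared).
fresh_sim_large <- function() {
  if (is.null(.fixture_cache$fresh_large)) {
    cfg <- sim_config(seed = 2026L, conditions = "fresh")
    .fixture_cache$fresh_large <- simulate_rrbs(cfg)
  }
  .fixture_cache$fresh_large
}

# Simulated null paired data: nsite sites x nmale males, all at true ratio
# `r`, depth ~ NegBin(mu, size) + 1 (so every male is informative).
null_paired <- function(nsite, nmale, r = 0.5, mu = 30, size = 8) {
  n <- nsite * nmale
  df <- rnbinom(n, mu = mu, size = size) + 1L
  dt <- rnbinom(n, mu = mu, size = size) + 1L
  mf <- rbinom(n, df, r)
  mt <- rbinom(n, dt, r)
  data.table(chrom = "chr1", pos = rep(seq_len(nsite), nmale),
             strand = "+", male = rep(seq_len(nmale), each = nsite),
             n_meth_f = mf, n_unmeth_f = df - mf,
             n_meth_t = mt, n_unmeth_t = dt - mt)
}

# Exact sign-flip permutation p-value for the weighted paired statistic:
# the independent oracle for paired_dm_test on small male counts.
signflip_p <- function(d, v) {
  w <- 1 / v
  D_obs <- sum(d * w) / sum(w)
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  D_perm <- as.vector(signs %*% (d * w)) / sum(w)
  mean(abs(D_perm) >= abs(D_obs) - 1e-12)
}

# Brute-force DMR oracle: every CpG-anchored window, then merged spans.
oracle_dmrs <- function(sites, window = 50L, min_cpg = 5L,
                        min_frac = 0.75, alpha = 0.001) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    d <- sites[sites$chrom == ch, ]
    d <- d[order(d$pos), ]
    spans <- list()
    for (i in seq_len(nrow(d))) {
      inw <- d$pos >= d$pos[i] & d$pos <= d$pos[i] + window - 1L
      if (sum(inw) >= min_cpg &&
          mean(d$p_value[inw] < alpha) >= min_frac)
        spans[[length(spans) + 1L]] <- c(d$pos[i], d$pos[i] + window - 1L)
    }
    if (!length(spans)) next
    spans <- do.call(rbind, spans)
    spans <- spans[order(spans[, 1L]), , drop = FALSE]
    merged <- spans[1L, , drop = FALSE]
    for (i in seq_len(nrow(spans))[-1L]) {
      last <- nrow(merged)
      if (spans[i, 1L] <= merged[last, 2L]) {
        merged[last, 2L] <- max(merged[last, 2L], spans[i, 2L])
      } else merged <- rbind(merged, spans[i, ])
    }
    out[[ch]] <- data.table(chrom = ch, start = merged[, 1L],
                            end = merged[, 2L])
  }
  if (!length(out)) return(data.table(chrom = character(),
                                      start = integer(),
                                      end = integer()))
  rbindlist(out)
}

# Write a small GFF3 with explicit transcript/exon structure.
write_test_gff3 <- function(path, genes) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf(
      "%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      g$chrom, g$start, g$end, g$strand, g$id))
    for (tx in g$transcripts) {
      lines <- c(lines, sprintf(
        "%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, tx$start, tx$end, g$strand, tx$id, g$id))
      for (i in seq_along(tx$exon_start)) {
        lines <- c(lines, sprintf(
          "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          g$chrom, tx$exon_start[i], tx$exon_end[i], g$strand,
          tx$id, i, tx$id))
      }
    }
  }
  writeLines(lines, path)
  path
}
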