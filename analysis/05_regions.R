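#!/usr/bin/env Rscript
# From DMCs to regions: the stringent sliding-window DMR rule (>= 50 b,
# >= 5 CpGs, >= 75% DMCs at p < 0.001) and the empirical "potentially
# sensitive region" rule (>= 2 DMCs within 100 b), annotated against the
# toy gene models (promoter 5 kb, exon 1, introns, downstream 1 kb).
# Requires results/dmc_*.tsv from 04_paired_dmc.R.

suppressMessages({
  library(cryomethyl)
  library(data.table)
})

indir <- "results/synthetic"
cx_files <- list.files(indir, pattern = "CX_report", full.names = TRUE)
counts <- rbindlist(lapply(cx_files, function(f) {
  stem <- sub("_male.*$", "", basename(f))
  male <- as.integer(sub("^.*_male(\\d+)\\..*$", "\\1", basename(f)))
  read_cx_report(f, male = male, condition = stem)
}))
genes <- read_gff3_genes(file.path(indir, "genes.gff3"))

all_dmcs <- list()
n_dmrs <- 0L
for (cp in c("DMSO", "MeOH", "glycerol")) {
  dmcs <- fread(sprintf("results/dmc_%s.tsv", cp))
  all_dmcs[[cp]] <- dmcs[, .(chrom, pos, strand, condition = cp)]
  tests <- paired_dm_test(build_paired_table(counts, cp),
                          min_males = 6L)$tests
  dmrs <- detect_dmrs(tests, window = 50L, min_cpg = 5L,
                      min_frac = 0.75, alpha = 0.001)
  n_dmrs <- n_dmrs + nrow(dmrs)
  cat(sprintf("%-9s DMCs: %d -> DMRs by the 50 b / 5 CpG / 75%% rule: %d\n",
              cp, nrow(dmcs), nrow(dmrs)))
  if (nrow(dmrs)) fwrite(dmrs, sprintf("results/dmr_%s.tsv", cp),
                         sep = "\t")
}
if (n_dmrs == 0L) {
  cat("no DMRs: injected DMCs are sparse, so few 50 b windows hold 5\n")
  cat("CpGs with 75% of them differential (the stringent rule rarely\n")
  cat("fires when effects are isolated cytosines).\n")
}

sens <- detect_sensitive_regions(rbindlist(all_dmcs), max_gap = 100L)
if (nrow(sens) > 0L)
  sens <- annotate_region(sens, genes)
fwrite(sens, "results/sensitive_regions.tsv", sep = "\t")
cat(sprintf("\npotentially sensitive regions (>= 2 DMCs within 100 b): %d\n",
            nrow(sens)))
if (nrow(sens) > 0L) {
  cat("feature labels of the sensitive regions:\n")
  print(sens[, .N, by = features][order(-N)])
}
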