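#!/usr/bin/env Rscript
# Does the per-male DMC burden track the cellular damage? Spearman rank
# correlation (permutation p-values) between each male's expressed DMC
# count and its quality metrics, within each cryoprotectant. Burden and
# quality are generated independently, so no correlation should emerge;
# glycerol fertilization is degenerate (all zero) and is flagged, not
# tested.

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
quality <- read_quality_table(file.path(indir, "quality.csv"))

dmc_results <- lapply(
  c(DMSO = "DMSO", MeOH = "MeOH", glycerol = "glycerol"),
  function(cp) dmc_analysis(counts, cp, min_males = 6L, alpha = 0.001))

screen <- quality_correlation_screen(dmc_results, quality, seed = 42L)
fwrite(screen, "results/quality_correlations.tsv", sep = "\t")

print(screen[, .(condition, metric, n, rho = round(rho, 3),
                 p_value = round(p_value, 3), degenerate)])
n_sig <- screen[!(degenerate) & p_value < 0.05, .N]
cat(sprintf("\nsignificant correlations at p < 0.05: %d of %d tests\n",
            n_sig, screen[!(degenerate), .N]))
cat("burden and quality are simulated independently, so any hit here is\n")
cat("a false positive; occasional ones are expected at the 5% level.\n")
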