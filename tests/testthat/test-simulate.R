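test_that("CpG enumeration lists both strands of every CG dinucleotide", {
  cfg <- sim_config(seed = 9L, n_chrom = 2L, chrom_length = 50000L)
  g <- build_toy_genome(cfg)
  for (ch in names(g$genome)) {
    s <- as.character(g$genome[[ch]])
    cg <- gregexpr("CG", s, fixed = TRUE)[[1L]]  # independent scan
    cg <- cg[cg > 0L]
    sites <- g$cpg_sites[chrom == ch]
    expect_equal(nrow(sites), 2L * length(cg))
    expect_equal(sites[strand == "+", sort(pos)], sort(as.integer(cg)))
    expect_equal(sites[strand == "-", sort(pos)], sort(as.integer(cg) + 1L))
  }
})

test_that("planted CCGG count is Poisson-consistent with the density", {
  cfg <- sim_config(seed = 21L, n_chrom = 1L, chrom_length = 100000L,
                    mspi_density = 5)
  g <- build_toy_genome(cfg)
  n_ccgg <- Biostrings::vcountPattern("CCGG", g$genome)[1L]
  # 99% band around lambda = 5/kb * 100 kb = 500
  expect_gt(n_ccgg, qpois(0.005, 500))
  expect_lt(n_ccgg, qpois(0.995, 500))
  expect_equal(nrow(g$ccgg), n_ccgg)  # planting accounts for every motif
})

test_that("MspI digestion cuts C^CGG and size-selects fragments", {
  genome <- Biostrings::DNAStringSet(c(toy = "AAACCGGAAACCGGAAA"))
  frags <- digest_mspi(genome, frag_min = 5L, frag_max = 10L)
  expect_equal(nrow(frags), 3L)
  expect_equal(frags$start, c(1L, 5L, 12L))
  expect_equal(frags$end, c(4L, 11L, 17L))
  mid <- as.character(Biostrings::subseq(genome[[1L]], 5L, 11L))
  expect_equal(mid, "CGGAAAC")
  expect_equal(frags$length[2L], 7L)
  expect_equal(frags$retained, c(FALSE, TRUE, TRUE))
  # no CCGG: a single fragment
  frags2 <- digest_mspi(Biostrings::DNAStringSet(c(x = "ATATATAT")), 2, 100)
  expect_equal(nrow(frags2), 1L)
})

test_that("fragment count equals CCGG count + 1 per chromosome", {
  cfg <- sim_config(seed = 13L, n_chrom = 2L, chrom_length = 60000L)
  g <- build_toy_genome(cfg)
  frags <- digest_mspi(g$genome, cfg$frag_min, cfg$frag_max)
  for (ch in names(g$genome)) {
    n_ccgg <- length(gregexpr("CCGG",
                              as.character(g$genome[[ch]]))[[1L]])
    expect_equal(nrow(frags[chrom == ch]), n_ccgg + 1L)
  }
})

test_that("truth mixture frequencies match the configured weights", {
  cfg <- sim_config(seed = 17L, n_chrom = 1L, chrom_length = 1500000L,
                    conditions = "fresh")
  g <- build_toy_genome(cfg)
  sites <- mark_observable(g$cpg_sites,
                           digest_mspi(g$genome, cfg$frag_min,
                                       cfg$frag_max))
  truth <- assign_truth(cfg, sites)
  per_cpg <- truth$sites[!duplicated(cpg_id), base_ratio]
  n <- length(per_cpg)
  expect_gt(n, 50000L)
  band <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(per_cpg == 1) - 0.86), band(0.86))
  expect_lt(abs(mean(per_cpg == 0) - 0.12), band(0.12))
  mid <- per_cpg[per_cpg > 0 & per_cpg < 1]
  expect_true(all(mid >= 0.05 & mid <= 0.95))
})

test_that("null configuration injects no effect; full concordance hits all males", {
  cfg <- sim_config(seed = 19L, n_chrom = 1L, chrom_length = 100000L,
                    n_dmc_true = 20L, dmc_effect = 0)
  g <- build_toy_genome(cfg)
  sites <- mark_observable(g$cpg_sites,
                           digest_mspi(g$genome, cfg$frag_min,
                                       cfg$frag_max))
  truth <- assign_truth(cfg, sites)
  for (m in c(1L, 7L))
    expect_equal(truth_ratio(truth, "DMSO", m),
                 truth_ratio(truth, "fresh", m))
  cfg2 <- sim_config(seed = 19L, n_chrom = 1L, chrom_length = 100000L,
                     n_dmc_true = 20L, dmc_concordance = 1)
  truth2 <- assign_truth(cfg2, sites)
  expect_true(all(vapply(truth2$dmcs$males, length, integer(1)) == 12L))
})

test_that("every injected DMC is recorded with direction and male subset", {
  sim <- fixture_sim()
  dmcs <- sim$truth$dmcs
  expect_equal(nrow(dmcs), sim$config$n_dmc_true)
  expect_true(all(dmcs$direction %in% c("hyper", "hypo")))
  expect_true(all(vapply(dmcs$males, length, integer(1)) ==
                    ceiling(sim$config$dmc_concordance *
                              sim$config$n_males)))
  # injected sites lie on retained fragments (observable)
  key_obs <- sim$cpg_sites[observable == TRUE,
                           paste(chrom, pos, strand)]
  expect_true(all(paste(dmcs$chrom, dmcs$pos, dmcs$strand) %in% key_obs))
  expect_error(assign_truth(sim_config(n_dmc_true = 10000000L),
                            sim$cpg_sites),
               "observable")
})

test_that("bisulfite conversion logic follows r' = r + (1-r)(1-c)", {
  base <- sim_config(seed = 23L, n_chrom = 1L, chrom_length = 150000L,
                     conditions = "fresh", n_males = 2L,
                     site_dropout_mean = 1)
  # all-unmethylated truth, perfect conversion: no methylated call
  cfg <- base; cfg$p_methylated_site <- 0; cfg$p_unmethylated_site <- 1
  cfg$conversion_rate <- 1
  sim <- simulate_rrbs(cfg)
  expect_equal(sum(sim$counts$n_meth), 0L)
  # all-methylated truth: every read methylated regardless of conversion
  cfg$p_methylated_site <- 1; cfg$p_unmethylated_site <- 0
  cfg$conversion_rate <- 0.99
  sim <- simulate_rrbs(cfg)
  expect_equal(sum(sim$counts$n_unmeth), 0L)
  # unmethylated truth at conversion 0.996: observed methylated fraction
  # within 3 sigma of 0.004
  cfg$p_methylated_site <- 0; cfg$p_unmethylated_site <- 1
  cfg$conversion_rate <- 0.996
  sim <- simulate_rrbs(cfg)
  reads <- sum(sim$counts$n_meth + sim$counts$n_unmeth)
  frac <- sum(sim$counts$n_meth) / reads
  expect_lt(abs(frac - 0.004), 3 * sqrt(0.004 * 0.996 / reads))
})

test_that("identical seeds give identical simulations and fixture files", {
  cfg <- sim_config(seed = 29L, n_males = 2L,
                    conditions = c("fresh", "DMSO"), n_chrom = 1L,
                    chrom_length = 80000L, n_dmc_true = 5L)
  s1 <- simulate_rrbs(cfg)
  s2 <- simulate_rrbs(cfg)
  expect_identical(s1$counts, s2$counts)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_set(cfg, d1)
  write_fixture_set(cfg, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("the default design emits 48 sample files and zero glycerol fertilization", {
  cfg <- sim_config(seed = 31L, n_chrom = 1L, chrom_length = 60000L,
                    n_dmc_true = 2L)
  dir <- withr::local_tempdir()
  write_fixture_set(cfg, dir)
  expect_equal(length(list.files(dir, pattern = "\\.cov$")), 48L)
  expect_equal(length(list.files(dir, pattern = "CX_report")), 48L)
  q <- read_quality_table(file.path(dir, "quality.csv"))
  expect_equal(nrow(q), 48L)
  expect_true(all(q[condition == "glycerol", fert_norm] == 0))
  expect_true(all(q[condition == "glycerol", motility] == 0))
})

test_that("generated global methylation tracks the analytic mixture mean", {
  sim <- fresh_sim_large()
  est <- sim$counts[, .(m = global_mean_methylation(.SD, 10L)),
                    by = male]
  expect_lt(abs(mean(est$m) - mixture_mean_pct(sim$config)), 0.5)
})

test_that("mixture calibration hits a requested analytic mean", {
  cfg <- calibrate_mixture(sim_config(), 86.34)
  expect_equal(mixture_mean_pct(cfg), 86.34)
  expect_error(calibrate_mixture(sim_config(), 0.4), "unreachable")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_methylated_site = 0.9,
                          p_unmethylated_site = 0.2), "mixture")
  expect_error(sim_config(frag_min = 100L, frag_max = 50L), "frag_min")
  expect_error(sim_config(conversion_rate = 0.5), "conversion_rate")
  expect_error(sim_config(chrom_length = 100L), "chrom_length")
})
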