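test_that("paired extraction is the site-key intersection", {
  fresh <- mk_meth(pos = c(10L, 20L, 30L), n_meth = 1L, n_unmeth = 1L,
                   male = 1L, condition = "fresh")
  treated <- mk_meth(pos = c(20L, 30L, 40L), n_meth = 2L, n_unmeth = 0L,
                     male = 1L, condition = "DMSO")
  p <- extract_paired(fresh, treated)
  expect_equal(sort(p$pos), c(20L, 30L))
  expect_equal(p$n_meth_t, c(2L, 2L))
  disjoint <- extract_paired(fresh, mk_meth(pos = 99L, n_meth = 1L,
                                            n_unmeth = 0L, male = 1L))
  expect_equal(nrow(disjoint), 0L)
  expect_error(extract_paired(fresh, mk_meth(pos = 10L, n_meth = 1L,
                                             n_unmeth = 0L, male = 2L)),
               "male mismatch")
})

test_that("paired extraction agrees with a brute-force key intersection", {
  sim <- fixture_sim()
  m1f <- sim$counts[condition == "fresh" & male == 1L]
  m1t <- sim$counts[condition == "DMSO" & male == 1L]
  p <- extract_paired(m1f, m1t)
  kf <- paste(m1f$chrom, m1f$pos, m1f$strand)
  kt <- paste(m1t$chrom, m1t$pos, m1t$strand)
  expect_equal(sort(paste(p$chrom, p$pos, p$strand)),
               sort(intersect(kf, kt)))
})

test_that("sharing distribution counts males per distinct site", {
  paired <- rbind(
    mk_paired(1, 1, 1, 1, pos = 10L)[, male := 1L],
    mk_paired(1, 1, 1, 1, pos = 20L)[, male := 1L],
    mk_paired(1, 1, 1, 1, pos = 20L)[, male := 2L],
    mk_paired(1, 1, 1, 1, pos = 30L)[, male := 2L])
  sh <- sharing_distribution(paired, n_males = 2L, cum_min = 2L)
  expect_equal(sh$histogram$count, c(2L, 1L))
  expect_equal(sum(sh$histogram$count), nrow(sh$per_site))
  expect_equal(sh$cum_pct_at_least, 100 / 3)
  # all males identical: every site in the top class
  all_same <- rbindlist(lapply(1:12, function(m)
    copy(mk_paired(1, 1, 1, 1, pos = c(10L, 20L)))[, male := m]))
  sh2 <- sharing_distribution(all_same, n_males = 12L)
  expect_equal(sh2$histogram$count, c(rep(0L, 11L), 2L))
})

test_that("sharing histogram equals a brute-force dictionary count", {
  sim <- fixture_sim()
  paired <- build_paired_table(sim$counts, "DMSO")
  sh <- sharing_distribution(paired, n_males = 12L)
  dict <- table(table(paste(paired$chrom, paired$pos, paired$strand)))
  oracle <- integer(12L)
  oracle[as.integer(names(dict))] <- as.integer(dict)
  expect_equal(sh$histogram$count, oracle)
  expect_equal(sum(sh$histogram$count), nrow(sh$per_site))
  oracle_cum <- 100 * sum(oracle[6:12]) / sum(oracle)
  expect_equal(sh$cum_pct_at_least, oracle_cum)
})

test_that("shared-site selection is inclusive at the threshold", {
  per_site <- data.table(chrom = "chr1", pos = c(1L, 2L, 3L),
                         strand = "+", n_males_with_site = c(6L, 5L, 12L))
  sel <- select_shared_sites(per_site, min_males = 6L)
  expect_equal(sel$pos, c(1L, 3L))
  expect_error(select_shared_sites(per_site, min_males = 13L),
               "exceeds")
})

test_that("the paired test matches its closed-form single-male value", {
  # fresh 10/10 methylated, treated 0/10: with pseudocounts,
  # d = asin(sqrt(0.5/11)) - asin(sqrt(10.5/11)) = -1.1410966606,
  # v = 2 / 44, z = d / sqrt(v) = -5.3522177606 (hand-computed)
  p <- mk_paired(10L, 0L, 0L, 10L)
  res <- paired_dm_test(p, min_males = 1L)
  expect_equal(res$tests$statistic, -5.3522177606, tolerance = 1e-9)
  expect_equal(res$tests$p_value, 8.688275e-08, tolerance = 1e-5)
  expect_equal(res$deltas$delta, -1)
})

test_that("identical counts give z = 0 and p = 1; thin sites are skipped", {
  p <- mk_paired(rep(5L, 8L), rep(5L, 8L), rep(5L, 8L), rep(5L, 8L))
  res <- paired_dm_test(p, min_males = 6L)
  expect_equal(res$tests$statistic, 0)
  expect_equal(res$tests$p_value, 1)
  thin <- mk_paired(rep(5L, 5L), rep(5L, 5L), rep(0L, 5L), rep(10L, 5L))
  expect_equal(nrow(paired_dm_test(thin, min_males = 6L)$tests), 0L)
})

test_that("null type-I error at alpha 0.001 sits in the binomial 99% band", {
  set.seed(61)
  nsite <- 10000L
  res <- paired_dm_test(null_paired(nsite, 12L, r = 0.5, mu = 30))
  frac <- mean(res$tests$p_value < 0.001)
  band <- 2.576 * sqrt(0.001 * 0.999 / nsite)
  expect_lt(abs(frac - 0.001), band)
  # and across the depth range of the study (10-40)
  set.seed(67)
  res2 <- paired_dm_test(null_paired(nsite, 12L, r = 0.5,
                                     mu = runif(nsite * 12L, 10, 40)))
  frac2 <- mean(res2$tests$p_value < 0.001)
  expect_lt(abs(frac2 - 0.001), band)
})

test_that("the paired test tracks an exact sign-flip permutation oracle", {
  set.seed(73)
  n_males <- 6L
  n_sites <- 200L
  p_wald <- p_perm <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    # sites span the study's depth range; a quarter carry a real effect
    shift <- if (runif(1L) < 0.25) 0.25 else 0
    mu <- runif(1L, 10, 40)
    df <- rnbinom(n_males, mu = mu, size = 8) + 1L
    dt_ <- rnbinom(n_males, mu = mu, size = 8) + 1L
    r <- runif(1L, 0.3, 0.7)
    paired <- mk_paired(rbinom(n_males, df, r), 0L,
                        rbinom(n_males, dt_, pmin(1, r + shift)), 0L)
    paired$n_unmeth_f <- df - paired$n_meth_f
    paired$n_unmeth_t <- dt_ - paired$n_meth_t
    res <- paired_dm_test(paired, min_males = n_males)
    p_wald[i] <- res$tests$p_value
    y_f <- asin(sqrt((paired$n_meth_f + 0.5) / (df + 1)))
    y_t <- asin(sqrt((paired$n_meth_t + 0.5) / (dt_ + 1)))
    v <- 1 / (4 * (dt_ + 1)) + 1 / (4 * (df + 1))
    p_perm[i] <- signflip_p(y_t - y_f, v)
  }
  expect_gt(cor(rank(p_wald), rank(p_perm)), 0.9)
})

test_that("DMC calling uses a strict threshold and classifies trends", {
  tests <- list(
    tests = data.table(chrom = "chr1", pos = 1:3, strand = "+",
                       n_males = 6L, statistic = c(5, -5, 1),
                       p_value = c(0.0005, 0.001, 0.5)),
    deltas = data.table(chrom = "chr1", pos = rep(1:3, each = 2L),
                        strand = "+", male = rep(1:2, 3L),
                        delta = c(0.4, 0.5, -0.4, -0.5, 0, 0)))
  dmcs <- call_dmcs(tests, alpha = 0.001)
  expect_equal(nrow(dmcs), 1L)  # p == alpha exactly is NOT a DMC
  expect_equal(dmcs$trend_class, "hyper")
  empty <- call_dmcs(list(tests = tests$tests[0], deltas = tests$deltas[0]))
  expect_equal(nrow(empty), 0L)
})

test_that("majority-trend classification follows the strict > 50% rule", {
  expect_equal(classify_dmc(c(rep(-0.2, 8L), rep(0.1, 4L))), "hypo")
  expect_equal(classify_dmc(c(rep(0.1, 6L), rep(-0.1, 6L))),
               "unclassified")
  expect_equal(classify_dmc(c(rep(0.1, 4L), rep(-0.1, 3L))), "hyper")
  # zeros dilute the majority but vote for neither side
  expect_equal(classify_dmc(c(0.1, 0.1, 0, 0)), "unclassified")
  expect_equal(classify_dmc(numeric()), "unclassified")
})

test_that("trend classes partition the called DMCs", {
  sim <- fixture_sim()
  res <- dmc_analysis(sim$counts, "DMSO")
  expect_gt(nrow(res$dmcs), 0L)
  expect_equal(sum(res$dmcs$trend_class %in%
                     c("hyper", "hypo", "unclassified")),
               nrow(res$dmcs))
})

test_that("Venn partition counts match brute-force membership", {
  a <- sprintf("chr1 %d +", 1:3)
  b <- sprintf("chr1 %d +", 11:14)
  c_ <- sprintf("chr1 %d +", 21:25)
  v <- overlap_counts(list(A = a, B = b, C = c_))
  expect_equal(unname(v[c("A", "B", "C")]), c(3L, 4L, 5L))
  expect_equal(sum(v[4:7]), 0L)
  v2 <- overlap_counts(list(A = a, B = a, C = a))
  expect_equal(unname(v2["A&B&C"]), 3L)
  expect_equal(sum(v2[1:6]), 0L)
  set.seed(79)
  keys <- sprintf("chr1 %d +", 1:40)
  sets <- lapply(1:3, function(i) sample(keys, 20L))
  names(sets) <- c("DMSO", "MeOH", "glycerol")
  v3 <- overlap_counts(sets)
  # oracle: enumerate membership of every key
  oracle <- integer(7L)
  for (k in unique(unlist(sets))) {
    inset <- vapply(sets, function(s) k %in% s, logical(1))
    lbl <- paste(names(sets)[inset], collapse = "&")
    oracle[match(lbl, names(v3))] <- oracle[match(lbl, names(v3))] + 1L
  }
  expect_equal(unname(v3), oracle)
  expect_equal(sum(v3), length(unique(unlist(sets))))
})

test_that("injected DMCs are recovered with their true direction", {
  cfg <- sim_config(seed = 11L, conditions = c("fresh", "DMSO"),
                    n_chrom = 1L, chrom_length = 300000L,
                    n_dmc_true = 200L, site_dropout_mean = 1)
  sim <- simulate_rrbs(cfg)
  res <- dmc_analysis(sim$counts, "DMSO")
  truth_key <- sim$truth$dmcs[, paste(chrom, pos, strand)]
  called_key <- res$dmcs[, paste(chrom, pos, strand)]
  recovery <- mean(truth_key %in% called_key)
  expect_gte(recovery, 0.8)
  hits <- merge(sim$truth$dmcs[, .(chrom, pos, strand, direction)],
                res$dmcs[, .(chrom, pos, strand, trend_class)],
                by = c("chrom", "pos", "strand"))
  expect_gte(mean(hits$direction == hits$trend_class), 0.9)
})
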