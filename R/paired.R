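#' Extract paired cytosines for one male
#'
#' A paired cytosine is a (chrom, pos, strand) site read with depth >= 1 in
#' both the fresh and the treated sample of the same male. Both count pairs
#' are retained; no depth filter beyond presence is applied (the bimodal
#' methylome makes even depth-1 calls informative).
#'
#' @param fresh,treated methylome tables for the same male.
#' @return data.table: chrom, pos, strand, n_meth_f, n_unmeth_f, n_meth_t,
#'   n_unmeth_t (plus male when present in the inputs).
#' @export
extract_paired <- function(fresh, treated) {
  f <- as.data.table(fresh)
  t_ <- as.data.table(treated)
  if ("male" %in% names(f) && "male" %in% names(t_)) {
    mf <- unique(f$male); mt <- unique(t_$male)
    if (length(mf) == 1L && length(mt) == 1L && mf != mt)
      stop(sprintf("male mismatch: fresh male %s vs treated male %s",
                   mf, mt))
  }
  out <- merge(f[, .(chrom, pos, strand, n_meth_f = n_meth,
                     n_unmeth_f = n_unmeth)],
               t_[, .(chrom, pos, strand, n_meth_t = n_meth,
                      n_unmeth_t = n_unmeth)],
               by = c("chrom", "pos", "strand"))
  if ("male" %in% names(f) && nrow(f) > 0L)
    out[, male := f$male[1L]]
  out[]
}

#' Build the paired-site table for one cryoprotectant across all males
#'
#' @param counts long methylome table (male + condition columns).
#' @param treatment the cryoprotectant condition.
#' @param fresh label of the fresh control condition.
#' @return long paired table: one row per male x paired site.
#' @export
build_paired_table <- function(counts, treatment, fresh = "fresh") {
  dt <- as.data.table(counts)
  if (!treatment %in% dt$condition)
    stop(sprintf("condition '%s' absent from the data", treatment))
  males <- sort(unique(dt$male))
  out <- lapply(males, function(m)
    extract_paired(dt[condition == fresh & male == m],
                   dt[condition == treatment & male == m]))
  rbindlist(out)
}

#' Sharing distribution of paired cytosines across males
#'
#' For each distinct paired site, how many males possess it; histogram over
#' 1..n_males as counts and percents of the distinct paired sites, plus the
#' cumulative percent of sites shared by at least `cum_min` males.
#'
#' @param paired long paired table from [build_paired_table()].
#' @param n_males total number of males in the design.
#' @param cum_min threshold for the cumulative percent (default 6).
#' @return list: `per_site` (site key + n_males_with_site), `histogram`
#'   (n_males, count, percent), `cum_pct_at_least` the cumulative percent.
#' @export
sharing_distribution <- function(paired, n_males = 12L, cum_min = 6L) {
  dt <- as.data.table(paired)
  per_site <- dt[, .(n_males_with_site = uniqueN(male)),
                 by = .(chrom, pos, strand)]
  counts <- tabulate(per_site$n_males_with_site, nbins = n_males)
  total <- nrow(per_site)
  hist <- data.table(n_males = seq_len(n_males), count = counts,
                     percent = if (total > 0L) 100 * counts / total
                               else rep(0, n_males))
  cum <- if (total > 0L) 100 * sum(counts[cum_min:n_males]) / total else 0
  list(per_site = per_site[], histogram = hist,
       cum_pct_at_least = cum)
}

#' Select paired sites shared by at least `min_males` males
#'
#' @param sharing result of [sharing_distribution()] (or its `per_site`).
#' @param min_males inclusive threshold (default 6).
#' @param n_males design size, for validation.
#' @return data.table of site keys.
#' @export
select_shared_sites <- function(sharing, min_males = 6L, n_males = 12L) {
  if (min_males > n_males)
    stop("min_males exceeds the number of males")
  per_site <- if (is.data.frame(sharing)) as.data.table(sharing)
              else sharing$per_site
  per_site[n_males_with_site >= min_males,
           .(chrom, pos, strand, n_males_with_site)]
}

#' Paired differential-methylation test (arcsine-link Wald test)
#'
#' Per informative male m, the methylation proportion is stabilized with
#' pseudocounts and an arcsine-square-root link:
#' y = arcsin(sqrt((n_meth + 0.5) / (depth + 1))). The paired difference
#' d_m = y_treated - y_fresh has delta-method variance
#' v_m = 1/(4 (depth_t + 1)) + 1/(4 (depth_f + 1)). The test statistic is
#' the inverse-variance-weighted mean difference divided by its standard
#' error: z = D / sqrt(1 / sum(1/v_m)) with
#' D = sum(d_m / v_m) / sum(1/v_m); two-sided p from the standard normal.
#' Pseudocounts keep the transform away from the degenerate 0/1 boundary
#' in the depth-1 regime the pairing admits.
#'
#' Sites with fewer than `min_males` informative males are skipped.
#'
#' @param paired long paired table.
#' @param min_males minimum number of informative males per site.
#' @return list: `tests` (chrom, pos, strand, n_males, statistic, p_value),
#'   `deltas` (chrom, pos, strand, male, delta) where delta is the raw
#'   treated-minus-fresh ratio difference used for trend classification.
#' @export
paired_dm_test <- function(paired, min_males = 6L) {
  dt <- as.data.table(paired)
  dt <- dt[, n_site := .N, by = .(chrom, pos, strand)][n_site >= min_males]
  if (nrow(dt) == 0L)
    return(list(tests = data.table(chrom = character(), pos = integer(),
                                   strand = character(),
                                   n_males = integer(),
                                   statistic = numeric(),
                                   p_value = numeric()),
                deltas = data.table(chrom = character(), pos = integer(),
                                    strand = character(), male = integer(),
                                    delta = numeric())))
  depth_f <- dt$n_meth_f + dt$n_unmeth_f
  depth_t <- dt$n_meth_t + dt$n_unmeth_t
  y_f <- asin(sqrt((dt$n_meth_f + 0.5) / (depth_f + 1)))
  y_t <- asin(sqrt((dt$n_meth_t + 0.5) / (depth_t + 1)))
  dt[, d := y_t - y_f]
  dt[, v := 1 / (4 * (depth_t + 1)) + 1 / (4 * (depth_f + 1))]
  dt[, delta := n_meth_t / depth_t - n_meth_f / depth_f]
  tests <- dt[, {
    w <- 1 / v
    D <- sum(d * w) / sum(w)
    z <- D * sqrt(sum(w))
    .(n_males = .N, statistic = z, p_value = 2 * pnorm(-abs(z)))
  }, by = .(chrom, pos, strand)]
  deltas <- dt[, .(chrom, pos, strand, male, delta)]
  list(tests = tests[], deltas = deltas[])
}

#' Classify a DMC's trend from its per-male deltas
#'
#' The denominator is the number of males possessing the paired site
#' (informative males). Positive deltas count toward hypermethylation,
#' negative toward hypomethylation, zeros toward neither; a class is
#' assigned only when its count strictly exceeds half the denominator.
#'
#' @param deltas numeric vector of per-male treated-minus-fresh ratio
#'   differences.
#' @return "hyper", "hypo" or "unclassified".
#' @export
classify_dmc <- function(deltas) {
  n <- length(deltas)
  if (n == 0L) return("unclassified")
  pos <- sum(deltas > 0)
  neg <- sum(deltas < 0)
  if (pos > n / 2) "hyper"
  else if (neg > n / 2) "hypo"
  else "unclassified"
}

#' Call DMCs at a raw p-value threshold and classify their trend
#'
#' A site is a DMC when p < alpha (strict). No multiple-testing correction
#' is applied by default; the raw threshold is the one the region rule
#' uses. Set `fdr = TRUE` to threshold Benjamini-Hochberg-adjusted
#' p-values instead.
#'
#' @param test_result list from [paired_dm_test()].
#' @param alpha significance threshold (default 0.001).
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @return data.table: site key, n_males, statistic, p_value, trend_class;
#'   the per-male deltas of the called DMCs are attached as the `deltas`
#'   attribute.
#' @export
call_dmcs <- function(test_result, alpha = 0.001, fdr = FALSE) {
  tests <- copy(test_result$tests)
  p <- if (fdr) stats::p.adjust(tests$p_value, "BH") else tests$p_value
  dmcs <- tests[p < alpha]
  deltas <- merge(test_result$deltas,
                  dmcs[, .(chrom, pos, strand)],
                  by = c("chrom", "pos", "strand"))
  cls <- deltas[, .(trend_class = classify_dmc(delta)),
                by = .(chrom, pos, strand)]
  out <- merge(dmcs, cls, by = c("chrom", "pos", "strand"),
               all.x = TRUE, sort = FALSE)
  out[is.na(trend_class), trend_class := "unclassified"]
  setorder(out, chrom, pos, strand)
  setattr(out, "deltas", deltas)
  out[]
}

#' Venn partition of DMC sets across the three cryoprotectants
#'
#' Counts of the 7 exclusive regions of a 3-set Venn diagram over site
#' keys.
#'
#' @param sets named list of 3 data.tables (or character key vectors) of
#'   DMC sites.
#' @return named integer vector: each exclusive region, named by the
#'   participating sets joined with "&".
#' @export
overlap_counts <- function(sets) {
  if (length(sets) != 3L) stop("exactly three DMC sets expected")
  keys <- lapply(sets, function(s) {
    if (is.character(s)) unique(s)
    else unique(paste(s$chrom, s$pos, s$strand))
  })
  nm <- names(keys)
  if (is.null(nm)) nm <- c("A", "B", "C")
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  out <- integer(7L)
  labels <- character(7L)
  i <- 0L
  for (size in 1:3) {
    for (combo in as.data.frame(combn(3L, size))) {
      i <- i + 1L
      labels[i] <- paste(nm[combo], collapse = "&")
      in_combo <- rowSums(member[, combo, drop = FALSE]) == size
      out_combo <- rowSums(member[, -combo, drop = FALSE]) == 0L
      out[i] <- sum(in_combo & out_combo)
    }
  }
  setNames(out, labels)
}

#' End-to-end DMC analysis for one cryoprotectant
#'
#' Pairing, sharing filter, paired test and DMC calling in one call.
#'
#' @param counts long methylome table.
#' @param treatment cryoprotectant condition.
#' @param fresh fresh-control label.
#' @param min_males sharing threshold (default 6).
#' @param alpha DMC threshold (default 0.001).
#' @param n_males design size.
#' @return list: `paired` (long paired table), `sharing`, `tests`,
#'   `dmcs` (called DMC table with trend classes).
#' @export
dmc_analysis <- function(counts, treatment, fresh = "fresh",
                         min_males = 6L, alpha = 0.001, n_males = 12L) {
  paired <- build_paired_table(counts, treatment, fresh)
  sharing <- sharing_distribution(paired, n_males = n_males,
                                  cum_min = min_males)
  test_result <- paired_dm_test(paired, min_males = min_males)
  dmcs <- call_dmcs(test_result, alpha = alpha)
  list(paired = paired, sharing = sharing, tests = test_result,
       dmcs = dmcs)
}
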