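#' Global mean methylation of a sample
#'
#' 100 x the unweighted mean of per-cytosine methylation ratios over
#' records with depth >= `min_depth`. The cytosine (not the read) is the
#' analysis unit, so deep sites do not dominate.
#'
#' @param records methylome table.
#' @param min_depth minimum sequencing depth for a cytosine to qualify.
#' @return percent.
#' @export
global_mean_methylation <- function(records, min_depth = 10L) {
  dt <- as.data.table(records)
  depth <- dt$n_meth + dt$n_unmeth
  keep <- depth >= min_depth
  if (!any(keep)) stop("no record passes the depth filter")
  100 * mean(dt$n_meth[keep] / depth[keep])
}

#' Methylation-ratio histogram in 20 classes of 0.05
#'
#' Bins are left-closed: [0, 0.05), ..., [0.90, 0.95), with the last bin
#' [0.95, 1] closed on both sides (a ratio of exactly 0.95 falls in the top
#' bin). Only cytosines with depth >= `min_depth` qualify.
#'
#' @param records methylome table.
#' @param min_depth depth filter (default 10).
#' @return data.table: bin (1-20), lower, upper, count, percent. Counts sum
#'   to the number of qualifying cytosines.
#' @export
bin_ratios <- function(records, min_depth = 10L) {
  dt <- as.data.table(records)
  depth <- dt$n_meth + dt$n_unmeth
  keep <- depth >= min_depth
  ratio <- dt$n_meth[keep] / depth[keep]
  # guard against binary round-off at bin edges (e.g. 19/20 * 20 < 19)
  bin <- pmin(floor(ratio * 20 + 1e-9) + 1L, 20L)
  counts <- tabulate(bin, nbins = 20L)
  n <- sum(counts)
  data.table(bin = 1:20,
             lower = seq(0, 0.95, by = 0.05),
             upper = seq(0.05, 1, by = 0.05),
             count = counts,
             percent = if (n > 0L) 100 * counts / n else rep(0, 20L))
}

#' PCA of samples over shared cytosines
#'
#' Builds the samples x sites ratio matrix over sites present in every
#' included sample (complete-case intersection; no imputation), centers it,
#' and returns the first two principal-component coordinates. Component
#' signs are fixed by convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param counts long methylome table with male and condition columns.
#' @param min_depth depth filter applied before intersecting.
#' @return list: `coords` (condition, male, PC1, PC2),
#'   `var_explained` (length-2 fractions), `n_sites` used.
#' @export
pca_samples <- function(counts, min_depth = 1L) {
  dt <- as.data.table(counts)
  dt <- dt[n_meth + n_unmeth >= min_depth]
  dt[, sample_id := paste(condition, male, sep = ":")]
  n_samples <- length(unique(dt$sample_id))
  if (n_samples < 3L) stop("PCA needs at least 3 samples")
  dt[, key := paste(chrom, pos, strand)]
  shared <- dt[, .N, by = key][N == n_samples, key]
  if (length(shared) < 2L)
    stop("fewer than 2 sites shared by all samples")
  sub <- dt[key %in% shared]
  sub[, ratio := n_meth / (n_meth + n_unmeth)]
  wide <- dcast(sub, sample_id ~ key, value.var = "ratio")
  ids <- wide$sample_id
  mat <- as.matrix(wide[, -1])
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  for (j in seq_len(k)) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  parts <- tstrsplit(ids, ":", fixed = TRUE)
  coords <- data.table(condition = parts[[1]],
                       male = as.integer(parts[[2]]),
                       PC1 = pc$x[, 1L],
                       PC2 = if (k > 1L) pc$x[, 2L] else 0)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, var_explained = ve[seq_len(k)],
       n_sites = length(shared))
}

#' Rank-based comparison of a quantity across conditions
#'
#' Omnibus Kruskal-Wallis test over all groups, followed by pairwise
#' two-sided Mann-Whitney (Wilcoxon rank-sum) tests. Ties use midranks.
#' Degenerate all-equal input returns p = 1.
#'
#' @param values named list of numeric vectors, one per condition.
#' @return list: `omnibus_p`, `pairwise` (data.table: group1, group2, p).
#' @export
rank_compare_conditions <- function(values) {
  if (length(values) < 2L) stop("need at least 2 groups")
  if (any(lengths(values) < 2L)) stop("each group needs n >= 2")
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)))
  omnibus_p <- if (length(unique(x)) == 1L) 1
               else kruskal.test(x, g)$p.value
  pairs <- combn(names(values), 2L)
  pw <- data.table(group1 = pairs[1L, ], group2 = pairs[2L, ], p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- values[[pairs[1L, i]]]
    b <- values[[pairs[2L, i]]]
    pw$p[i] <- if (length(unique(c(a, b))) == 1L) 1 else
      suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
  }
  list(omnibus_p = omnibus_p, pairwise = pw[])
}
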