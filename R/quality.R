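#' Per-male DMC burden
#'
#' The number of called DMCs at which the male is informative (possesses
#' the paired site) and shows a nonzero treated-minus-fresh delta. The
#' study's "DMC number" per male is not a cohort count; this counting rule
#' credits a male only with DMCs it actually expresses.
#'
#' @param dmcs called-DMC table from [call_dmcs()] (carries the per-male
#'   deltas as its `deltas` attribute), or a list with `dmcs`.
#' @param male male index; omit for all males at once.
#' @return integer count, or a data.table (male, n_dmc) when `male` is
#'   missing.
#' @export
per_male_dmc_count <- function(dmcs, male = NULL) {
  if (is.list(dmcs) && !is.data.frame(dmcs) && !is.null(dmcs$dmcs))
    dmcs <- dmcs$dmcs
  deltas <- attr(dmcs, "deltas")
  if (is.null(deltas)) stop("DMC table lacks per-male deltas")
  counts <- as.data.table(deltas)[delta != 0, .(n_dmc = .N), by = male]
  if (is.null(male)) return(counts[order(male)])
  hit <- match(male, counts$male)
  if (is.na(hit)) 0L else counts$n_dmc[hit]
}

#' Spearman rank correlation with permutation p-value
#'
#' Rank (monotone) correlation with midrank ties. The two-sided p-value is
#' computed by permutation of one vector: complete enumeration of all n!
#' permutations for n <= 7, otherwise a seeded Monte-Carlo sample of
#' permutations (the add-one estimator keeps p > 0). Constant vectors have
#' undefined rho and are flagged rather than tested.
#'
#' @param x,y paired numeric vectors, length >= 3, no missing pairs.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed seed for the Monte-Carlo branch.
#' @return list: rho, p_value, n, method ("exact" or "monte-carlo"),
#'   degenerate flag.
#' @export
spearman_perm <- function(x, y, n_perm = 20000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "none", degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 7L) {
    perms <- .all_permutations(n)
    rhos <- apply(perms, 1L, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    set.seed(seed)
    rhos <- replicate(n_perm, cor(rx, ry[sample.int(n)]))
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "monte-carlo"
  }
  list(rho = rho, p_value = p, n = n, method = method, degenerate = FALSE)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Correlate per-male DMC counts with a quality metric
#'
#' @param dmc_counts data.table (male, n_dmc) from [per_male_dmc_count()].
#' @param quality quality table (see [read_quality_table()]).
#' @param condition cryoprotectant whose quality values to use.
#' @param metric one of "membrane", "mito", "motility", "fert_norm".
#' @param ... passed to [spearman_perm()].
#' @return list as from [spearman_perm()] plus condition and metric.
#' @export
correlate_quality <- function(dmc_counts, quality, condition, metric,
                              ...) {
  cond_ <- condition
  q <- as.data.table(quality)[condition == cond_]
  merged <- merge(as.data.table(dmc_counts),
                  q[, c("male_id", metric), with = FALSE],
                  by.x = "male", by.y = "male_id")
  res <- spearman_perm(merged$n_dmc, merged[[metric]], ...)
  c(list(condition = condition, metric = metric), res)
}

#' Correlation screen over cryoprotectants and quality metrics
#'
#' Runs [correlate_quality()] for every cryoprotectant x metric pair;
#' degenerate pairs (constant metric, e.g. fertilization after glycerol)
#' are reported with `degenerate = TRUE` and no p-value.
#'
#' @param dmc_results named list of [dmc_analysis()] results (or called
#'   DMC tables), one per cryoprotectant.
#' @param quality quality table.
#' @param metrics metric columns to test.
#' @param ... passed to [spearman_perm()].
#' @return data.table: condition, metric, n, rho, p_value, method,
#'   degenerate.
#' @export
quality_correlation_screen <- function(dmc_results, quality,
                                       metrics = c("membrane", "mito",
                                                   "motility",
                                                   "fert_norm"),
                                       ...) {
  rows <- list()
  for (cond in names(dmc_results)) {
    counts <- per_male_dmc_count(dmc_results[[cond]])
    # males with zero expressed DMCs still belong in the correlation
    all_males <- unique(as.data.table(quality)[condition == cond,
                                               male_id])
    counts <- merge(data.table(male = all_males), counts, by = "male",
                    all.x = TRUE)
    counts[is.na(n_dmc), n_dmc := 0L]
    for (met in metrics) {
      res <- correlate_quality(counts, quality, cond, met, ...)
      rows[[length(rows) + 1L]] <- data.table(
        condition = cond, metric = met, n = res$n, rho = res$rho,
        p_value = res$p_value, method = res$method,
        degenerate = res$degenerate)
    }
  }
  rbindlist(rows)
}
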