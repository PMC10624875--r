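#' Simulation configuration for the synthetic RRBS generator
#'
#' Defaults emulate the study design the downstream analysis assumes: 12
#' males measured fresh and after cryopreservation with three
#' cryoprotectants; a strongly bimodal sperm methylome (most CpG cytosines
#' fully methylated, most of the rest fully unmethylated, global mean about
#' 86-87%); negative-binomial sequencing depth with median in the high
#' twenties; bisulfite conversion 99.6%; and injected differentially
#' methylated cytosines whose direction is shared by a majority of males.
#'
#' @param seed integer master seed; fanned out to per-stage substreams.
#' @param n_males number of males (paired design).
#' @param conditions condition labels; the first is the fresh control.
#' @param n_chrom,chrom_length toy genome shape (bases per chromosome).
#' @param mspi_density expected MspI (CCGG) sites per kb.
#' @param frag_min,frag_max RRBS size-selection bounds in bases.
#' @param p_methylated_site,p_unmethylated_site mixture weights of the fully
#'   methylated (ratio 1) and fully unmethylated (ratio 0) site classes; the
#'   remainder is intermediate with ratio ~ Uniform(0.05, 0.95).
#' @param depth_mean,depth_size negative-binomial depth model (mu / size).
#' @param conversion_rate probability that an unmethylated cytosine is
#'   bisulfite-converted (read as T); unconverted ones read as methylated.
#' @param over_conversion_rate probability that a methylated cytosine is
#'   spuriously converted; 0 by default.
#' @param site_dropout_mean mean per-sample inclusion probability of an
#'   observable site (Beta-distributed per-site propensity shared across
#'   samples, emulating fragments being sequenced in most males or few).
#' @param site_dropout_shape1 Beta shape1 of the propensity distribution
#'   (shape2 follows from the mean); values below 1 give the U-shaped,
#'   majority-shared sharing profile seen in real RRBS.
#' @param n_dmc_true injected DMCs per cryoprotectant.
#' @param dmc_effect absolute shift of the true ratio at injected DMCs.
#' @param dmc_concordance fraction of males sharing the injected direction.
#' @param n_genes toy genes emitted in the fixture GFF3.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_males = 12L,
                       conditions = c("fresh", "DMSO", "MeOH", "glycerol"),
                       n_chrom = 2L,
                       chrom_length = 1500000L,
                       mspi_density = 5,
                       frag_min = 40L,
                       frag_max = 220L,
                       p_methylated_site = 0.86,
                       p_unmethylated_site = 0.12,
                       depth_mean = 30,
                       depth_size = 8,
                       conversion_rate = 0.996,
                       over_conversion_rate = 0,
                       site_dropout_mean = 4 / 9,
                       site_dropout_shape1 = 0.5,
                       n_dmc_true = 300L,
                       dmc_effect = 0.5,
                       dmc_concordance = 0.75,
                       n_genes = 30L) {
  cfg <- list(seed = as.integer(seed), n_males = as.integer(n_males),
              conditions = conditions, n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              mspi_density = mspi_density, frag_min = as.integer(frag_min),
              frag_max = as.integer(frag_max),
              p_methylated_site = p_methylated_site,
              p_unmethylated_site = p_unmethylated_site,
              depth_mean = depth_mean, depth_size = depth_size,
              conversion_rate = conversion_rate,
              over_conversion_rate = over_conversion_rate,
              site_dropout_mean = site_dropout_mean,
              site_dropout_shape1 = site_dropout_shape1,
              n_dmc_true = as.integer(n_dmc_true), dmc_effect = dmc_effect,
              dmc_concordance = dmc_concordance,
              n_genes = as.integer(n_genes))
  if (cfg$p_methylated_site + cfg$p_unmethylated_site > 1)
    stop("mixture weights exceed 1")
  if (cfg$frag_min >= cfg$frag_max) stop("frag_min must be < frag_max")
  if (cfg$conversion_rate <= 0.9 || cfg$conversion_rate > 1)
    stop("conversion_rate must be in (0.9, 1]")
  if (cfg$chrom_length < cfg$frag_max)
    stop("chrom_length smaller than frag_max")
  structure(cfg, class = "sim_config")
}

#' Calibrate the mixture so its analytic mean hits a target
#'
#' Keeps the intermediate-class weight fixed and solves the fully-methylated
#' weight so that the analytic mean of the true-ratio mixture (ratio-1 sites
#' + intermediate sites at mean 0.5) equals `target_mean_pct`.
#'
#' @param config a `sim_config`.
#' @param target_mean_pct desired global mean methylation in percent.
#' @return the modified config.
#' @export
calibrate_mixture <- function(config, target_mean_pct) {
  p_int <- 1 - config$p_methylated_site - config$p_unmethylated_site
  p_meth <- target_mean_pct / 100 - p_int * 0.5
  if (p_meth < 0 || p_meth + p_int > 1)
    stop("target mean unreachable with this intermediate weight")
  config$p_methylated_site <- p_meth
  config$p_unmethylated_site <- 1 - p_meth - p_int
  config
}

#' Analytic mean of the true-ratio mixture, in percent
#' @param config a `sim_config`.
#' @export
mixture_mean_pct <- function(config) {
  p_int <- 1 - config$p_methylated_site - config$p_unmethylated_site
  100 * (config$p_methylated_site + p_int * 0.5)
}

# Deterministic per-stage substream: re-running one stage never perturbs the
# random numbers of another.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# Mutate away every CCGG occurrence (second C -> A); iterated because a
# mutation window can abut another occurrence.
.scrub_ccgg <- function(bases) {
  repeat {
    s <- paste0(bases, collapse = "")
    hits <- gregexpr("CCGG", s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(bases)
    bases[hits + 1L] <- "A"
  }
}

#' Build a toy genome with planted MspI sites
#'
#' Random A/C/G/T sequence per chromosome in which accidental CCGG motifs
#' are removed and CCGG sites are planted at approximately `mspi_density`
#' per kb (Poisson-distributed count, minimum spacing enforced so motifs
#' never overlap). Background CG dinucleotides occur at the random-sequence
#' rate and supply the bulk of the CpG sites; each CG dinucleotide at
#' (p, p+1) contributes two strand-resolved cytosines: (+, p) and (-, p+1).
#'
#' @param config a `sim_config`.
#' @return list with `genome` (DNAStringSet), `cpg_sites` (data.table:
#'   chrom, pos, strand, cpg_id with the two strands of one dinucleotide
#'   sharing cpg_id), `ccgg` (data.table of planted CCGG starts).
#' @export
build_toy_genome <- function(config) {
  set.seed(.stage_seed(config$seed, "genome"))
  L <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  seqs <- character(config$n_chrom)
  ccgg <- vector("list", config$n_chrom)
  for (k in seq_len(config$n_chrom)) {
    bases <- .scrub_ccgg(.random_bases(L))
    n_plant <- stats::rpois(1L, config$mspi_density * L / 1000)
    cand <- sort(sample.int(L - 4L, min(n_plant, L %/% 8L)))
    # enforce spacing >= 5 so planted motifs cannot overlap
    keep <- c(TRUE, diff(cand) >= 5L)
    cand <- cand[keep]
    # a C immediately before a planted CCGG would create a second,
    # overlapping CCGG; neutralize it
    prev <- cand - 1L
    prev <- prev[prev >= 1L]
    bases[prev][bases[prev] == "C"] <- "T"
    for (off in 0:3) bases[cand + off] <- c("C", "C", "G", "G")[off + 1L]
    seqs[k] <- paste0(bases, collapse = "")
    ccgg[[k]] <- data.table(chrom = chroms[k], pos = cand)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  sites <- vector("list", config$n_chrom)
  offset <- 0L
  for (k in seq_len(config$n_chrom)) {
    cg <- Biostrings::start(Biostrings::matchPattern(
      "CG", genome[[k]]))
    sites[[k]] <- data.table(
      chrom = rep(chroms[k], 2L * length(cg)),
      pos = c(cg, cg + 1L),
      strand = rep(c("+", "-"), each = length(cg)),
      cpg_id = rep(offset + seq_along(cg), 2L))
    offset <- offset + length(cg)
  }
  cpg_sites <- rbindlist(sites)
  setorder(cpg_sites, chrom, pos, strand)
  list(genome = genome, cpg_sites = cpg_sites, ccgg = rbindlist(ccgg))
}

#' In silico MspI digestion with size selection
#'
#' MspI cuts C^CGG: between the first C and the CGG of every CCGG motif.
#' Fragments outside `[frag_min, frag_max]` are discarded (RRBS size
#' selection); the retained fragments define which cytosines are observable.
#'
#' @param genome `DNAStringSet`.
#' @param frag_min,frag_max size-selection bounds in bases.
#' @return data.table: chrom, start, end, length, retained (logical), one
#'   row per fragment before size selection.
#' @export
digest_mspi <- function(genome, frag_min = 40L, frag_max = 220L) {
  out <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    L <- length(genome[[k]])
    cut_after <- Biostrings::start(Biostrings::matchPattern(
      "CCGG", genome[[k]]))
    starts <- c(1L, cut_after + 1L)
    ends <- c(cut_after, L)
    out[[k]] <- data.table(chrom = names(genome)[k], start = starts,
                           end = ends)
  }
  frags <- rbindlist(out)
  frags[, length := end - start + 1L]
  frags[, retained := length >= frag_min & length <= frag_max]
  frags[]
}

#' Mark cytosines observable under retained fragments
#'
#' @param cpg_sites data.table from [build_toy_genome()].
#' @param fragments data.table from [digest_mspi()].
#' @return `cpg_sites` with a logical `observable` column.
#' @export
mark_observable <- function(cpg_sites, fragments) {
  ret <- fragments[retained == TRUE]
  sites <- copy(cpg_sites)
  sites[, observable := FALSE]
  for (ch in unique(sites$chrom)) {
    f <- ret[chrom == ch]
    if (nrow(f) == 0L) next
    idx <- sites[chrom == ch, which = TRUE]
    p <- sites$pos[idx]
    j <- findInterval(p, f$start)
    ok <- j >= 1L & p <= f$end[pmax(j, 1L)]
    sites[idx[ok], observable := TRUE]
  }
  sites[]
}

#' Assign ground-truth methylation ratios and inject DMCs
#'
#' Baseline ratio per CpG dinucleotide (shared by its two strands, all
#' males and all conditions) from the three-component mixture. For each
#' cryoprotectant, `n_dmc_true` observable strand-resolved sites receive a
#' direction and a +/- `dmc_effect` shift, clipped to `[0, 1]`, applied in a
#' random subset of `ceiling(dmc_concordance * n_males)` males. When the
#' sampled direction cannot realize the full effect (e.g. hypermethylation
#' of an already fully methylated site), the opposite direction is used and
#' recorded, so every injected DMC is observable at full effect whenever
#' the baseline allows it.
#'
#' @param config a `sim_config`.
#' @param cpg_sites sites with `observable` column.
#' @return list of class `truth_table`: `sites` (with base_ratio), `dmcs`
#'   (condition, chrom, pos, strand, direction, effect, males list-column).
#' @export
assign_truth <- function(config, cpg_sites) {
  set.seed(.stage_seed(config$seed, "truth"))
  sites <- copy(cpg_sites)
  n_cpg <- max(sites$cpg_id)
  p_int <- 1 - config$p_methylated_site - config$p_unmethylated_site
  comp <- sample.int(3L, n_cpg, replace = TRUE,
                     prob = c(config$p_methylated_site,
                              config$p_unmethylated_site, p_int))
  base <- ifelse(comp == 1L, 1, ifelse(comp == 2L, 0, NA))
  n_int <- sum(comp == 3L)
  base[comp == 3L] <- runif(n_int, 0.05, 0.95)
  sites[, base_ratio := base[cpg_id]]
  treats <- setdiff(config$conditions, config$conditions[1L])
  obs_idx <- sites[observable == TRUE, which = TRUE]
  dmc_list <- vector("list", length(treats))
  n_conc <- ceiling(config$dmc_concordance * config$n_males)
  for (i in seq_along(treats)) {
    if (config$n_dmc_true > length(obs_idx))
      stop("n_dmc_true exceeds the number of observable sites")
    pick <- sample(obs_idx, config$n_dmc_true)
    r <- sites$base_ratio[pick]
    want <- sample(c(1, -1), config$n_dmc_true, replace = TRUE)
    head_up <- pmin(config$dmc_effect, 1 - r)   # achievable hyper shift
    head_dn <- pmin(config$dmc_effect, r)       # achievable hypo shift
    dir <- want
    flip <- (want == 1 & head_up < config$dmc_effect &
               head_dn > head_up) |
            (want == -1 & head_dn < config$dmc_effect &
               head_up > head_dn)
    dir[flip] <- -dir[flip]
    eff <- ifelse(dir == 1, head_up, head_dn)
    males <- replicate(config$n_dmc_true,
                       sort(sample.int(config$n_males, n_conc)),
                       simplify = FALSE)
    dmc_list[[i]] <- data.table(
      condition = treats[i],
      chrom = sites$chrom[pick], pos = sites$pos[pick],
      strand = sites$strand[pick],
      direction = ifelse(dir == 1, "hyper", "hypo"),
      effect = eff, base_ratio = r, males = males)
  }
  structure(list(sites = sites,
                 dmcs = if (length(dmc_list)) rbindlist(dmc_list)
                        else data.table(),
                 config = config),
            class = "truth_table")
}

#' True methylation ratio for one male x condition over all sites
#'
#' @param truth a `truth_table`.
#' @param condition condition label.
#' @param male male index.
#' @return numeric vector aligned with `truth$sites` rows.
#' @export
truth_ratio <- function(truth, condition, male) {
  r <- truth$sites$base_ratio
  if (nrow(truth$dmcs) == 0L || condition == truth$config$conditions[1L])
    return(r)
  cond <- condition
  d <- truth$dmcs[truth$dmcs$condition == cond]
  if (nrow(d) == 0L) return(r)
  hit <- vapply(d$males, function(m) male %in% m, logical(1))
  d <- d[hit]
  if (nrow(d) == 0L) return(r)
  key <- paste(truth$sites$chrom, truth$sites$pos, truth$sites$strand)
  idx <- match(paste(d$chrom, d$pos, d$strand), key)
  shift <- ifelse(d$direction == "hyper", d$effect, -d$effect)
  r[idx] <- pmin(1, pmax(0, r[idx] + shift))
  r
}

#' Simulate bisulfite read counts for the whole paired design
#'
#' Per site and sample: inclusion by the site's shared Beta propensity
#' (partial genome representation), depth ~ NegBin(depth_mean, depth_size),
#' methylated calls ~ Binomial(depth, r') with
#' r' = r (1 - over_conversion) + (1 - r)(1 - conversion_rate):
#' unconverted unmethylated cytosines read as methylated. Depth-0 records
#' are omitted.
#'
#' @param truth a `truth_table`.
#' @param config a `sim_config` (defaults to the one inside `truth`).
#' @return long data.table: chrom, pos, strand, n_meth, n_unmeth, male,
#'   condition; only observable, included, depth>0 records.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  set.seed(.stage_seed(config$seed, "counts"))
  obs <- truth$sites[observable == TRUE]
  n <- nrow(obs)
  b <- config$site_dropout_shape1
  propensity <- if (config$site_dropout_mean >= 1) rep(1, n)
    else rbeta(n, b, b * (1 - config$site_dropout_mean) /
                 config$site_dropout_mean)
  out <- vector("list", config$n_males * length(config$conditions))
  i <- 0L
  for (cond in config$conditions) {
    for (m in seq_len(config$n_males)) {
      i <- i + 1L
      keep <- runif(n) < propensity
      depth <- rnbinom(sum(keep), mu = config$depth_mean,
                       size = config$depth_size)
      r <- truth_ratio(truth, cond, m)[truth$sites$observable][keep]
      r_obs <- r * (1 - config$over_conversion_rate) +
        (1 - r) * (1 - config$conversion_rate)
      n_meth <- rbinom(sum(keep), depth, r_obs)
      nonzero <- depth > 0L
      out[[i]] <- data.table(
        chrom = obs$chrom[keep][nonzero], pos = obs$pos[keep][nonzero],
        strand = obs$strand[keep][nonzero],
        n_meth = n_meth[nonzero],
        n_unmeth = depth[nonzero] - n_meth[nonzero],
        male = m, condition = cond)
    }
  }
  rbindlist(out)
}

#' Run the full generator in memory
#'
#' genome -> MspI digestion -> truth assignment -> count simulation.
#'
#' @param config a `sim_config`.
#' @return list: genome, cpg_sites (with observability), fragments, truth,
#'   counts (long data.table), config.
#' @export
simulate_rrbs <- function(config = sim_config()) {
  g <- build_toy_genome(config)
  frags <- digest_mspi(g$genome, config$frag_min, config$frag_max)
  sites <- mark_observable(g$cpg_sites, frags)
  truth <- assign_truth(config, sites)
  counts <- simulate_counts(truth, config)
  list(genome = g$genome, cpg_sites = sites, fragments = frags,
       truth = truth, counts = counts, config = config)
}

#' Simulate the sperm-quality table
#'
#' Values mimic the study's condition ordering: membrane and mitochondria
#' quality DMSO >= glycerol >= MeOH; motility and fertilization
#' DMSO > MeOH > glycerol, with glycerol losing motility and fertilization
#' entirely (all zeros). Fertilization is normalized to the fresh-control
#' mean (so fresh averages 100 and values may exceed 100).
#'
#' @param config a `sim_config`.
#' @return data.table: male_id, condition, membrane, mito, motility,
#'   fert_norm.
#' @export
simulate_quality <- function(config = sim_config()) {
  set.seed(.stage_seed(config$seed, "quality"))
  spec <- list(
    fresh    = c(membrane = 98, mb_sd = 1,  mito = 90, mt_sd = 4,
                 motility = 99, mo_sd = 1,  fert = 100, ft_sd = 10),
    DMSO     = c(membrane = 84, mb_sd = 5,  mito = 60, mt_sd = 8,
                 motility = 25, mo_sd = 10, fert = 55,  ft_sd = 18),
    MeOH     = c(membrane = 55, mb_sd = 15, mito = 15, mt_sd = 8,
                 motility = 5,  mo_sd = 4,  fert = 15,  ft_sd = 10),
    glycerol = c(membrane = 80, mb_sd = 6,  mito = 55, mt_sd = 8,
                 motility = 0,  mo_sd = 0,  fert = 0,   ft_sd = 0))
  rows <- lapply(config$conditions, function(cond) {
    p <- spec[[cond]]
    if (is.null(p)) p <- spec$fresh
    n <- config$n_males
    clip <- function(x) pmin(100, pmax(0, x))
    data.table(
      male_id = seq_len(n), condition = cond,
      membrane = round(clip(rnorm(n, p["membrane"], p["mb_sd"])), 1),
      mito = round(clip(rnorm(n, p["mito"], p["mt_sd"])), 1),
      motility = round(clip(rnorm(n, p["motility"], p["mo_sd"])), 1),
      fert_norm = round(pmax(0, rnorm(n, p["fert"], p["ft_sd"])), 1))
  })
  rbindlist(rows)
}

#' Simulate toy gene models and write them as GFF3
#'
#' Random non-overlapping genes with 1-5 exons each, both strands.
#'
#' @param config a `sim_config`.
#' @param genome `DNAStringSet` (for chromosome bounds).
#' @param path optional GFF3 output path.
#' @return data.table of gene/mRNA/exon features (1-based closed).
#' @export
simulate_genes <- function(config, genome, path = NULL) {
  set.seed(.stage_seed(config$seed, "genes"))
  feats <- list()
  gid <- 0L
  per_chrom <- ceiling(config$n_genes / length(genome))
  for (k in seq_along(genome)) {
    L <- length(genome[[k]])
    ch <- names(genome)[k]
    slots <- floor(L / per_chrom)
    for (j in seq_len(per_chrom)) {
      if (gid >= config$n_genes) break
      gid <- gid + 1L
      lo <- (j - 1L) * slots + 1L
      glen <- sample(2000:min(8000, slots - 2L), 1L)
      gstart <- lo + sample.int(max(1L, slots - glen - 1L), 1L)
      gend <- gstart + glen - 1L
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample.int(5L, 1L)
      # exon boundaries: split the span into 2*n_ex-1 blocks
      cuts <- sort(sample.int(glen - 1L, 2L * n_ex - 1L))
      bnd <- c(0L, cuts, glen)
      ex_start <- gstart + bnd[seq(1L, 2L * n_ex, by = 2L)]
      ex_end <- gstart + bnd[seq(2L, 2L * n_ex + 1L, by = 2L)] - 1L
      ex_start[1L] <- gstart
      ex_end[n_ex] <- gend
      gene_id <- sprintf("gene%03d", gid)
      feats[[length(feats) + 1L]] <- data.table(
        chrom = ch, type = "gene", start = gstart, end = gend,
        strand = strand, id = gene_id, parent = NA_character_)
      feats[[length(feats) + 1L]] <- data.table(
        chrom = ch, type = "mRNA", start = gstart, end = gend,
        strand = strand, id = paste0(gene_id, ".t1"), parent = gene_id)
      feats[[length(feats) + 1L]] <- data.table(
        chrom = ch, type = "exon", start = ex_start, end = ex_end,
        strand = strand,
        id = sprintf("%s.e%d", gene_id, seq_len(n_ex)),
        parent = paste0(gene_id, ".t1"))
    }
  }
  dt <- rbindlist(feats)
  if (!is.null(path)) {
    attr_col <- ifelse(is.na(dt$parent),
                       sprintf("ID=%s", dt$id),
                       sprintf("ID=%s;Parent=%s", dt$id, dt$parent))
    lines <- sprintf("%s\tcryomethyl\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     dt$chrom, dt$type, dt$start, dt$end, dt$strand,
                     attr_col)
    writeLines(c("##gff-version 3", lines), path)
  }
  dt[]
}

#' Write a complete on-disk fixture set
#'
#' Emits, reproducibly from the seed: the toy genome FASTA, per-sample
#' Bismark coverage and CX report files (one each per male x condition),
#' a toy GFF3, the quality-table CSV, and truth tables (site baselines and
#' injected DMCs).
#'
#' @param config a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the list from [simulate_rrbs()] plus file paths.
#' @export
write_fixture_set <- function(config, outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2L) != 0L)
    stop(sprintf("output directory '%s' is not writable", outdir))
  sim <- simulate_rrbs(config)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  simulate_genes(config, sim$genome, file.path(outdir, "genes.gff3"))
  write_quality_table(simulate_quality(config),
                      file.path(outdir, "quality.csv"))
  for (cond in config$conditions) {
    for (m in seq_len(config$n_males)) {
      rec <- sim$counts[condition == cond & male == m]
      stem <- sprintf("%s_male%02d", cond, m)
      write_bismark_coverage(rec, file.path(outdir, paste0(stem, ".cov")))
      write_cx_report(rec, file.path(outdir, paste0(stem, ".CX_report.txt")))
    }
  }
  fwrite(sim$truth$sites, file.path(outdir, "truth_sites.tsv"), sep = "\t")
  dmcs <- copy(sim$truth$dmcs)
  if (nrow(dmcs) > 0L)
    dmcs[, males := vapply(males, paste, character(1), collapse = ",")]
  fwrite(dmcs, file.path(outdir, "truth_dmcs.tsv"), sep = "\t")
  jsonlite::write_json(unclass(config),
                       file.path(outdir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(outdir = outdir)))
}
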