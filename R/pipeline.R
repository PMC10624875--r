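#' Pipeline configuration
#'
#' Bundles the simulation settings and every analysis parameter. All
#' defaults are the study's printed values: depth filter 10 for the
#' ratio histogram, sharing threshold 6 males, DMC threshold p < 0.001,
#' DMR rule 50 b / 5 CpGs / 75% DMCs, sensitive-region gap 100 b,
#' promoter 5 kb, downstream 1 kb.
#'
#' @param outdir output directory for stage tables and the manifest.
#' @param sim a `sim_config` for the synthetic study; its first condition
#'   is the fresh control.
#' @param min_depth depth filter for global summaries.
#' @param min_males paired-site sharing threshold.
#' @param alpha DMC p-value threshold.
#' @param dmr_window,dmr_min_cpg,dmr_min_frac DMR window rule.
#' @param max_gap sensitive-region chaining distance.
#' @param promoter_len,downstream_len annotation window lengths.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = sim_config(),
                            min_depth = 10L, min_males = 6L,
                            alpha = 0.001, dmr_window = 50L,
                            dmr_min_cpg = 5L, dmr_min_frac = 0.75,
                            max_gap = 100L, promoter_len = 5000L,
                            downstream_len = 1000L) {
  structure(list(outdir = outdir, sim = sim, min_depth = min_depth,
                 min_males = min_males, alpha = alpha,
                 dmr_window = dmr_window, dmr_min_cpg = dmr_min_cpg,
                 dmr_min_frac = dmr_min_frac, max_gap = max_gap,
                 promoter_len = promoter_len,
                 downstream_len = downstream_len),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic study end to end
#'
#' simulate -> genome representation -> global methylation -> paired DMC
#' calling (one run per cryoprotectant) -> DMR / sensitive-region
#' detection and annotation -> quality correlation. Stage tables are
#' written as TSV under `config$outdir` together with a JSON run manifest
#' (seed, parameters, per-stage row counts). Deterministic given the seed.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  sim_cfg <- config$sim

  say("stage simulate: %d males x %d conditions", sim_cfg$n_males,
      length(sim_cfg$conditions))
  sim <- .stage("simulate", simulate_rrbs(sim_cfg))
  quality <- .stage("simulate", simulate_quality(sim_cfg))
  genes_path <- out("genes.gff3")
  .stage("simulate", simulate_genes(sim_cfg, sim$genome, genes_path))
  genes <- .stage("simulate", read_gff3_genes(genes_path))

  say("stage represent")
  n_genomic <- .stage("represent",
                      count_genomic_cpg_cytosines(sim$genome))
  rep_sum <- .stage("represent",
                    representation_summary(sim$counts, n_genomic))
  fwrite(rep_sum$samples, out("representation_samples.tsv"), sep = "\t")
  fwrite(rep_sum$conditions, out("representation_conditions.tsv"),
         sep = "\t")

  say("stage global")
  global <- .stage("global", sim$counts[, .(
    mean_pct = global_mean_methylation(.SD, config$min_depth)),
    by = .(condition, male)])
  fwrite(global, out("global_means.tsv"), sep = "\t")
  hist_fresh <- .stage("global", bin_ratios(
    sim$counts[condition == sim_cfg$conditions[1L]], config$min_depth))
  fwrite(hist_fresh, out("ratio_histogram_fresh.tsv"), sep = "\t")
  omnibus <- .stage("global", rank_compare_conditions(
    split(global$mean_pct, global$condition)))

  treats <- setdiff(sim_cfg$conditions, sim_cfg$conditions[1L])
  dmc_results <- list()
  for (tr in treats) {
    say("stage dmc: %s", tr)
    dmc_results[[tr]] <- .stage(paste0("dmc:", tr), dmc_analysis(
      sim$counts, tr, fresh = sim_cfg$conditions[1L],
      min_males = config$min_males, alpha = config$alpha,
      n_males = sim_cfg$n_males))
    fwrite(dmc_results[[tr]]$dmcs, out(sprintf("dmc_%s.tsv", tr)),
           sep = "\t")
  }
  venn <- if (length(treats) == 3L)
    overlap_counts(lapply(dmc_results, `[[`, "dmcs")) else NULL

  say("stage regions")
  all_dmcs <- rbindlist(lapply(names(dmc_results), function(tr)
    dmc_results[[tr]]$dmcs[, .(chrom, pos, strand, condition = tr)]))
  sensitive <- .stage("regions",
                      detect_sensitive_regions(all_dmcs, config$max_gap))
  dmrs <- .stage("regions", rbindlist(lapply(names(dmc_results),
    function(tr) {
      d <- detect_dmrs(dmc_results[[tr]]$tests$tests,
                       window = config$dmr_window,
                       min_cpg = config$dmr_min_cpg,
                       min_frac = config$dmr_min_frac,
                       alpha = config$alpha)
      if (nrow(d)) d[, condition := tr]
      d
    }), fill = TRUE))
  if (nrow(sensitive) > 0L)
    sensitive <- .stage("regions", annotate_region(
      sensitive, genes, config$promoter_len, config$downstream_len))
  fwrite(sensitive, out("sensitive_regions.tsv"), sep = "\t")
  fwrite(dmrs, out("dmrs.tsv"), sep = "\t")

  say("stage correlate")
  correlations <- .stage("correlate", quality_correlation_screen(
    dmc_results, quality, seed = sim_cfg$seed))
  fwrite(correlations, out("quality_correlations.tsv"), sep = "\t")

  manifest <- list(
    seed = sim_cfg$seed,
    parameters = unclass(config[setdiff(names(config),
                                        c("outdir", "sim"))]),
    sim_parameters = unclass(sim_cfg),
    n_samples = sim_cfg$n_males * length(sim_cfg$conditions),
    rows = list(
      counts = nrow(sim$counts),
      representation_samples = nrow(rep_sum$samples),
      global_means = nrow(global),
      dmc_tables = length(dmc_results),
      dmcs = vapply(dmc_results, function(r) nrow(r$dmcs), integer(1)),
      sensitive_regions = nrow(sensitive),
      dmrs = nrow(dmrs),
      correlations = nrow(correlations)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, quality = quality, genes = genes,
                 n_genomic = n_genomic, representation = rep_sum,
                 global = global, histogram_fresh = hist_fresh,
                 omnibus = omnibus, dmc = dmc_results, venn = venn,
                 sensitive = sensitive, dmrs = dmrs,
                 correlations = correlations, manifest = manifest))
}
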