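# One-command end-to-end run over a simulated (or on-disk) data set:
# simulate -> write standard files -> read back -> call TSSs -> classify ->
# promoters -> normalization/TE -> buffering, with a machine-readable run
# manifest. The numbered scripts under analysis/ are thin narrative
# drivers over this module.

#' Default pipeline thresholds
#'
#' All stage parameters in one place: clustering gap 100 bp, sd threshold
#' 10, minimum cluster reads 3, TEX- window +/-5 bp, classification window
#' -500..+150, leaderless max 8 nt, long leader min 151 nt, fold-change 2,
#' alpha 0.05, 16 pattern groups, TE pseudocount 1.
#'
#' @return Named list of thresholds.
#' @export
run_thresholds <- function() {
  list(cluster_gap = 100, sd_threshold = 10, min_reads = 3,
       control_window = 5, upstream = 500, downstream = 150,
       leaderless_max = 8, long_leader_min = 151,
       fc_threshold = 2, alpha = 0.05, k_groups = 16, te_pseudocount = 1)
}

#' Run the full pipeline on a synthetic data set
#'
#' Simulates a data set, round-trips it through the standard file formats,
#' then runs TSS calling, classification, promoter analysis, expression/TE
#' and buffering analysis, writing stage outputs and a JSON manifest
#' (package version, seed, thresholds, per-stage record counts) under
#' `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param thresholds Threshold list, see [run_thresholds()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_all <- function(config = sim_config(), out_dir,
                    thresholds = run_thresholds()) {
  th <- utils::modifyList(run_thresholds(), thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  sim <- stage("simulate", simulate_dataset(config))
  input_dir <- file.path(out_dir, "inputs")
  paths <- stage("write_inputs", write_simulation(sim, input_dir))

  # read everything back through the format layer
  genome <- stage("read", read_fasta(paths$fasta))
  genes <- stage("read", read_gff(paths$gff))
  tex_plus <- list(
    "+" = stage("read", read_bedgraph(paths$tex_plus_fwd, "TEX_plus", "+")),
    "-" = stage("read", read_bedgraph(paths$tex_plus_rev, "TEX_plus", "-")))
  tex_minus <- list(
    "+" = stage("read", read_bedgraph(paths$tex_minus_fwd, "TEX_minus", "+")),
    "-" = stage("read", read_bedgraph(paths$tex_minus_rev, "TEX_minus", "-")))
  mrna <- stage("read", read_counts(paths$mrna))
  rpf <- stage("read", read_counts(paths$rpf))
  phase <- sim$phase

  called <- stage("call", call_tss(
    tex_plus, tex_minus, min_reads = th$min_reads,
    cluster_gap = th$cluster_gap, sd_threshold = th$sd_threshold,
    control_window = th$control_window))

  records <- stage("classify", classify_tss(
    called, genes, upstream = th$upstream, downstream = th$downstream,
    leaderless_max = th$leaderless_max,
    long_leader_min = th$long_leader_min))
  write_tss_table(records, file.path(out_dir, "tss_classified.tsv"),
                  seqname = genome$name)

  promoters <- stage("promoters", promoter_table(records, genome))
  utils::write.table(promoters, file.path(out_dir, "promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  expr <- stage("expr", {
    sf_m <- size_factors(mrna)
    sf_r <- size_factors(rpf)
    norm_m <- normalize_counts(mrna, sf_m)
    norm_r <- normalize_counts(rpf, sf_r)
    phase_m <- collapse_replicates(norm_m, phase)
    phase_r <- collapse_replicates(norm_r, phase)
    cut <- expressed_cutoff(phase_m,
                            genes$gene_id[genes$category == "secondary_metabolic"])
    flags <- differential_flags(mrna, phase, sf = sf_m,
                                fc_threshold = th$fc_threshold,
                                alpha = th$alpha,
                                expressed = cut$expressed,
                                exclude = terminal_gene_ids(genes))
    te <- translation_efficiency(phase_r, phase_m,
                                 pseudocount = th$te_pseudocount)
    list(sf_mrna = sf_m, sf_rpf = sf_r, phase_mrna = phase_m,
         phase_rpf = phase_r, cutoff = cut, flags = flags, te = te)
  })
  write_counts(round(expr$phase_mrna, 3), file.path(out_dir, "mrna_phase_norm.tsv"))
  write_counts(round(expr$phase_rpf, 3), file.path(out_dir, "rpf_phase_norm.tsv"))

  buffering <- stage("buffering", {
    slopes <- lapply(c("T", "L", "S"), function(p) {
      dm <- phase_log2fc(expr$phase_mrna, "M", p)
      dte <- phase_log2fc(expr$te$te, "M", p, pseudocount = 0)
      buffering_correlation(dm, dte, category = genes$category)
    })
    names(slopes) <- c("T", "L", "S")
    k <- min(th$k_groups, nrow(expr$phase_mrna))
    groups <- pattern_groups(expr$phase_mrna, expr$phase_rpf, k = k)
    trends <- trend_groups(expr$phase_mrna, expr$phase_rpf)
    stoich <- if (any(!is.na(genes$operon_id))) {
      stoichiometry_check(normalize_counts(rpf, expr$sf_rpf), genes)
    } else NULL
    list(slopes = slopes, groups = groups, trends = trends, stoich = stoich)
  })
  utils::write.table(buffering$groups, file.path(out_dir, "pattern_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(buffering$stoich)) {
    utils::write.table(buffering$stoich, file.path(out_dir, "stoichiometry.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "txlandscape",
    version = as.character(utils::packageVersion("txlandscape")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    thresholds = th,
    n_genes = nrow(genes),
    n_called_tss = nrow(called),
    n_classified = nrow(records),
    class_counts = as.list(table(records$class_label)),
    cutoff = expr$cutoff$cutoff,
    buffering_slope_S = buffering$slopes$S$overall$slope
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, genes = genes, called = called,
                 records = records, promoters = promoters, expr = expr,
                 buffering = buffering, manifest = manifest))
}
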