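# Synthetic-data generator with planted ground truth. It emulates the
# study design the pipeline targets: a high-G+C single-chromosome
# bacterial genome; TEX+/TEX- 5'-end profiles with sharp peaks at planted
# TSSs (TEX-enriched), RNA-processing-site peaks only in TEX-, and uniform
# background; and mRNA/RPF negative-binomial count matrices over four
# growth phases with planted fold-changes, a planted translational
# buffering slope, and operons with known subunit stoichiometry.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: genome G+C 0.721,
#' purine at the TSS (+1) 0.879, 21% leaderless and 15.3% long-leader
#' primary TSSs with leadered 5'-UTRs around a 44-nt median, start codon
#' usage ATG/GTG/TTG = 0.584/0.371/0.045, four growth phases (M, T, L, S)
#' in duplicate, and planted -10/-35 promoters with 15-20-nt spacers.
#'
#' @param seed Integer RNG seed.
#' @param genome_length Genome length in bp (must be >= 1000 * n_genes).
#' @param n_genes Number of genes.
#' @param n_tss Number of planted (primary) TSSs (<= n_genes).
#' @param leaderless_fraction Fraction of planted TSSs with UTR < 9 nt.
#' @param long_leader_fraction Fraction with UTR > 150 nt.
#' @param tss_height_mean NB mean of TEX+ peak height at planted TSSs.
#' @param peak_nb_size NB size (inverse overdispersion) of peak heights.
#' @param tex_minus_retention Fraction of the TEX+ peak height retained in
#'   TEX- (primary 5' ends persist in the untreated library).
#' @param processing_site_rate RNA-processing sites per kb (TEX- only).
#' @param background_rate Uniform background reads per kb per library.
#' @param nb_dispersion NB dispersion of counts (`Var = mu + d mu^2`).
#' @param buffering_slope Planted slope of delta-log-TE on delta-log-mRNA,
#'   in `[-1, 0]` (0 = no buffering, -1 = complete buffering).
#' @param phase_foldchange_sd SD of per-gene log2 fold-changes per phase.
#' @param rpf_extra_sd SD of the RPF-specific log2 noise term.
#' @param n_reps Replicates per growth phase.
#' @param gc Genome G+C content.
#' @param tss_purine_fraction Purine fraction planted at the TSS (+1).
#' @param secondary_fraction Fraction of genes tagged "secondary_metabolic".
#' @param regulator_fraction Fraction tagged "regulator".
#' @param mrna_mean Baseline mRNA abundance (expected normalized counts
#'   per kb at the reference phase).
#' @param operon_mean Baseline abundance of operon transcripts (the
#'   stoichiometry analysis targets highly expressed complexes).
#' @param n_diff_genes Genes planted with a fixed fold-change (for power
#'   studies).
#' @param diff_log2fc Planted log2 fold-change of those genes at phases
#'   T and L.
#' @param plant_promoters Plant -10/-35 hexamers upstream of each TSS.
#' @param spacer_range Planted -35/-10 spacer lengths (nt).
#' @param include_operons Plant the 1:4 and 1:10:2:1:3:1:3:1 operons.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_genes = 50L,
                       n_tss = n_genes,
                       leaderless_fraction = 0.21,
                       long_leader_fraction = 0.153,
                       tss_height_mean = 50,
                       peak_nb_size = 5,
                       tex_minus_retention = 0.5,
                       processing_site_rate = 0.2,
                       background_rate = 0.2,
                       nb_dispersion = 0.01,
                       buffering_slope = -0.5,
                       phase_foldchange_sd = 1,
                       rpf_extra_sd = 0.1,
                       n_reps = 2L,
                       gc = 0.721,
                       tss_purine_fraction = 0.879,
                       secondary_fraction = 0.1,
                       regulator_fraction = 0.1,
                       mrna_mean = 500,
                       operon_mean = 2000,
                       n_diff_genes = 0L,
                       diff_log2fc = 2,
                       plant_promoters = TRUE,
                       spacer_range = 15:20,
                       include_operons = TRUE) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes), n_tss = as.integer(n_tss),
              leaderless_fraction = leaderless_fraction,
              long_leader_fraction = long_leader_fraction,
              tss_height_mean = tss_height_mean, peak_nb_size = peak_nb_size,
              tex_minus_retention = tex_minus_retention,
              processing_site_rate = processing_site_rate,
              background_rate = background_rate,
              nb_dispersion = nb_dispersion,
              buffering_slope = buffering_slope,
              phase_foldchange_sd = phase_foldchange_sd,
              rpf_extra_sd = rpf_extra_sd, n_reps = as.integer(n_reps),
              gc = gc, tss_purine_fraction = tss_purine_fraction,
              secondary_fraction = secondary_fraction,
              regulator_fraction = regulator_fraction,
              mrna_mean = mrna_mean, operon_mean = operon_mean,
              n_diff_genes = as.integer(n_diff_genes),
              diff_log2fc = diff_log2fc,
              plant_promoters = plant_promoters, spacer_range = spacer_range,
              include_operons = include_operons)
  props <- c(cfg$leaderless_fraction, cfg$long_leader_fraction,
             cfg$tex_minus_retention, cfg$gc, cfg$tss_purine_fraction,
             cfg$secondary_fraction, cfg$regulator_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$buffering_slope < -1 || cfg$buffering_slope > 0) {
    stop("buffering_slope must lie in [-1, 0]")
  }
  if (cfg$genome_length < 10L * cfg$n_genes * 100L) {
    stop("config error: genome_length must be >= 1000 * n_genes")
  }
  if (cfg$n_tss > cfg$n_genes) stop("n_tss must be <= n_genes")
  class(cfg) <- "sim_config"
  cfg
}

revcomp_chars <- function(ch) rev(chartr("ACGTN", "TGCAN", ch))

# write an oriented motif (letters read 5'->3' on `strand`) starting at
# offset `off` relative to the TSS into the genome character vector
plant_oriented <- function(gvec, tss, strand, off, letters) {
  k <- length(letters)
  if (strand == "+") {
    gvec[tss + off + seq_len(k) - 1L] <- letters
  } else {
    gvec[tss - off - seq_len(k) + 1L] <- chartr("ACGTN", "TGCAN", letters)
  }
  gvec
}

#' Simulate a genome, annotation and TSS ground truth
#'
#' Places non-overlapping genes on both strands of a random genome at the
#' configured G+C, tags a subset "secondary_metabolic", plants two operons
#' with known stoichiometry (a 1:4 two-gene operon and an eight-gene
#' 1:10:2:1:3:1:3:1 operon) when the gene count allows, writes real start
#' codons, and plants one TSS per selected gene with the configured
#' leaderless/long-leader mix, a purine-biased +1 base and -10/-35
#' promoter hexamers at a known spacer.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([genome_seq()]), `genes` (gene table) and
#'   `truth` (list holding `tss_truth` etc.).
#' @export
simulate_genome_annotation <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  n <- config$n_genes
  base_p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
  gvec <- sample(names(base_p), L, replace = TRUE, prob = base_p)

  slot <- L %/% n
  if (slot < 1000L) stop("config error: gene slots too small")
  up_margin <- 300L
  max_len <- min(900L, slot - 400L)
  lens <- sample(300:max_len, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # operons: adjacent same-strand genes of equal length so count-level and
  # per-kb stoichiometric ratios coincide
  operon_id <- rep(NA_character_, n)
  stoich <- rep(NA_integer_, n)
  if (config$include_operons && n >= 12L) {
    mid <- n %/% 2L
    opA <- c(mid - 1L, mid)
    operon_id[opA] <- "op_rpl"
    stoich[opA] <- c(1L, 4L)
    if (n >= 18L) {
      opB <- (mid + 2L):(mid + 9L)
      operon_id[opB] <- "op_atp"
      stoich[opB] <- c(1L, 10L, 2L, 1L, 3L, 1L, 3L, 1L)
    }
    opidx <- which(!is.na(operon_id))
    strand[opidx] <- "+"
    lens[opidx] <- 600L
  }

  s0 <- (seq_len(n) - 1L) * slot
  start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      start[i] <- s0[i] + up_margin + 1L
      end[i] <- start[i] + lens[i] - 1L
    } else {
      end[i] <- s0[i] + slot - up_margin
      start[i] <- end[i] - lens[i] + 1L
    }
  }
  if (any(end > L) || any(start < 1L) ||
      any(start[-1L] <= end[-n])) {
    stop("config error: genes cannot be placed without overlap")
  }

  category <- rep("other", n)
  free <- which(is.na(operon_id))
  n_sec <- round(config$secondary_fraction * n)
  sec <- sample(free, min(n_sec, length(free)))
  category[sec] <- "secondary_metabolic"
  free2 <- setdiff(free, sec)
  n_reg <- round(config$regulator_fraction * n)
  category[sample(free2, min(n_reg, length(free2)))] <- "regulator"

  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    start = start, end = end, strand = strand,
    category = category, operon_id = operon_id, stoichiometry = stoich,
    stringsAsFactors = FALSE
  )

  # start codons written into the sequence
  codon_usage <- c(ATG = 0.584, GTG = 0.371, TTG = 0.045)
  codons <- sample(names(codon_usage), n, replace = TRUE, prob = codon_usage)
  for (i in seq_len(n)) {
    cl <- strsplit(codons[i], "")[[1L]]
    if (strand[i] == "+") {
      gvec[start[i] + 0:2] <- cl
    } else {
      gvec[end[i] - 0:2] <- chartr("ACGTN", "TGCAN", cl)
    }
  }

  # planted TSSs: one per selected gene
  with_tss <- sort(sample(n, config$n_tss))
  u <- stats::runif(length(with_tss))
  utr <- integer(length(with_tss))
  lf <- config$leaderless_fraction
  llf <- config$long_leader_fraction
  for (j in seq_along(with_tss)) {
    if (u[j] < lf) {
      utr[j] <- sample(0:8, 1L)
    } else if (u[j] < lf + llf) {
      utr[j] <- sample(151:250, 1L)
    } else {
      utr[j] <- min(150L, max(9L, round(stats::rlnorm(1L, log(44), 0.55))))
    }
  }
  gi <- with_tss
  tss_pos <- ifelse(strand[gi] == "+", start[gi] - utr, end[gi] + utr)

  purine <- stats::runif(length(gi)) < config$tss_purine_fraction
  plus1 <- ifelse(purine, sample(c("A", "G"), length(gi), replace = TRUE),
                  sample(c("C", "T"), length(gi), replace = TRUE))
  for (j in seq_along(gi)) {
    gvec <- plant_oriented(gvec, tss_pos[j], strand[gi[j]], 0L, plus1[j])
    if (config$plant_promoters) {
      ns <- function(k) sample(names(base_p), k, replace = TRUE, prob = base_p)
      m10 <- c("T", "A", ns(3L), "T")
      m35 <- c(ns(1L), "T", "G", "A", "C", "C")
      sp <- sample(config$spacer_range, 1L)
      gvec <- plant_oriented(gvec, tss_pos[j], strand[gi[j]], -12L, m10)
      gvec <- plant_oriented(gvec, tss_pos[j], strand[gi[j]], -18L - sp, m35)
    }
  }

  truth <- list(
    tss_truth = data.frame(
      position = as.integer(tss_pos),
      strand = strand[gi],
      gene_id = genes$gene_id[gi],
      utr = utr,
      is_leaderless = utr < 9L,
      stringsAsFactors = FALSE
    ),
    stoichiometry_truth = genes[!is.na(genes$operon_id),
                                c("gene_id", "operon_id", "stoichiometry")],
    config = config
  )
  list(genome = genome_seq("synthetic_chr", paste(gvec, collapse = "")),
       genes = genes, truth = truth)
}

#' Simulate TEX+/TEX- 5'-end profiles
#'
#' Each planted TSS receives a TEX+ peak of NB-distributed height (forced
#' >= 3 reads, satisfying the caller's count filter) and a TEX- peak of
#' `tex_minus_retention` times that height placed within +/-2 bp.
#' RNA-processing sites (Poisson per kb) receive TEX--only peaks, and a
#' uniform Poisson background of single reads is added to both libraries.
#'
#' @param genome A [genome_seq()] (used for its length).
#' @param genes Gene table (unused; kept for interface symmetry).
#' @param truth Truth list from [simulate_genome_annotation()].
#' @param config A [sim_config()].
#' @return List `tex_plus`, `tex_minus`; each a named list of profiles
#'   by strand (`"+"`, `"-"`).
#' @export
simulate_5prime_profiles <- function(genome, genes, truth, config) {
  set.seed(config$seed + 1L)
  L <- length(genome)
  tt <- truth$tss_truth
  out <- list(tex_plus = list(), tex_minus = list())
  for (s in c("+", "-")) {
    sel <- tt$strand == s
    pos <- tt$position[sel]
    h <- pmax(stats::rnbinom(sum(sel), mu = config$tss_height_mean,
                             size = config$peak_nb_size), 3L)
    # TEX-: retained primary 5' ends, jittered within +/-2 bp
    hm <- round(h * config$tex_minus_retention)
    jit <- sample(-2:2, sum(sel), replace = TRUE)
    mpos <- pmin(pmax(pos + jit, 1L), L)
    keepm <- hm > 0L
    # processing sites: TEX- only
    npr <- stats::rpois(1L, config$processing_site_rate * L / 1000)
    prp <- if (npr > 0L) sample.int(L, npr, replace = TRUE) else integer(0)
    prh <- if (npr > 0L) pmax(stats::rnbinom(npr, mu = config$tss_height_mean,
                                             size = config$peak_nb_size), 1L) else integer(0)
    # uniform background of single reads, independent per library
    nbg_p <- stats::rpois(1L, config$background_rate * L / 1000)
    nbg_m <- stats::rpois(1L, config$background_rate * L / 1000)
    bg_p <- if (nbg_p > 0L) sample.int(L, nbg_p, replace = TRUE) else integer(0)
    bg_m <- if (nbg_m > 0L) sample.int(L, nbg_m, replace = TRUE) else integer(0)

    out$tex_plus[[s]] <- five_prime_profile(
      c(pos, bg_p), c(h, rep(1L, length(bg_p))), s, "TEX_plus")
    out$tex_minus[[s]] <- five_prime_profile(
      c(mpos[keepm], prp, bg_m),
      c(hm[keepm], prh, rep(1L, length(bg_m))), s, "TEX_minus")
  }
  out
}

#' Simulate mRNA and RPF count matrices with planted truth
#'
#' Per-gene baseline abundances are log-normal around `mrna_mean`
#' (operon transcripts around `operon_mean`, shared within an operon);
#' per-phase mRNA log2 fold-changes are Normal(0, `phase_foldchange_sd`)
#' (plus a planted rising trend for secondary metabolic genes and a fixed
#' `diff_log2fc` at phases T and L for `n_diff_genes` genes); RPF log2
#' fold-changes are `(1 + buffering_slope)` times the mRNA fold-changes
#' plus Normal(0, `rpf_extra_sd`) noise. Within operons mRNA abundances
#' are equal while RPF abundances are proportional to subunit
#' stoichiometry. Counts are NB with the configured dispersion; expected
#' counts scale with gene length (per kb) and a per-library depth factor.
#'
#' @param genes Gene table.
#' @param truth Truth list (updated copy is returned).
#' @param config A [sim_config()].
#' @return List with `mrna`, `rpf` (integer matrices), `phase` (per
#'   sample), and `truth` extended with `mrna_log2fc`, `rpf_log2fc`,
#'   `diff_genes`, `depth_mrna`, `depth_rpf`.
#' @export
simulate_count_matrices <- function(genes, truth, config) {
  set.seed(config$seed + 2L)
  n <- nrow(genes)
  phases <- c("M", "T", "L", "S")
  reps <- config$n_reps
  samples <- paste(rep(phases, each = reps), seq_len(reps), sep = "_")
  phase <- rep(phases, each = reps)
  len_kb <- (genes$end - genes$start + 1) / 1e3

  base_m <- stats::rnorm(n, log2(config$mrna_mean), 1)
  te_dev <- stats::rnorm(n, 0, 0.5)
  base_r <- base_m + te_dev
  sec <- genes$category == "secondary_metabolic"
  base_m[sec] <- base_m[sec] - 1.5
  base_r[sec] <- base_r[sec] - 1.5

  # operon transcripts: shared mRNA baseline; RPF proportional to stoichiometry
  for (op in unique(stats::na.omit(genes$operon_id))) {
    idx <- which(genes$operon_id == op)
    base_m[idx] <- log2(config$operon_mean)
    base_r[idx] <- log2(config$operon_mean) + log2(genes$stoichiometry[idx])
  }

  delta_m <- matrix(stats::rnorm(n * 3L, 0, config$phase_foldchange_sd),
                    n, 3L, dimnames = list(genes$gene_id, c("T", "L", "S")))
  delta_m[sec, ] <- sweep(delta_m[sec, , drop = FALSE], 2L,
                          c(1.5, 2.5, 3.5), "+")
  diff_genes <- character(0)
  if (config$n_diff_genes > 0L) {
    pool <- which(is.na(genes$operon_id) & !sec)
    di <- sample(pool, min(config$n_diff_genes, length(pool)))
    delta_m[di, c("T", "L")] <- delta_m[di, c("T", "L")] + config$diff_log2fc
    diff_genes <- genes$gene_id[di]
  }
  # operon members share the transcript-level fold-changes
  for (op in unique(stats::na.omit(genes$operon_id))) {
    idx <- which(genes$operon_id == op)
    delta_m[idx, ] <- rep(delta_m[idx[1L], ], each = length(idx))
  }
  delta_r <- (1 + config$buffering_slope) * delta_m +
    matrix(stats::rnorm(n * 3L, 0, config$rpf_extra_sd), n, 3L)
  dimnames(delta_r) <- dimnames(delta_m)
  # translational noise acts on the shared transcript: operon members keep
  # identical RPF fold-changes so the planted stoichiometric ratios hold
  for (op in unique(stats::na.omit(genes$operon_id))) {
    idx <- which(genes$operon_id == op)
    delta_r[idx, ] <- rep(delta_r[idx[1L], ], each = length(idx))
  }

  depth_m <- stats::rlnorm(length(samples), 0, 0.15)
  depth_r <- stats::rlnorm(length(samples), 0, 0.15)
  names(depth_m) <- names(depth_r) <- samples

  expected_mu <- function(base, delta, depth) {
    mu <- matrix(0, n, length(samples), dimnames = list(genes$gene_id, samples))
    for (j in seq_along(samples)) {
      d <- if (phase[j] == "M") 0 else delta[, phase[j]]
      mu[, j] <- 2^(base + d) * len_kb * depth[j]
    }
    mu
  }
  draw <- function(mu) {
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$nb_dispersion),
                  n, length(samples), dimnames = dimnames(mu))
    storage.mode(cnt) <- "integer"
    cnt
  }
  mu_m <- expected_mu(base_m, delta_m, depth_m)
  mu_r <- expected_mu(base_r, delta_r, depth_r)
  mrna <- draw(mu_m)
  rpf <- draw(mu_r)

  truth$mrna_log2fc <- delta_m
  truth$rpf_log2fc <- delta_r
  truth$buffering_slope <- config$buffering_slope
  truth$diff_genes <- diff_genes
  truth$depth_mrna <- depth_m
  truth$depth_rpf <- depth_r
  truth$mu_mrna <- mu_m
  truth$mu_rpf <- mu_r
  list(mrna = mrna, rpf = rpf, phase = phase, truth = truth)
}

#' Simulate a full synthetic data set
#'
#' Convenience wrapper chaining [simulate_genome_annotation()],
#' [simulate_5prime_profiles()] and [simulate_count_matrices()].
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `genes`, `profiles`, `mrna`, `rpf`,
#'   `phase`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ga <- simulate_genome_annotation(config)
  prof <- simulate_5prime_profiles(ga$genome, ga$genes, ga$truth, config)
  cm <- simulate_count_matrices(ga$genes, ga$truth, config)
  list(genome = ga$genome, genes = ga$genes, profiles = prof,
       mrna = cm$mrna, rpf = cm$rpf, phase = cm$phase, truth = cm$truth)
}

#' Write a simulated data set to standard files
#'
#' Emits exactly the formats the readers consume: FASTA genome, GFF3
#' annotation, four bedGraph profiles (library x strand), two TSV count
#' matrices, a TSV TSS truth table and a flat key=value config file.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  paths <- list(
    fasta = p("genome.fa"), gff = p("genes.gff3"),
    tex_plus_fwd = p("tex_plus_fwd.bedgraph"),
    tex_plus_rev = p("tex_plus_rev.bedgraph"),
    tex_minus_fwd = p("tex_minus_fwd.bedgraph"),
    tex_minus_rev = p("tex_minus_rev.bedgraph"),
    mrna = p("mrna_counts.tsv"), rpf = p("rpf_counts.tsv"),
    tss_truth = p("tss_truth.tsv"), config = p("config.txt")
  )
  write_fasta(sim$genome, paths$fasta)
  write_gff(sim$genes, paths$gff, seqname = sim$genome$name)
  write_bedgraph(sim$profiles$tex_plus[["+"]], paths$tex_plus_fwd, sim$genome$name)
  write_bedgraph(sim$profiles$tex_plus[["-"]], paths$tex_plus_rev, sim$genome$name)
  write_bedgraph(sim$profiles$tex_minus[["+"]], paths$tex_minus_fwd, sim$genome$name)
  write_bedgraph(sim$profiles$tex_minus[["-"]], paths$tex_minus_rev, sim$genome$name)
  write_counts(sim$mrna, paths$mrna)
  write_counts(sim$rpf, paths$rpf)
  utils::write.table(sim$truth$tss_truth, paths$tss_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$truth$config
  keys <- setdiff(names(cfg), "spacer_range")
  writeLines(c(paste0(keys, "=", vapply(cfg[keys], function(x)
    paste(x, collapse = ","), character(1))),
    paste0("spacer_range=", paste(cfg$spacer_range, collapse = ","))),
    paths$config)
  invisible(paths)
}
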