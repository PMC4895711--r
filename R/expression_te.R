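# Normalization of count matrices (median-of-ratios size factors),
# expressed-gene cutoff, differential-expression flags (two-sample
# negative-binomial test with pooled method-of-moments dispersion) and
# translation efficiency.

#' Median-of-ratios size factors
#'
#' Per-sample size factor: the median across genes (with all-positive
#' counts) of the ratio of the gene's count to its geometric mean across
#' samples. This is the classical RNA-seq median-of-ratios estimator.
#'
#' @param mat Gene-by-sample count matrix (>= 2 samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(mat) {
  if (ncol(mat) < 2L) stop("size factors need at least two samples")
  logs <- log(mat)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use)) stop("no gene with nonzero counts in all samples")
  sf <- apply(logs, 2L, function(lc) exp(stats::median((lc - loggeo)[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Normalize a count matrix by size factors
#'
#' @param mat Gene-by-sample count matrix.
#' @param sf Size factors, one per sample.
#' @return Matrix of normalized (real-valued) counts.
#' @export
normalize_counts <- function(mat, sf = size_factors(mat)) {
  if (length(sf) != ncol(mat)) stop("one size factor per sample required")
  if (any(!is.finite(sf) | sf <= 0)) stop("size factors must be positive and finite")
  sweep(mat, 2L, sf, "/")
}

#' Reads per kilobase per million mapped reads
#'
#' @param counts Count vector or gene-by-sample matrix.
#' @param gene_length Gene length(s) in bp (> 0).
#' @param library_size Library size(s) in reads; defaults to column sums.
#' @return RPKM values with the shape of `counts`.
#' @export
rpkm <- function(counts, gene_length, library_size = NULL) {
  if (any(gene_length <= 0)) stop("gene lengths must be positive")
  if (is.matrix(counts)) {
    if (is.null(library_size)) library_size <- colSums(counts)
    if (any(library_size <= 0)) stop("library sizes must be positive")
    sweep(counts / (gene_length / 1e3), 2L, library_size / 1e6, "/")
  } else {
    if (is.null(library_size)) stop("library_size required for a count vector")
    counts / (gene_length / 1e3) / (library_size / 1e6)
  }
}

#' Collapse replicate samples to per-phase values
#'
#' Replicate columns of a normalized matrix are merged by their mean, one
#' column per growth phase.
#'
#' @param norm_mat Normalized gene-by-sample matrix.
#' @param phase Character vector mapping each sample to its phase.
#' @param phases Phase order of the output (default: order of appearance).
#' @return Gene-by-phase matrix.
#' @export
collapse_replicates <- function(norm_mat, phase, phases = unique(phase)) {
  stopifnot(length(phase) == ncol(norm_mat))
  out <- sapply(phases, function(p) {
    rowMeans(norm_mat[, phase == p, drop = FALSE])
  })
  colnames(out) <- phases
  out
}

#' Expressed-gene cutoff from a reference gene set
#'
#' The cutoff is the median normalized expression of the reference set
#' (the secondary metabolic genes, assumed minimal at the reference
#' phase); a gene counts as expressed iff its normalized value strictly
#' exceeds the cutoff at one or more phases.
#'
#' @param phase_mat Normalized gene-by-phase matrix.
#' @param reference_genes Gene IDs of the reference set (rownames of
#'   `phase_mat`).
#' @param reference_phase Column used to compute the cutoff (default the
#'   first, mid-exponential).
#' @return List with `cutoff` and logical `expressed` per gene.
#' @export
expressed_cutoff <- function(phase_mat, reference_genes,
                             reference_phase = colnames(phase_mat)[1L]) {
  ref <- intersect(reference_genes, rownames(phase_mat))
  if (length(ref) == 0L) stop("empty reference gene set")
  cutoff <- stats::median(phase_mat[ref, reference_phase])
  expressed <- apply(phase_mat > cutoff, 1L, any)
  list(cutoff = cutoff, expressed = expressed)
}

#' Pooled method-of-moments NB dispersion
#'
#' Dispersion `d` in `Var = mu + d * mu^2`, pooled across genes and
#' phases from within-phase replicate variability of normalized counts:
#' `d = sum(v - m) / sum(m^2)` over gene-phase cells with positive mean.
#'
#' @param mat Raw count matrix.
#' @param phase Phase label per sample.
#' @param sf Size factors (computed if omitted).
#' @return Non-negative dispersion estimate.
#' @export
pooled_dispersion <- function(mat, phase, sf = size_factors(mat)) {
  norm <- normalize_counts(mat, sf)
  num <- 0
  den <- 0
  for (p in unique(phase)) {
    cols <- which(phase == p)
    if (length(cols) < 2L) next
    sub <- norm[, cols, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    ok <- m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den == 0) stop("dispersion needs replicated phases")
  max(num / den, 1e-8)
}

#' Differential-expression flags across phase contrasts
#'
#' Per contrast, the log2 fold-change of normalized phase means and a
#' two-sided p-value from a two-sample negative-binomial test (normal
#' approximation on the log scale with pooled method-of-moments
#' dispersion). A gene is flagged differential iff |FC| >= `fc_threshold`
#' and p < `alpha` in at least `min_contrasts` contrasts. Genes that are
#' not expressed, or in `exclude` (e.g. the duplicated terminal genes of
#' the chromosome), get `NA` flags.
#'
#' @param mat Raw count matrix.
#' @param phase Phase label per sample.
#' @param contrasts List of 2-vectors of phase labels; default all pairs.
#' @param sf Size factors (computed if omitted).
#' @param dispersion NB dispersion (pooled MoM estimate if omitted).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param min_contrasts Number of qualifying contrasts required (default 2).
#' @param expressed Optional logical per gene.
#' @param exclude Optional gene IDs to exclude.
#' @return List with `log2fc` and `p` (gene x contrast matrices),
#'   `differential` (logical per gene, NA where excluded), `dispersion`,
#'   `contrasts`.
#' @export
differential_flags <- function(mat, phase, contrasts = NULL,
                               sf = size_factors(mat), dispersion = NULL,
                               fc_threshold = 2, alpha = 0.05,
                               min_contrasts = 2, expressed = NULL,
                               exclude = NULL) {
  phases <- unique(phase)
  if (is.null(contrasts)) {
    contrasts <- utils::combn(phases, 2L, simplify = FALSE)
  }
  if (length(contrasts) < 2L) stop("need at least two contrasts")
  if (is.null(dispersion)) dispersion <- pooled_dispersion(mat, phase, sf)
  norm <- normalize_counts(mat, sf)
  cn <- vapply(contrasts, function(ct) paste(ct, collapse = ":"), character(1))
  lfc <- p <- matrix(NA_real_, nrow(mat), length(contrasts),
                     dimnames = list(rownames(mat), cn))
  for (j in seq_along(contrasts)) {
    a <- contrasts[[j]][1L]; b <- contrasts[[j]][2L]
    ca <- which(phase == a); cb <- which(phase == b)
    m1 <- rowMeans(norm[, ca, drop = FALSE])
    m2 <- rowMeans(norm[, cb, drop = FALSE])
    lfc[, j] <- log2((m2 + 0.5 * (m2 == 0)) / (m1 + 0.5 * (m1 == 0)))
    ok <- m1 > 0 & m2 > 0
    se2 <- (1 / m1 + dispersion) / length(ca) + (1 / m2 + dispersion) / length(cb)
    z <- log(m2 / m1) / sqrt(se2)
    p[, j] <- ifelse(ok, 2 * stats::pnorm(-abs(z)), 1)
  }
  hits <- abs(lfc) >= log2(fc_threshold) & p < alpha
  differential <- rowSums(hits, na.rm = TRUE) >= min_contrasts
  if (!is.null(expressed)) differential[!expressed] <- NA
  if (!is.null(exclude)) differential[rownames(mat) %in% exclude] <- NA
  list(log2fc = lfc, p = p, differential = differential,
       dispersion = dispersion, contrasts = cn)
}

#' IDs of the first and last n annotated genes
#'
#' The terminal genes of the chromosome (sequence duplications at the
#' chromosome ends) are excluded from all expression analyses.
#'
#' @param genes Gene table.
#' @param n Number of genes to drop from each end (default 20).
#' @return Character vector of gene IDs.
#' @export
terminal_gene_ids <- function(genes, n = 20) {
  ord <- order(genes$start)
  n <- min(n, floor(nrow(genes) / 2))
  if (n == 0L) return(character(0))
  genes$gene_id[c(utils::head(ord, n), utils::tail(ord, n))]
}

#' Translation efficiency per gene and phase
#'
#' TE = (RPF + 1) / (mRNA + 1) on normalized per-phase values; the
#' pseudocount (default 1) avoids zero denominators and is applied here
#' only, not in differential testing.
#'
#' @param rpf_phase Normalized RPF gene-by-phase matrix.
#' @param mrna_phase Matching normalized mRNA matrix.
#' @param pseudocount Pseudocount added to both (default 1).
#' @return List with `te` (positive matrix) and `log2_te`.
#' @export
translation_efficiency <- function(rpf_phase, mrna_phase, pseudocount = 1) {
  if (!identical(dim(rpf_phase), dim(mrna_phase))) {
    stop("RPF and mRNA matrices must have identical shape")
  }
  if (!identical(rownames(rpf_phase), rownames(mrna_phase))) {
    stop("RPF and mRNA matrices must have matched genes")
  }
  te <- (rpf_phase + pseudocount) / (mrna_phase + pseudocount)
  list(te = te, log2_te = log2(te))
}

#' Log2 changes between two phases
#'
#' Convenience for fold-changes of normalized values or TE between a
#' reference phase and a later phase: `log2((x_b+pc)/(x_a+pc))`.
#'
#' @param phase_mat Gene-by-phase matrix.
#' @param from,to Phase (column) labels.
#' @param pseudocount Pseudocount (default 1).
#' @return Named numeric vector per gene.
#' @export
phase_log2fc <- function(phase_mat, from, to, pseudocount = 1) {
  log2((phase_mat[, to] + pseudocount) / (phase_mat[, from] + pseudocount))
}
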