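# Translational buffering: regression of TE changes on mRNA changes,
# hierarchical clustering of expression patterns (manhattan/complete
# heatmap order and the 16 x 16 -> 256 combinatorial Pearson groups),
# monotone trend labels (II/ID/DI/DD) and subunit-stoichiometry checks.

#' Correlation between mRNA changes and TE changes
#'
#' Pearson r and least-squares slope of the per-gene change in log TE on
#' the change in log mRNA, overall and (optionally) per gene category.
#' A slope of 0 means translation follows transcription; negative slopes
#' indicate translational buffering (ribosome occupancy changes are
#' damped relative to mRNA changes).
#'
#' @param delta_log_mrna Per-gene change in log2 mRNA.
#' @param delta_log_te Matching change in log2 TE.
#' @param category Optional per-gene category labels.
#' @return List with `overall` (`r`, `slope`, `n`) and, when categories
#'   are given, `by_category` (one entry per category with >= 3 genes).
#' @export
buffering_correlation <- function(delta_log_mrna, delta_log_te,
                                  category = NULL) {
  stopifnot(length(delta_log_mrna) == length(delta_log_te))
  fit <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("buffering correlation needs >= 3 genes")
    list(r = stats::cor(x, y),
         slope = stats::cov(x, y) / stats::var(x),
         n = length(x))
  }
  out <- list(overall = fit(delta_log_mrna, delta_log_te))
  if (!is.null(category)) {
    stopifnot(length(category) == length(delta_log_mrna))
    by_cat <- list()
    for (ct in unique(category)) {
      idx <- which(category == ct)
      if (sum(is.finite(delta_log_mrna[idx]) & is.finite(delta_log_te[idx])) >= 3L) {
        by_cat[[ct]] <- fit(delta_log_mrna[idx], delta_log_te[idx])
      }
    }
    out$by_category <- by_cat
  }
  out
}

#' Hierarchical clustering of expression rows (heatmap order)
#'
#' Agglomerative clustering with the stated metric and linkage
#' (manhattan/complete by default); deterministic for a given input
#' order.
#'
#' @param mat Gene-by-sample numeric matrix (>= 2 rows).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Linkage for [stats::hclust()].
#' @param k Optional number of row clusters to cut.
#' @return List with `hclust`, `order`, and `clusters` (when `k` given).
#' @export
heatmap_cluster <- function(mat, metric = "manhattan", linkage = "complete",
                            k = NULL) {
  if (nrow(mat) < 2L) stop("clustering needs >= 2 rows")
  hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
  out <- list(hclust = hc, order = hc$order)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

pearson_groups <- function(phase_mat, k) {
  prof <- log2(phase_mat + 1)
  flat <- apply(prof, 1L, function(x) stats::sd(x) == 0)
  ids <- integer(nrow(prof))
  names(ids) <- rownames(prof)
  k_eff <- if (any(flat)) k - 1L else k
  if (sum(!flat) < k_eff) stop("fewer variable genes than requested groups")
  d <- stats::as.dist(1 - stats::cor(t(prof[!flat, , drop = FALSE])))
  hc <- stats::hclust(d, method = "complete")
  ids[!flat] <- stats::cutree(hc, k = k_eff)
  ids[flat] <- k  # constant profiles form their own "flat" group
  ids
}

#' Combinatorial mRNA x RPF expression pattern groups
#'
#' Genes are divided into `k` groups by hierarchical clustering of their
#' per-gene phase profiles (log2(normalized+1)) under correlation
#' distance (1 - Pearson r) with complete linkage, independently for the
#' mRNA and RPF modalities; the tree is cut at exactly `k` groups and
#' each gene receives a combinatorial (mRNA group, RPF group) id from the
#' k x k grid (256 cells at the default k = 16). Genes with constant
#' profiles (undefined correlation) form their own group.
#'
#' @param mrna_phase Normalized mRNA gene-by-phase matrix.
#' @param rpf_phase Matching RPF matrix.
#' @param k Number of groups per modality (default 16).
#' @return Data frame with `gene_id`, `mrna_group`, `rpf_group`,
#'   `combo`; attribute `grid_size` = k^2.
#' @export
pattern_groups <- function(mrna_phase, rpf_phase, k = 16) {
  stopifnot(identical(rownames(mrna_phase), rownames(rpf_phase)))
  if (nrow(mrna_phase) < k) stop("need at least k genes")
  mg <- pearson_groups(mrna_phase, k)
  rg <- pearson_groups(rpf_phase, k)
  out <- data.frame(gene_id = rownames(mrna_phase),
                    mrna_group = as.integer(mg),
                    rpf_group = as.integer(rg),
                    combo = sprintf("m%02d_r%02d", mg, rg),
                    stringsAsFactors = FALSE)
  attr(out, "grid_size") <- as.integer(k)^2
  out
}

#' Monotone trend label of a phase profile
#'
#' Least-squares slope of the (log2) profile over the phase index:
#' increasing (`I`) above `+threshold`, decreasing (`D`) below
#' `-threshold`, otherwise `flat`. The default threshold is the slope
#' whose fitted end-to-end change across the phases is 1 on the log2
#' scale (i.e. `1/(phases-1)`).
#'
#' @param phase_mat Gene-by-phase matrix of log2 values (>= 3 phases).
#' @param threshold Slope threshold; default `1/(ncol-1)`.
#' @return Character vector of labels per gene.
#' @export
trend_labels <- function(phase_mat, threshold = NULL) {
  P <- ncol(phase_mat)
  if (P < 3L) stop("trend labels need >= 3 phases")
  if (is.null(threshold)) threshold <- 1 / (P - 1)
  x <- seq_len(P)
  xc <- x - mean(x)
  slope <- as.numeric(phase_mat %*% xc) / sum(xc^2)
  ifelse(slope > threshold, "I", ifelse(slope < -threshold, "D", "flat"))
}

#' Combined mRNA/RPF trend groups (II, ID, DI, DD, ...)
#'
#' @param mrna_phase,rpf_phase Normalized gene-by-phase matrices.
#' @param threshold Slope threshold passed to [trend_labels()].
#' @return Data frame with per-modality labels and the combined group.
#' @export
trend_groups <- function(mrna_phase, rpf_phase, threshold = NULL) {
  stopifnot(identical(rownames(mrna_phase), rownames(rpf_phase)))
  m <- trend_labels(log2(mrna_phase + 1), threshold)
  r <- trend_labels(log2(rpf_phase + 1), threshold)
  data.frame(gene_id = rownames(mrna_phase),
             mrna_trend = m, rpf_trend = r,
             group = paste0(ifelse(m == "flat", "F", m),
                            ifelse(r == "flat", "F", r)),
             stringsAsFactors = FALSE)
}

#' Subunit-stoichiometry proportionality of RPF levels
#'
#' Within each annotated operon, the length-normalized RPF signal of each
#' member (summed over samples, per kb) is divided by the first member's;
#' balanced translation predicts ratios equal to the annotated subunit
#' copy numbers even though the members share one transcript.
#'
#' @param rpf_norm Normalized RPF gene-by-sample matrix.
#' @param genes Gene table with `operon_id` and `stoichiometry` set for
#'   operon members.
#' @return Data frame with one row per operon member: observed and
#'   expected ratio and relative error.
#' @export
stoichiometry_check <- function(rpf_norm, genes) {
  ops <- genes[!is.na(genes$operon_id), , drop = FALSE]
  if (nrow(ops) == 0L) stop("no annotated operons")
  rows <- list()
  for (op in unique(ops$operon_id)) {
    mem <- ops[ops$operon_id == op, , drop = FALSE]
    mem <- mem[order(mem$start), , drop = FALSE]
    if (any(is.na(mem$stoichiometry))) stop("operon ", op, " lacks stoichiometry")
    val <- rowSums(rpf_norm[mem$gene_id, , drop = FALSE]) /
      ((mem$end - mem$start + 1) / 1e3)
    if (val[1L] == 0) stop("first member of operon ", op, " has zero RPF signal")
    obs <- val / val[1L]
    expd <- mem$stoichiometry / mem$stoichiometry[1L]
    rows[[op]] <- data.frame(operon_id = op, gene_id = mem$gene_id,
                             stoichiometry = mem$stoichiometry,
                             observed_ratio = as.numeric(obs),
                             expected_ratio = as.numeric(expd),
                             rel_error = abs(obs - expd) / expd,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
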