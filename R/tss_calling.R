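# TSS identification from TEX+ 5'-end profiles with TEX- validation.
#
# The caller reproduces the dRNA-seq clustering scheme: candidate 5'-end
# positions are chained into clusters (gap <= 100 bp), clusters are split
# into sub-clusters by a standard-deviation rule (sd of member positions
# < 10), low-count (sub-)clusters are dropped (total reads < 3), the
# maximum peak of each sub-cluster becomes a candidate TSS, closely spaced
# candidates within a cluster are pruned to the highest peak, and finally
# candidates without TEX- support within +/-5 bp are removed.

#' Sample standard deviation of genomic positions
#'
#' Uses the n-1 divisor; a single position has sd 0. This is the statistic
#' the sub-clustering and pruning rules threshold against.
#'
#' @param positions Numeric vector of genomic coordinates (length >= 1).
#' @return The sample standard deviation.
#' @export
position_sd <- function(positions) {
  if (length(positions) == 0L) stop("position_sd needs at least one position")
  if (length(positions) == 1L) return(0)
  stats::sd(positions)
}

new_peak_cluster <- function(positions, counts, strand) {
  list(positions = positions, counts = counts, strand = strand)
}

#' Partition a 5'-end profile into peak clusters
#'
#' Sorted nonzero positions are chained into one cluster while the gap to
#' the previous position is at most `cluster_gap` (default 100 bp). Every
#' position appears in exactly one cluster.
#'
#' @param profile A [five_prime_profile()] (TEX+).
#' @param cluster_gap Maximum chaining gap in bp.
#' @return List of peak clusters (`positions`, `counts`, `strand`).
#' @export
partition_candidates <- function(profile, cluster_gap = 100) {
  pos <- profile$positions
  cnt <- profile$counts
  if (length(pos) == 0L) return(list())
  brk <- c(0L, which(diff(pos) > cluster_gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    new_peak_cluster(pos[idx], cnt[idx], profile$strand)
  })
}

#' Sub-cluster a peak cluster by positional standard deviation
#'
#' Greedy left-to-right growth: the current sub-cluster is extended with
#' the next position while the sample sd of the extended set stays below
#' `sd_threshold`; otherwise a new sub-cluster is started. The partition
#' property is preserved.
#'
#' @param cluster A peak cluster.
#' @param sd_threshold Strict sd threshold (default 10).
#' @return List of sub-clusters.
#' @export
subcluster_by_sd <- function(cluster, sd_threshold = 10) {
  pos <- cluster$positions
  n <- length(pos)
  if (n == 0L) stop("empty cluster")
  start <- 1L
  out <- list()
  for (i in seq_len(n)[-1]) {
    if (!(position_sd(pos[start:i]) < sd_threshold)) {
      out[[length(out) + 1L]] <- new_peak_cluster(
        cluster$positions[start:(i - 1L)], cluster$counts[start:(i - 1L)],
        cluster$strand)
      start <- i
    }
  }
  out[[length(out) + 1L]] <- new_peak_cluster(
    cluster$positions[start:n], cluster$counts[start:n], cluster$strand)
  out
}

#' Remove clusters with too few total reads
#'
#' Applied after the 100-bp partition and again after sd sub-clustering.
#'
#' @param clusters List of (sub-)clusters.
#' @param min_total Minimum total read count to keep (default 3).
#' @return Filtered list.
#' @export
filter_min_reads <- function(clusters, min_total = 3) {
  Filter(function(cl) sum(cl$counts) >= min_total, clusters)
}

#' Select the maximum peak of each sub-cluster as a candidate TSS
#'
#' Ties at equal height are broken towards the 5'-most position relative
#' to the strand (smallest coordinate on `+`, largest on `-`).
#'
#' @param subclusters List of filtered sub-clusters.
#' @return Data frame with columns `position`, `strand`, `height`.
#' @export
select_subcluster_peaks <- function(subclusters) {
  if (length(subclusters) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      height = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(subclusters, function(cl) {
    h <- max(cl$counts)
    at <- cl$positions[cl$counts == h]
    p <- if (cl$strand == "+") min(at) else max(at)
    data.frame(position = p, strand = cl$strand, height = h,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prune closely located candidate TSSs within one cluster
#'
#' Candidates are grouped left to right while the sd of the group's
#' positions stays below `sd_threshold`; within each group only the
#' highest peak is retained (height tie broken towards the 5'-most
#' position).
#'
#' @param candidates Data frame (`position`, `strand`, `height`) sorted by
#'   position, all from one cluster.
#' @param sd_threshold Strict sd threshold (default 10).
#' @return Pruned data frame.
#' @export
prune_close_tss <- function(candidates, sd_threshold = 10) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  candidates <- candidates[order(candidates$position), , drop = FALSE]
  pos <- candidates$position
  group <- integer(n)
  g <- 1L
  start <- 1L
  group[1L] <- 1L
  for (i in 2:n) {
    if (!(position_sd(pos[start:i]) < sd_threshold)) {
      g <- g + 1L
      start <- i
    }
    group[i] <- g
  }
  keep <- unlist(lapply(split(seq_len(n), group), function(idx) {
    h <- candidates$height[idx]
    best <- idx[h == max(h)]
    if (candidates$strand[idx[1L]] == "+") best[1L] else best[length(best)]
  }), use.names = FALSE)
  candidates[sort(keep), , drop = FALSE]
}

#' Validate candidate TSSs against the TEX- control library
#'
#' A candidate is kept iff the TEX- profile has any read within
#' `window` bp (default +/-5) of its position; real primary 5' ends are
#' present in both libraries, whereas spurious TEX+ peaks are not.
#'
#' @param candidates Data frame (`position`, `strand`, `height`).
#' @param tex_minus TEX- [five_prime_profile()] on the same strand.
#' @param window Search half-window in bp.
#' @return Data frame of kept candidates with a `validated` column.
#' @export
validate_against_control <- function(candidates, tex_minus, window = 5) {
  if (nrow(candidates) == 0L) {
    candidates$validated <- logical(0)
    return(candidates)
  }
  mp <- tex_minus$positions
  ok <- vapply(candidates$position, function(p) {
    length(mp) > 0L && any(mp >= p - window & mp <= p + window)
  }, logical(1))
  out <- candidates[ok, , drop = FALSE]
  out$validated <- rep(TRUE, nrow(out))
  out
}

call_tss_one_strand <- function(tex_plus, tex_minus, min_reads, cluster_gap,
                                sd_threshold, control_window) {
  clusters <- partition_candidates(tex_plus, cluster_gap = cluster_gap)
  clusters <- filter_min_reads(clusters, min_total = min_reads)
  per_cluster <- lapply(clusters, function(cl) {
    sub <- subcluster_by_sd(cl, sd_threshold = sd_threshold)
    sub <- filter_min_reads(sub, min_total = min_reads)
    cand <- select_subcluster_peaks(sub)
    prune_close_tss(cand, sd_threshold = sd_threshold)
  })
  cand <- do.call(rbind, c(per_cluster, list(select_subcluster_peaks(list()))))
  validate_against_control(cand, tex_minus, window = control_window)
}

#' Call TSSs from paired TEX+/TEX- 5'-end profiles
#'
#' Runs the full composition per strand: 100-bp partition, read filter,
#' sd sub-clustering, read filter, peak selection, within-cluster pruning,
#' TEX- validation. Output is sorted by position.
#'
#' @param tex_plus Named list (`"+"`, `"-"`) of TEX+ profiles, or a single
#'   profile.
#' @param tex_minus Matching TEX- profiles.
#' @param min_reads Minimum total reads per (sub-)cluster (default 3).
#' @param cluster_gap Clustering gap in bp (default 100).
#' @param sd_threshold Sub-clustering/pruning sd threshold (default 10).
#' @param control_window TEX- validation half-window in bp (default 5).
#' @return Data frame with columns `position`, `strand`, `height`,
#'   `validated`.
#' @export
call_tss <- function(tex_plus, tex_minus, min_reads = 3, cluster_gap = 100,
                     sd_threshold = 10, control_window = 5) {
  if (inherits(tex_plus, "fiveprime_profile")) {
    tex_plus <- stats::setNames(list(tex_plus), tex_plus$strand)
  }
  if (inherits(tex_minus, "fiveprime_profile")) {
    tex_minus <- stats::setNames(list(tex_minus), tex_minus$strand)
  }
  out <- lapply(names(tex_plus), function(s) {
    ctrl <- tex_minus[[s]]
    if (is.null(ctrl)) {
      ctrl <- five_prime_profile(integer(0), integer(0), s, "TEX_minus")
    }
    call_tss_one_strand(tex_plus[[s]], ctrl, min_reads, cluster_gap,
                        sd_threshold, control_window)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      height = integer(0), validated = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
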