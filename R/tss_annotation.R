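# Classification of called TSSs against the gene annotation, 5'-UTR
# lengths, leader status, start-codon usage, TSS nucleotide context and
# sRNA candidate derivation.

start_codon_pos <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Classify TSSs relative to annotated genes
#'
#' For each gene, same-strand TSSs within a strand-oriented window from
#' `upstream` bp upstream to `downstream` bp downstream of the annotated
#' start codon are collected; the highest peak becomes the primary (P) TSS
#' (tie broken by distance to the start codon, then the 5'-most position)
#' and the rest are secondary (S). A TSS qualifying for several genes is
#' assigned to the gene with the nearest start codon. Remaining TSSs
#' inside an ORF on the same strand are internal (I), inside an ORF span
#' on the opposite strand antisense (A), and otherwise intergenic (N).
#' UTR length and leader status are filled for P/S records.
#'
#' @param candidates Data frame with `position`, `strand`, `height`.
#' @param genes Gene table (see [read_gff()]).
#' @param upstream,downstream Window extent around the start codon (bp).
#' @param leaderless_max Maximum 5'-UTR length of a leaderless mRNA (nt).
#' @param long_leader_min Minimum 5'-UTR length of a long leader (nt).
#' @return Data frame of TSS records with columns `position`, `strand`,
#'   `height`, `class_label`, `gene_id`, `utr_length`, `leader_status`.
#' @export
classify_tss <- function(candidates, genes, upstream = 500, downstream = 150,
                         leaderless_max = 8, long_leader_min = 151) {
  n <- nrow(candidates)
  rec <- data.frame(
    position = candidates$position,
    strand = candidates$strand,
    height = candidates$height,
    class_label = rep(NA_character_, n),
    gene_id = rep(NA_character_, n),
    utr_length = rep(NA_integer_, n),
    leader_status = rep("undefined", n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(rec)
  sc <- start_codon_pos(genes)

  # window membership and nearest-start-codon assignment
  assigned_gene <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- rec$position[i]
    same <- which(genes$strand == rec$strand[i])
    if (length(same) == 0L) next
    lo <- ifelse(genes$strand[same] == "+", sc[same] - upstream, sc[same] - downstream)
    hi <- ifelse(genes$strand[same] == "+", sc[same] + downstream, sc[same] + upstream)
    inwin <- same[p >= lo & p <= hi]
    if (length(inwin) > 0L) {
      d <- abs(p - sc[inwin])
      assigned_gene[i] <- inwin[order(d, genes$start[inwin])[1L]]
    }
  }

  # per-gene primary/secondary
  for (g in unique(assigned_gene[!is.na(assigned_gene)])) {
    idx <- which(assigned_gene == g)
    h <- rec$height[idx]
    best <- idx[h == max(h)]
    if (length(best) > 1L) {
      d <- abs(rec$position[best] - sc[g])
      best <- best[d == min(d)]
      if (length(best) > 1L) {
        best <- if (genes$strand[g] == "+") {
          best[which.min(rec$position[best])]
        } else best[which.max(rec$position[best])]
      }
    }
    best <- best[1L]
    rec$class_label[idx] <- "S"
    rec$class_label[best] <- "P"
    rec$gene_id[idx] <- genes$gene_id[g]
    for (i in idx) {
      u <- utr_length(rec$position[i], rec$strand[i],
                      genes$start[g], genes$end[g], genes$strand[g])
      rec$utr_length[i] <- u
      rec$leader_status[i] <- if (is.na(u)) "undefined" else {
        leader_status(u, leaderless_max = leaderless_max,
                      long_leader_min = long_leader_min)
      }
    }
  }

  # remaining: internal / antisense / intergenic
  left <- which(is.na(rec$class_label))
  for (i in left) {
    p <- rec$position[i]
    host <- genes$start <= p & genes$end >= p
    if (any(host & genes$strand == rec$strand[i])) {
      rec$class_label[i] <- "I"
      rec$gene_id[i] <- genes$gene_id[which(host & genes$strand == rec$strand[i])[1L]]
    } else if (any(host)) {
      rec$class_label[i] <- "A"
      rec$gene_id[i] <- genes$gene_id[which(host)[1L]]
    } else {
      rec$class_label[i] <- "N"
    }
  }
  rec
}

#' 5'-UTR length of a primary/secondary TSS
#'
#' Strand-oriented distance from the TSS to the first base of the start
#' codon: `start - position` on `+`, `position - end` on `-`. A negative
#' value (TSS downstream of the start codon, still within the
#' classification window) is undefined (`NA`) and excluded from UTR
#' statistics.
#'
#' @param position TSS position (1-based).
#' @param strand TSS strand.
#' @param gene_start,gene_end Gene coordinates (1-based inclusive).
#' @param gene_strand Gene strand.
#' @return UTR length in nt, or `NA_integer_`.
#' @export
utr_length <- function(position, strand, gene_start, gene_end, gene_strand) {
  if (strand != gene_strand) stop("TSS and gene must be on the same strand")
  u <- if (strand == "+") gene_start - position else position - gene_end
  if (u < 0) NA_integer_ else as.integer(u)
}

#' Leader status of a 5'-UTR
#'
#' UTRs shorter than 9 nt are leaderless (no ribosome-binding leader),
#' longer than 150 nt long leaders (candidate regulatory structures),
#' anything between is a conventional leadered mRNA.
#'
#' @param utr UTR length in nt (defined, non-negative).
#' @param leaderless_max Maximum leaderless UTR length (default 8).
#' @param long_leader_min Minimum long-leader UTR length (default 151).
#' @return `"leaderless"`, `"leadered"` or `"long_leader"`.
#' @export
leader_status <- function(utr, leaderless_max = 8, long_leader_min = 151) {
  if (length(utr) != 1L || is.na(utr)) stop("undefined UTR length")
  if (utr <= leaderless_max) "leaderless"
  else if (utr >= long_leader_min) "long_leader"
  else "leadered"
}

oriented_base <- function(genome, position, strand) {
  b <- substr(genome$seq, position, position)
  if (strand == "-") chartr("ACGTN", "TGCAN", b) else b
}

#' Start-codon usage over a gene set
#'
#' Reads the 3-mer at each annotated start codon (reverse-complemented on
#' `-`) and tabulates fractions over ATG/GTG/TTG/CTG/other. Genes whose
#' codon window falls outside the genome are skipped with a warning.
#'
#' @param genes Gene table.
#' @param genome A [genome_seq()].
#' @return Named numeric vector of fractions summing to 1.
#' @export
start_codon_usage <- function(genes, genome) {
  L <- length(genome)
  codons <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      from <- genes$start[i]; to <- genes$start[i] + 2L
      if (from < 1L || to > L) { skipped <- skipped + 1L; next }
      codons <- c(codons, substr(genome$seq, from, to))
    } else {
      from <- genes$end[i] - 2L; to <- genes$end[i]
      if (from < 1L || to > L) { skipped <- skipped + 1L; next }
      fwd <- substr(genome$seq, from, to)
      rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", fwd), "")[[1L]]),
                  collapse = "")
      codons <- c(codons, rc)
    }
  }
  if (skipped > 0L) warning(skipped, " gene(s) with codon window outside genome skipped")
  lv <- c("ATG", "GTG", "TTG", "CTG")
  lab <- ifelse(codons %in% lv, codons, "other")
  tab <- table(factor(lab, levels = c(lv, "other")))
  stats::setNames(as.numeric(tab) / length(codons), names(tab))
}

#' Nucleotide context around TSSs
#'
#' Per-offset nucleotide composition on the TSS strand at offsets -2..+2
#' (the TSS itself is +1) plus the purine (A+G) fraction at +1. TSSs with
#' context extending beyond the genome are skipped.
#'
#' @param records TSS data frame (`position`, `strand`).
#' @param genome A [genome_seq()].
#' @return List with `fractions` (5 x 4 matrix, offsets x ACGT) and
#'   `purine_fraction` at +1.
#' @export
tss_context <- function(records, genome) {
  L <- length(genome)
  offsets <- c(-2L, -1L, 0L, 1L, 2L)  # 0 is the TSS (+1 in promoter numbering)
  keep <- records$position - 2L >= 1L & records$position + 2L <= L
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) stop("no TSS with full -2..+2 context")
  bases <- matrix(NA_character_, nrow(records), length(offsets))
  for (i in seq_len(nrow(records))) {
    p <- records$position[i]
    s <- records$strand[i]
    for (j in seq_along(offsets)) {
      gp <- if (s == "+") p + offsets[j] else p - offsets[j]
      bases[i, j] <- oriented_base(genome, gp, s)
    }
  }
  fr <- t(apply(bases, 2L, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    as.numeric(tab) / sum(tab)
  }))
  rownames(fr) <- c("-2", "-1", "+1", "+2", "+3")
  colnames(fr) <- c("A", "C", "G", "T")
  list(fractions = fr, purine_fraction = fr["+1", "A"] + fr["+1", "G"])
}

#' Derive sRNA candidates from antisense/intergenic TSSs
#'
#' All antisense (A) and intergenic (N) TSSs are sRNA candidates; a
#' candidate is flagged as (potentially) coding when its ribosome
#' occupancy (RPF RPKM) reaches `occupancy_threshold` — by default the
#' expressed-gene cutoff.
#'
#' @param records Classified TSS data frame.
#' @param rpf_rpkm Numeric vector of per-record RPF RPKM values (aligned
#'   with `records` rows).
#' @param occupancy_threshold Occupancy threshold.
#' @return Data frame of candidates with a logical `coding_flag`.
#' @export
srna_candidates <- function(records, rpf_rpkm, occupancy_threshold) {
  stopifnot(length(rpf_rpkm) == nrow(records))
  sel <- records$class_label %in% c("A", "N")
  out <- records[sel, , drop = FALSE]
  out$rpf_rpkm <- rpf_rpkm[sel]
  out$coding_flag <- out$rpf_rpkm >= occupancy_threshold
  rownames(out) <- NULL
  out
}
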