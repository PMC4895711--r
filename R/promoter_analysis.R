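# Promoter-architecture analysis: strand-oriented promoter windows, IUPAC
# consensus scanning of the -10 (TANNNT) and -35 (NTGACC) hexamers, flanked
# motif extraction, -35/-10 spacer lengths, promoter G+C, and translation
# initiation region (TIR) composition profiles.

#' Strand-oriented subsequence around a TSS
#'
#' Returns the sequence at offsets `from_off..to_off` relative to the TSS
#' (offset 0 = the TSS base) read 5'->3' on the TSS strand; reverse
#' complemented on `-`.
#'
#' @param genome A [genome_seq()].
#' @param position TSS position (1-based).
#' @param strand TSS strand.
#' @param from_off,to_off Offsets relative to the TSS (`from_off <= to_off`).
#' @return Character scalar, or `NA` if outside the genome.
#' @export
oriented_subseq <- function(genome, position, strand, from_off, to_off) {
  stopifnot(from_off <= to_off)
  L <- length(genome)
  if (strand == "+") {
    a <- position + from_off; b <- position + to_off
    if (a < 1L || b > L) return(NA_character_)
    substr(genome$seq, a, b)
  } else {
    a <- position - to_off; b <- position - from_off
    if (a < 1L || b > L) return(NA_character_)
    s <- substr(genome$seq, a, b)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }
}

#' Extract the -10 and -35 promoter windows of a TSS
#'
#' The -10 window is the 20 nt immediately upstream of the TSS (offsets
#' -20..-1); the -35 window covers offsets -40..-25 (16 nt). Both are on
#' the TSS strand. TSSs closer than 40 bp to the genome edge are skipped
#' (`NA` windows) with a warning.
#'
#' @param record One-row TSS data frame or list with `position`, `strand`.
#' @param genome A [genome_seq()].
#' @return List with `tss_position`, `strand`, `minus10_window` (20 nt),
#'   `minus35_window` (16 nt).
#' @export
extract_windows <- function(record, genome) {
  m10 <- oriented_subseq(genome, record$position, record$strand, -20L, -1L)
  m35 <- oriented_subseq(genome, record$position, record$strand, -40L, -25L)
  if (is.na(m10) || is.na(m35)) {
    warning("TSS at ", record$position, " too close to genome edge; skipped")
  }
  list(tss_position = record$position, strand = record$strand,
       minus10_window = m10, minus35_window = m35)
}

#' Scan a promoter window for an IUPAC consensus hexamer
#'
#' All exact IUPAC matches are reported with their hexamer-start offset
#' relative to the TSS; if several match, the hit closest to the TSS
#' (largest offset) is marked primary.
#'
#' @param window Window sequence (TSS strand).
#' @param pattern 6-letter IUPAC pattern (e.g. `"TANNNT"`, `"NTGACC"`).
#' @param window_offset Offset of the window's first base relative to the
#'   TSS (-20 for the -10 window, -40 for the -35 window).
#' @return Data frame with columns `offset`, `hexamer`, `primary`
#'   (zero rows when nothing matches).
#' @export
scan_consensus <- function(window, pattern, window_offset = -20L) {
  stopifnot(nchar(pattern) == 6L)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(window),
                                   fixed = FALSE)
  st <- IRanges::start(hits)
  if (length(st) == 0L) {
    return(data.frame(offset = integer(0), hexamer = character(0),
                      primary = logical(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    offset = as.integer(window_offset + st - 1L),
    hexamer = substring(window, st, st + 5L),
    stringsAsFactors = FALSE
  )
  out$primary <- out$offset == max(out$offset)
  out
}

#' Extract a flanked motif sequence around a hexamer hit
#'
#' For the -10 motif the 21-bp context N8-hexamer-N7 is returned; for the
#' -35 motif the 16-bp context N4-hexamer-N6. Flanks falling outside the
#' genome give `NA` (record skipped).
#'
#' @param record TSS record (`position`, `strand`).
#' @param genome A [genome_seq()].
#' @param hit_offset Hexamer start offset relative to the TSS.
#' @param motif `"minus10"` or `"minus35"`.
#' @return Character scalar (21 or 16 nt) or `NA`.
#' @export
flanked_motif <- function(record, genome, hit_offset,
                          motif = c("minus10", "minus35")) {
  motif <- match.arg(motif)
  flank <- if (motif == "minus10") c(8L, 7L) else c(4L, 6L)
  oriented_subseq(genome, record$position, record$strand,
                  hit_offset - flank[1L], hit_offset + 5L + flank[2L])
}

#' Spacer length between the -35 and -10 hexamers
#'
#' Number of nucleotides strictly between the 3' end of the -35 hexamer
#' and the 5' end of the -10 hexamer.
#'
#' @param minus10_offset Start offset of the -10 hexamer (relative to TSS).
#' @param minus35_offset Start offset of the -35 hexamer.
#' @return Spacer length in nt (>= 0).
#' @export
spacer_length <- function(minus10_offset, minus35_offset) {
  sp <- minus10_offset - (minus35_offset + 5L) - 1L
  if (sp < 0L) stop("overlapping -10/-35 hexamers")
  as.integer(sp)
}

#' G+C content of a sequence
#'
#' `N` bases are excluded from the denominator.
#'
#' @param sequence DNA string.
#' @return Proportion of G+C.
#' @export
gc_content <- function(sequence) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  b <- strsplit(toupper(sequence), "")[[1L]]
  denom <- sum(b != "N")
  if (denom == 0L) stop("all-N sequence")
  sum(b %in% c("G", "C")) / denom
}

#' Promoter table for a set of classified TSSs
#'
#' Convenience wrapper: windows, consensus hits, flanked motifs and spacer
#' length per TSS. TSSs without both hexamers get `NA` spacers.
#'
#' @param records Classified TSS data frame.
#' @param genome A [genome_seq()].
#' @param minus10_pattern,minus35_pattern IUPAC hexamer patterns.
#' @return Data frame, one row per usable TSS, with hexamer sequences,
#'   offsets, spacer length and promoter (-40..-1) G+C content.
#' @export
promoter_table <- function(records, genome,
                           minus10_pattern = "TANNNT",
                           minus35_pattern = "NTGACC") {
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    win <- suppressWarnings(extract_windows(rec, genome))
    if (is.na(win$minus10_window) || is.na(win$minus35_window)) next
    h10 <- scan_consensus(win$minus10_window, minus10_pattern, -20L)
    h35 <- scan_consensus(win$minus35_window, minus35_pattern, -40L)
    o10 <- if (nrow(h10)) h10$offset[h10$primary][1L] else NA_integer_
    o35 <- if (nrow(h35)) h35$offset[h35$primary][1L] else NA_integer_
    sp <- if (!is.na(o10) && !is.na(o35) && o10 - (o35 + 5L) - 1L >= 0L) {
      spacer_length(o10, o35)
    } else NA_integer_
    prom <- oriented_subseq(genome, rec$position, rec$strand, -40L, -1L)
    rows[[i]] <- data.frame(
      position = rec$position, strand = rec$strand,
      minus10_offset = o10,
      minus10_hexamer = if (nrow(h10)) h10$hexamer[h10$primary][1L] else NA_character_,
      minus35_offset = o35,
      minus35_hexamer = if (nrow(h35)) h35$hexamer[h35$primary][1L] else NA_character_,
      spacer = sp,
      promoter_gc = gc_content(prom),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(position = integer(0), strand = character(0),
                      minus10_offset = integer(0), minus10_hexamer = character(0),
                      minus35_offset = integer(0), minus35_hexamer = character(0),
                      spacer = integer(0), promoter_gc = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Translation-initiation-region composition profiles by gene group
#'
#' For each gene group (e.g. top/bottom 20% by translation efficiency) the
#' 20-nt TIR upstream of the start codon is extracted (strand-oriented)
#' and summarized as: pooled G+C content, per-offset purine fraction over
#' offsets -20..-1, and the mean purine fraction over the ribosome-binding
#' region (-12..-8). Genes too close to the genome edge are skipped.
#'
#' @param gene_groups Named list of gene tables (subsets of the annotation).
#' @param genome A [genome_seq()].
#' @param window TIR width in nt (default 20).
#' @return Named list per group with `gc`, `purine_by_offset` (named
#'   numeric, offsets -window..-1), `rbs_purine_mean`, `n`.
#' @export
tir_profile <- function(gene_groups, genome, window = 20) {
  L <- length(genome)
  lapply(gene_groups, function(genes) {
    seqs <- character(0)
    for (i in seq_len(nrow(genes))) {
      if (genes$strand[i] == "+") {
        a <- genes$start[i] - window; b <- genes$start[i] - 1L
        if (a < 1L || b > L) next
        seqs <- c(seqs, substr(genome$seq, a, b))
      } else {
        a <- genes$end[i] + 1L; b <- genes$end[i] + window
        if (a < 1L || b > L) next
        fwd <- substr(genome$seq, a, b)
        seqs <- c(seqs, paste(rev(strsplit(chartr("ACGTN", "TGCAN", fwd),
                                           "")[[1L]]), collapse = ""))
      }
    }
    if (length(seqs) == 0L) {
      return(list(gc = NA_real_, purine_by_offset = NULL,
                  rbs_purine_mean = NA_real_, n = 0L))
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    offs <- seq(-window, -1L)
    purine <- colMeans(mat == "A" | mat == "G")
    names(purine) <- as.character(offs)
    rbs <- mean(purine[as.character(seq(-12L, -8L))])
    list(gc = gc_content(paste(seqs, collapse = "")),
         purine_by_offset = purine,
         rbs_purine_mean = rbs,
         n = length(seqs))
  })
}
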