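# Readers/writers for the standard file formats the pipeline consumes and
# emits: FASTA genome, GFF3 annotation, 4-column bedGraph 5'-end profiles,
# TSV count matrices, and the TSV/BED6 TSS tables. All internal coordinates
# are 1-based inclusive; BED/bedGraph conversion happens only at this
# boundary.

#' Genome sequence container
#'
#' A minimal single-chromosome genome: a name and an uppercase DNA string
#' over A/C/G/T/N. The organism modelled here has a single (linear)
#' chromosome, so multi-record FASTA input beyond the first record is
#' rejected with a warning.
#'
#' @param name Sequence name.
#' @param seq DNA string (character scalar).
#' @return An object of class `genome_seq` with fields `name` and `seq`.
#' @export
genome_seq <- function(name, seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("genome sequence must have length >= 1")
  if (grepl("[^ACGTN]", seq)) {
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  }
  structure(list(name = as.character(name), seq = seq), class = "genome_seq")
}

#' @export
length.genome_seq <- function(x) nchar(x$seq)

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp\n", x$name, length(x)))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Multi-line records are concatenated; only the first record is used (a
#' warning is raised if more are present).
#'
#' @param path Path to a FASTA file.
#' @return A [genome_seq()] object.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             " (", conditionMessage(e), ")")
  )
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  if (length(seqs) > 1L) {
    warning("multiple FASTA records in ", path, "; using the first only")
  }
  nm <- sub("\\s.*$", "", names(seqs)[1L])
  genome_seq(nm, as.character(seqs[[1L]]))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_seq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features. Coordinates are 1-based inclusive as in GFF3.
#' Optional attributes `category`, `operon_id` and `stoichiometry` are read
#' if present, defaulting to `"other"` / `NA` / `NA`.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `category`, `operon_id`, `stoichiometry`.
#' @export
read_gff <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("not a readable GFF3 file: ", path,
                             " (", conditionMessage(e), ")")
  )
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", path)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids))) stop("gene feature without ID attribute in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) stop("gene feature with undefined strand in ", path)
  mc <- S4Vectors::mcols(gr)
  grab <- function(col, default) {
    if (col %in% colnames(mc)) {
      v <- as.character(mc[[col]])
      v[is.na(v) | !nzchar(v)] <- default
      v
    } else rep(default, length(gr))
  }
  genes <- data.frame(
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    category = grab("category", "other"),
    operon_id = grab("operon_id", NA_character_),
    stoichiometry = suppressWarnings(as.integer(grab("stoichiometry", NA_character_))),
    stringsAsFactors = FALSE
  )
  if (any(genes$end < genes$start)) stop("gene feature with end < start in ", path)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene IDs in ", path)
  genes[order(genes$start), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' @param genes Gene data frame as returned by [read_gff()].
#' @param path Output path.
#' @param seqname Chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "txlandscape"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$category <- genes$category
  gr$operon_id <- genes$operon_id
  gr$stoichiometry <- ifelse(is.na(genes$stoichiometry), NA_character_,
                             as.character(genes$stoichiometry))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' 5'-end read-count profile
#'
#' Sparse per-position 5'-end read counts for one library (TEX+ or TEX-) on
#' one strand. Positions are 1-based; only positions with count > 0 are
#' stored.
#'
#' @param positions Integer genomic positions (1-based).
#' @param counts Matching positive integer read counts.
#' @param strand `"+"` or `"-"`.
#' @param library `"TEX_plus"` or `"TEX_minus"`.
#' @return An object of class `fiveprime_profile`.
#' @export
five_prime_profile <- function(positions, counts,
                               strand = c("+", "-"),
                               library = c("TEX_plus", "TEX_minus")) {
  strand <- match.arg(strand)
  library <- match.arg(library)
  positions <- as.integer(positions)
  counts <- as.integer(counts)
  stopifnot(length(positions) == length(counts))
  if (any(counts < 0L)) stop("negative read counts")
  keep <- counts > 0L
  positions <- positions[keep]
  counts <- counts[keep]
  if (anyDuplicated(positions)) {
    agg <- rowsum(counts, positions)
    positions <- as.integer(rownames(agg))
    counts <- as.integer(agg[, 1L])
  }
  o <- order(positions)
  structure(list(library = library, strand = strand,
                 positions = positions[o], counts = counts[o]),
            class = "fiveprime_profile")
}

#' @export
print.fiveprime_profile <- function(x, ...) {
  cat(sprintf("<fiveprime_profile> %s strand %s: %d positions, %d reads\n",
              x$library, x$strand, length(x$positions), sum(x$counts)))
  invisible(x)
}

#' Read a 5'-end profile from bedGraph
#'
#' bedGraph intervals are 0-based half-open; each interval `[s, e)` with
#' value `v` contributes count `v` at 1-based positions `s+1 .. e`.
#' Overlapping intervals are summed.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param library `"TEX_plus"` or `"TEX_minus"`.
#' @param strand `"+"` or `"-"`.
#' @return A [five_prime_profile()].
#' @export
read_bedgraph <- function(path, library = c("TEX_plus", "TEX_minus"),
                          strand = c("+", "-")) {
  library <- match.arg(library)
  strand <- match.arg(strand)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("not a readable bedGraph file: ", path,
                             " (", conditionMessage(e), ")")
  )
  if (length(gr) == 0L) {
    return(five_prime_profile(integer(0), integer(0), strand, library))
  }
  score <- gr$score
  if (any(score < 0)) stop("negative values in bedGraph ", path)
  if (any(score != round(score))) stop("non-integer read counts in bedGraph ", path)
  # rtracklayer already converts to 1-based inclusive ranges
  s <- GenomicRanges::start(gr)
  w <- GenomicRanges::width(gr)
  pos <- unlist(lapply(seq_along(s), function(i) s[i] + seq_len(w[i]) - 1L),
                use.names = FALSE)
  cnt <- rep(as.integer(score), w)
  five_prime_profile(pos, cnt, strand, library)
}

#' Write a 5'-end profile to bedGraph
#'
#' @param profile A [five_prime_profile()].
#' @param path Output path.
#' @param seqname Chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, seqname = "chr") {
  if (length(profile$positions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = profile$positions, width = 1L),
    score = profile$counts
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a classified TSS table (TSV plus BED6 companion)
#'
#' Records are sorted by position then strand. A BED6 companion file
#' (`<path-without-ext>.bed`, 0-based half-open, name = class label,
#' score = peak height) is written next to the TSV.
#'
#' @param records Data frame with columns `position`, `strand`, `height`,
#'   `class_label`, `gene_id`, `utr_length`, `leader_status`.
#' @param path Output TSV path.
#' @param seqname Chromosome name used in the BED file.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(records, path, seqname = "chr") {
  cols <- c("position", "strand", "height", "class_label", "gene_id",
            "utr_length", "leader_status")
  out <- records[, cols, drop = FALSE]
  out <- out[order(out$position, out$strand), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_path <- paste0(tools::file_path_sans_ext(path), ".bed")
  if (nrow(out) > 0L) {
    bed <- data.frame(chrom = seqname,
                      start = out$position - 1L,
                      end = out$position,
                      name = out$class_label,
                      score = out$height,
                      strand = out$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    writeLines(character(0), bed_path)
  }
  invisible(path)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column must be `gene_id`; remaining columns are sample labels.
#' All cells must be non-negative integers with no missing values.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with gene IDs as rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene_id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene_id in ", path)
  vals <- df[, -1L, drop = FALSE]
  if (anyNA(vals)) stop("missing cells in count table ", path)
  m <- as.matrix(vals)
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0)) {
    stop("count table must contain non-negative integers: ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a gene-by-sample count matrix to TSV
#'
#' @param mat Matrix with gene IDs as rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
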