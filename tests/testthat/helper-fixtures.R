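# Small fixture builders shared across test files.

make_profile <- function(positions, counts, strand = "+",
                         library = "TEX_plus") {
  five_prime_profile(positions, counts, strand, library)
}

make_genes <- function(start, end, strand, gene_id = NULL,
                       category = "other") {
  n <- length(start)
  data.frame(
    gene_id = if (is.null(gene_id)) sprintf("g%02d", seq_len(n)) else gene_id,
    start = start, end = end, strand = strand,
    category = rep_len(category, n),
    operon_id = NA_character_, stoichiometry = NA_integer_,
    stringsAsFactors = FALSE
  )
}

make_candidates <- function(position, height, strand = "+") {
  data.frame(position = position,
             strand = rep_len(strand, length(position)),
             height = height, stringsAsFactors = FALSE)
}

# genome of given length from a fixed base, with planted motifs
make_genome <- function(length, fill = "C") {
  genome_seq("chr", strrep(fill, length))
}

plant_seq <- function(genome, at, seq) {
  s <- genome$seq
  substr(s, at, at + nchar(seq) - 1L) <- seq
  genome_seq(genome$name, s)
}

revcomp_str <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}
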