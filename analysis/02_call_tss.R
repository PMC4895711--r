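#!/usr/bin/env Rscript
# Call TSSs from the TEX+ 5'-end profiles with TEX- validation: 100-bp
# clustering, sd < 10 sub-clustering, >= 3-read filter, per-sub-cluster
# maximum peak, within-cluster pruning, +/-5 bp TEX- support. Compares the
# called set against the planted truth.

suppressMessages(library(txlandscape))

tex_plus <- list(
  "+" = read_bedgraph("results/data/tex_plus_fwd.bedgraph", "TEX_plus", "+"),
  "-" = read_bedgraph("results/data/tex_plus_rev.bedgraph", "TEX_plus", "-"))
tex_minus <- list(
  "+" = read_bedgraph("results/data/tex_minus_fwd.bedgraph", "TEX_minus", "+"),
  "-" = read_bedgraph("results/data/tex_minus_rev.bedgraph", "TEX_minus", "-"))

called <- call_tss(tex_plus, tex_minus)
write.table(called, "results/tss_called.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/data/tss_truth.tsv")
key <- function(df) paste(df$position, df$strand)
precision <- mean(key(called) %in% key(truth))
recall <- mean(key(truth) %in% key(called))
message(nrow(called), " TSSs called from ",
        sum(sapply(tex_plus, function(p) length(p$positions))),
        " nonzero TEX+ positions")
message("vs planted truth (n = ", nrow(truth), "): precision = ",
        round(precision, 3), ", recall = ", round(recall, 3))
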