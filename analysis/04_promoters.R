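#!/usr/bin/env Rscript
# Promoter architecture of the classified TSSs: -10 (TANNNT) and -35
# (NTGACC) consensus hexamers in their strand-oriented windows, spacer
# lengths between the motifs, and promoter G+C content.

suppressMessages(library(txlandscape))

genome <- read_fasta("results/data/genome.fa")
records <- read.delim("results/tss_classified.tsv")

prom <- promoter_table(records, genome)
write.table(prom, "results/promoters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n <- nrow(prom)
message("promoters analysed: ", n)
message("-10 motif found: ", round(100 * mean(!is.na(prom$minus10_offset)), 1),
        "%;  -35 motif found: ",
        round(100 * mean(!is.na(prom$minus35_offset)), 1), "%")
sp <- prom$spacer[!is.na(prom$spacer)]
hist_tab <- as.data.frame(table(spacer = sp))
write.table(hist_tab, "results/spacer_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("spacers 15-20 nt: ", round(100 * mean(sp >= 15 & sp <= 20), 1),
        "% of ", length(sp))
message("mean promoter G+C: ", round(100 * mean(prom$promoter_gc), 1),
        "% (genome-wide ", round(100 * gc_content(genome$seq), 1), "%)")
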