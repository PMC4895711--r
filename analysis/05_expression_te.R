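#!/usr/bin/env Rscript
# Normalize the mRNA and RPF count matrices (median-of-ratios), set the
# expressed-gene cutoff from the secondary metabolic reference set at
# mid-exponential phase, flag differential genes (|FC| >= 2 and p < 0.05
# in >= 2 phase contrasts, terminal genes excluded), and compute the
# translation-efficiency table.

suppressMessages(library(txlandscape))

genes <- read_gff("results/data/genes.gff3")
mrna <- read_counts("results/data/mrna_counts.tsv")
rpf <- read_counts("results/data/rpf_counts.tsv")
phase <- sub("_.*", "", colnames(mrna))

sf_m <- size_factors(mrna)
sf_r <- size_factors(rpf)
message("mRNA size factors: ", paste(round(sf_m, 3), collapse = ", "))

pm <- collapse_replicates(normalize_counts(mrna, sf_m), phase)
pr <- collapse_replicates(normalize_counts(rpf, sf_r), phase)
write_counts(round(pm, 3), "results/mrna_phase_norm.tsv")
write_counts(round(pr, 3), "results/rpf_phase_norm.tsv")

cut <- expressed_cutoff(pm, genes$gene_id[genes$category == "secondary_metabolic"])
message("expressed-gene cutoff (reference-set median at M): ",
        round(cut$cutoff, 1), "; expressed: ", sum(cut$expressed), "/",
        length(cut$expressed))

excl <- terminal_gene_ids(genes)
fl <- differential_flags(mrna, phase, expressed = cut$expressed,
                         exclude = excl)
message("pooled NB dispersion: ", signif(fl$dispersion, 3))
message("differential genes (>= 2 contrasts): ",
        sum(fl$differential, na.rm = TRUE), " of ",
        sum(!is.na(fl$differential)), " testable")
flag_tab <- data.frame(gene_id = rownames(mrna), differential = fl$differential,
                       round(fl$log2fc, 3), check.names = FALSE)
write.table(flag_tab, "results/differential_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

te <- translation_efficiency(pr, pm)
write_counts(round(te$te, 4), "results/te_table.tsv")
message("TE table written (pseudocount 1); median TE at M: ",
        round(median(te$te[, "M"]), 3))
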