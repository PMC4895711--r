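#!/usr/bin/env Rscript
# Translational buffering and pattern structure: regression of TE changes
# on mRNA changes per phase contrast (overall and per category), the
# 16 x 16 combinatorial mRNA/RPF pattern groups, monotone trend groups
# (II/ID/DI/DD), subunit-stoichiometry proportionality of the planted
# operons, and TIR composition of the high- vs low-TE gene quintiles.

suppressMessages(library(txlandscape))

genome <- read_fasta("results/data/genome.fa")
genes <- read_gff("results/data/genes.gff3")
mrna <- read_counts("results/data/mrna_counts.tsv")
rpf <- read_counts("results/data/rpf_counts.tsv")
phase <- sub("_.*", "", colnames(mrna))
pm <- collapse_replicates(normalize_counts(mrna), phase)
pr <- collapse_replicates(normalize_counts(rpf), phase)
te <- translation_efficiency(pr, pm)

cat_of <- genes$category[match(rownames(pm), genes$gene_id)]
slope_rows <- lapply(c("T", "L", "S"), function(p) {
  b <- buffering_correlation(phase_log2fc(pm, "M", p),
                             phase_log2fc(te$te, "M", p, pseudocount = 0),
                             category = cat_of)
  data.frame(contrast = paste0("M:", p), r = b$overall$r,
             slope = b$overall$slope, n = b$overall$n)
})
slopes <- do.call(rbind, slope_rows)
write.table(slopes, "results/buffering_slopes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("buffering slope by contrast (planted -0.5):")
print(slopes, row.names = FALSE)

k <- min(16L, nrow(pm))
groups <- pattern_groups(pm, pr, k = k)
write.table(groups, "results/pattern_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(k, " groups per modality -> ", attr(groups, "grid_size"),
        "-cell combinatorial grid; ", length(unique(groups$combo)),
        " cells occupied")

trends <- trend_groups(pm, pr)
write.table(trends, "results/trend_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("trend groups: ", paste(names(table(trends$group)),
                                table(trends$group), sep = "=", collapse = ", "))

st <- stoichiometry_check(normalize_counts(rpf), genes)
write.table(st, "results/stoichiometry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("stoichiometry recovery (max relative error per operon):")
print(aggregate(rel_error ~ operon_id, st, max), row.names = FALSE)

# TIR composition of high- vs low-TE genes at mid-exponential phase
te_m <- te$te[, "M"]
qs <- quantile(te_m, c(0.2, 0.8))
tir <- tir_profile(list(
  high = genes[genes$gene_id %in% names(te_m)[te_m >= qs[2]], ],
  low = genes[genes$gene_id %in% names(te_m)[te_m <= qs[1]], ]), genome)
message("TIR G+C: high-TE ", round(100 * tir$high$gc, 1), "%, low-TE ",
        round(100 * tir$low$gc, 1), "%")
message("RBS-region purine (-12..-8): high-TE ",
        round(tir$high$rbs_purine_mean, 3), ", low-TE ",
        round(tir$low$rbs_purine_mean, 3))
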