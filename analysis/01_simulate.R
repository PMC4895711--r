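#!/usr/bin/env Rscript
# Generate the synthetic study data set: a high-G+C genome with annotated
# genes and operons, TEX+/TEX- 5'-end profiles with planted TSSs, and
# mRNA/RPF count matrices over four growth phases (duplicates) with a
# planted translational-buffering slope of -0.5. All downstream scripts
# start from the standard files written here.

suppressMessages(library(txlandscape))

seed <- 1L
cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)
paths <- write_simulation(sim, "results/data")

message("genome: ", length(sim$genome), " bp, G+C = ",
        round(gc_content(sim$genome$seq), 3))
message("genes: ", nrow(sim$genes), " (",
        sum(sim$genes$category == "secondary_metabolic"),
        " secondary metabolic, ",
        sum(!is.na(sim$genes$operon_id)), " in operons)")
message("planted TSSs: ", nrow(sim$truth$tss_truth), " (",
        sum(sim$truth$tss_truth$is_leaderless), " leaderless)")
message("count matrices: ", nrow(sim$mrna), " genes x ", ncol(sim$mrna),
        " samples (mRNA and RPF)")
message("inputs written under results/data/")
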