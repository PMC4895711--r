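test_that("TSS classes follow the window scheme around start codons", {
  genes <- make_genes(1000L, 2000L, "+", "g1")
  # lone TSS in the -500..+150 window -> primary
  rec <- classify_tss(make_candidates(950L, 10L), genes)
  expect_equal(rec$class_label, "P")
  expect_equal(rec$gene_id, "g1")
  expect_equal(rec$utr_length, 50L)
  # a second, lower TSS -> secondary
  rec <- classify_tss(make_candidates(c(950L, 900L), c(10L, 4L)), genes)
  expect_equal(rec$class_label[rec$position == 900L], "S")
  # same strand inside the ORF beyond +150 -> internal
  rec <- classify_tss(make_candidates(1500L, 5L), genes)
  expect_equal(rec$class_label, "I")
  # opposite strand inside the ORF -> antisense
  rec <- classify_tss(make_candidates(1500L, 5L, strand = "-"), genes)
  expect_equal(rec$class_label, "A")
  # no gene in range -> intergenic
  rec <- classify_tss(make_candidates(400L, 5L), genes)
  expect_equal(rec$class_label, "N")
})

test_that("multi-gene ambiguity resolves to the nearest start codon", {
  genes <- make_genes(c(1000L, 1300L), c(1200L, 2000L), c("+", "+"))
  rec <- classify_tss(make_candidates(1250L, 8L), genes)
  expect_equal(rec$gene_id, "g02")  # 50 bp from g02's codon, 250 from g01's
})

test_that("classification is exhaustive, exclusive, and strand-oriented", {
  set.seed(10)
  genes <- make_genes(seq(1000L, 19000L, by = 2000L),
                      seq(1800L, 19800L, by = 2000L),
                      sample(c("+", "-"), 10, replace = TRUE))
  cands <- make_candidates(sort(sample.int(20000L, 60L)),
                           sample(3:30, 60, replace = TRUE),
                           strand = sample(c("+", "-"), 60, replace = TRUE))
  rec <- classify_tss(cands, genes)
  expect_false(anyNA(rec$class_label))
  expect_equal(sum(table(rec$class_label)), nrow(cands))
  expect_true(all(!is.na(rec$gene_id[rec$class_label %in% c("P", "S")])))
  # at most one primary TSS per gene
  p <- rec[rec$class_label == "P", ]
  expect_false(anyDuplicated(p$gene_id) > 0)
})

test_that("classification matches the per-pair brute-force oracle", {
  set.seed(11)
  for (rep in 1:40) {
    ng <- sample(2:8, 1)
    starts <- sort(sample.int(15000L, ng)) + (0:(ng - 1)) * 1200L
    genes <- make_genes(starts, starts + sample(500:900, ng, replace = TRUE),
                        sample(c("+", "-"), ng, replace = TRUE))
    nc <- sample(3:20, 1)
    cands <- make_candidates(sample.int(max(genes$end) + 1000L, nc),
                             sample(3:30, nc, replace = TRUE),
                             strand = sample(c("+", "-"), nc, replace = TRUE))
    rec <- classify_tss(cands, genes)
    orc <- oracle_classify(cands, genes)
    expect_equal(rec$class_label, orc$class_label)
    expect_equal(rec$gene_id[rec$class_label %in% c("P", "S")],
                 orc$gene_id[orc$class_label %in% c("P", "S")])
  }
})

test_that("UTR length is strand-oriented and undefined inside the ORF", {
  expect_equal(utr_length(950L, "+", 1000L, 2000L, "+"), 50L)
  expect_equal(utr_length(1000L, "+", 1000L, 2000L, "+"), 0L)
  expect_true(is.na(utr_length(1030L, "+", 1000L, 2000L, "+")))
  expect_equal(utr_length(2050L, "-", 1000L, 2000L, "-"), 50L)
  expect_true(is.na(utr_length(1980L, "-", 1000L, 2000L, "-")))
  expect_error(utr_length(950L, "+", 1000L, 2000L, "-"), "strand")
})

test_that("leader status splits at <9 and >150 nt", {
  expect_equal(leader_status(8), "leaderless")
  expect_equal(leader_status(9), "leadered")
  expect_equal(leader_status(44), "leadered")
  expect_equal(leader_status(150), "leadered")
  expect_equal(leader_status(151), "long_leader")
  expect_error(leader_status(NA), "undefined")
})

test_that("start-codon usage reads oriented codons from the genome", {
  g <- make_genome(200)
  g <- plant_seq(g, 50, "ATG")
  g <- plant_seq(g, 100, "ATG")
  g <- plant_seq(g, 120, "ATG")
  g <- plant_seq(g, 148, "CAT")  # '-' strand gene ending CAT == ATG
  g <- plant_seq(g, 80, "GTG")
  genes <- make_genes(c(50L, 100L, 120L, 130L, 80L),
                      c(70L, 110L, 140L, 150L, 95L),
                      c("+", "+", "+", "-", "+"))
  fr <- start_codon_usage(genes, g)
  expect_equal(unname(fr["ATG"]), 0.8)
  expect_equal(unname(fr["GTG"]), 0.2)
  expect_equal(sum(fr), 1)

  # codon window outside the genome is skipped with a warning
  genes2 <- rbind(genes, make_genes(199L, 250L, "+", "gx"))
  expect_warning(fr2 <- start_codon_usage(genes2, g), "skipped")
  expect_equal(sum(fr2), 1)
})

test_that("TSS context recovers the planted purine preference", {
  cfg <- sim_config(seed = 12, genome_length = 5e5, n_genes = 500,
                    tss_purine_fraction = 0.9)
  ga <- simulate_genome_annotation(cfg)
  ctx <- tss_context(ga$truth$tss_truth, ga$genome)
  expect_equal(ctx$purine_fraction, 0.9, tolerance = 0.04 / 0.9)
  expect_equal(unname(rowSums(ctx$fractions)), rep(1, 5))
})

test_that("sRNA candidates are the A/N TSSs with an occupancy flag", {
  rec <- data.frame(position = c(100L, 200L, 300L, 400L),
                    strand = "+", height = 5L,
                    class_label = c("P", "A", "N", "I"),
                    gene_id = c("g1", NA, NA, "g2"),
                    utr_length = c(10L, NA, NA, NA),
                    leader_status = c("leadered", rep("undefined", 3)),
                    stringsAsFactors = FALSE)
  out <- srna_candidates(rec, rpf_rpkm = c(99, 0, 50, 99),
                         occupancy_threshold = 32.8)
  expect_equal(out$class_label, c("A", "N"))
  expect_equal(out$coding_flag, c(FALSE, TRUE))
})

test_that("recovered leaderless fraction matches the planted fraction", {
  f <- 0.21
  cfg <- sim_config(seed = 13, genome_length = 4e5, n_genes = 400,
                    leaderless_fraction = f)
  ga <- simulate_genome_annotation(cfg)
  sim <- simulate_dataset(cfg)
  called <- call_tss(sim$profiles$tex_plus, sim$profiles$tex_minus)
  rec <- classify_tss(called, sim$genes)
  ps <- rec[rec$class_label %in% c("P", "S") & rec$leader_status != "undefined", ]
  n <- nrow(ps)
  expect_gte(n, 300)
  got <- mean(ps$leader_status == "leaderless")
  expect_lt(abs(got - f), 3 * sqrt(f * (1 - f) / n))
})
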