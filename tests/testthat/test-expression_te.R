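test_that("median-of-ratios size factors reproduce closed-form cases", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-3)

  m3 <- matrix(c(4L, 9L), 1, 2, dimnames = list("g", c("s1", "s2")))
  expect_equal(unname(size_factors(m3)), c(4 / 6, 9 / 6), tolerance = 1e-6)

  expect_error(size_factors(cbind(c(0L, 0L), c(1L, 2L))), "nonzero")
})

test_that("size factors agree with the DESeq2 reference estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(30)
  m <- matrix(rnbinom(400 * 6, mu = 80, size = 10), 400, 6)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("normalization is invariant to per-sample scaling", {
  set.seed(31)
  m <- matrix(rnbinom(200 * 4, mu = 100, size = 20) + 1L, 200, 4)
  sf1 <- size_factors(m)
  norm1 <- normalize_counts(m, sf1)
  m2 <- m
  m2[, 3] <- m[, 3] * 3L
  sf2 <- size_factors(m2)
  norm2 <- normalize_counts(m2, sf2)
  # the scaled column's factor triples and its normalized values relative
  # to any other column are unchanged (size factors are defined up to a
  # common rescaling of the geometric-mean reference)
  expect_equal(sf2[3] / sf2[1], 3 * sf1[3] / sf1[1], tolerance = 1e-10)
  expect_equal(norm2[, 3] / norm2[, 1], norm1[, 3] / norm1[, 1],
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_equal(normalize_counts(m, rep(1, 4)), m, ignore_attr = TRUE)
  expect_equal(normalize_counts(matrix(10, 1, 2), c(2, 2)),
               matrix(5, 1, 2))
  expect_error(normalize_counts(m, c(1, -1, 1, 1)), "positive")
})

test_that("RPKM follows its defining ratio", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_error(rpkm(10, 0, 1e6), "positive")
})

test_that("the expressed cutoff is the reference median with a strict rule", {
  pm <- rbind(r1 = c(M = 10, T = 1, L = 1, S = 1),
              r2 = c(M = 30, T = 1, L = 1, S = 1),
              r3 = c(M = 50, T = 1, L = 1, S = 1),
              gA = c(M = 30, T = 30, L = 30, S = 30),   # never above cutoff
              gB = c(M = 5, T = 31, L = 2, S = 2))      # above at one phase
  out <- expressed_cutoff(pm, c("r1", "r2", "r3"))
  expect_equal(out$cutoff, 30)
  expect_false(out$expressed[["gA"]])
  expect_true(out$expressed[["gB"]])
  expect_error(expressed_cutoff(pm, character(0)), "empty")
})

test_that("identical phase values yield zero fold-change and no flag", {
  m <- matrix(50L, 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  phase <- rep(c("M", "T", "L", "S"), each = 2)
  fl <- differential_flags(m, phase, dispersion = 0.01)
  expect_true(all(fl$log2fc == 0))
  expect_false(any(fl$differential))
})

test_that("the NB test is calibrated and powered on planted data", {
  # clean null: no planted fold-changes anywhere
  cfg0 <- sim_config(seed = 32, genome_length = 1e6, n_genes = 1000,
                     phase_foldchange_sd = 0, secondary_fraction = 0,
                     regulator_fraction = 0, include_operons = FALSE)
  ga0 <- simulate_genome_annotation(cfg0)
  cm0 <- simulate_count_matrices(ga0$genes, ga0$truth, cfg0)
  fl0 <- differential_flags(cm0$mrna, cm0$phase)
  n <- nrow(cm0$mrna)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(mean(fl0$p[, "M:T"] < 0.05), 0.05 + 3 * se)
  expect_lte(mean(fl0$differential), 0.05 + 3 * se)

  # planted 4-fold genes at phases T and L are flagged
  cfg1 <- sim_config(seed = 33, genome_length = 1e6, n_genes = 1000,
                     phase_foldchange_sd = 0, secondary_fraction = 0,
                     regulator_fraction = 0, include_operons = FALSE,
                     n_diff_genes = 150, diff_log2fc = 2)
  ga1 <- simulate_genome_annotation(cfg1)
  cm1 <- simulate_count_matrices(ga1$genes, ga1$truth, cfg1)
  excl <- terminal_gene_ids(ga1$genes)
  fl1 <- differential_flags(cm1$mrna, cm1$phase, exclude = excl)
  diff_ok <- setdiff(cm1$truth$diff_genes, excl)
  expect_gte(mean(fl1$differential[diff_ok]), 0.95)
  null_ok <- setdiff(rownames(cm1$mrna), c(cm1$truth$diff_genes, excl))
  expect_lte(mean(fl1$differential[null_ok]), 0.05 + 3 * se)
  # excluded terminal genes never carry a flag
  expect_true(all(is.na(fl1$differential[excl])))
})

test_that("tightening the fold-change threshold never adds flags", {
  cfg <- sim_config(seed = 34, genome_length = 2e5, n_genes = 200)
  ga <- simulate_genome_annotation(cfg)
  cm <- simulate_count_matrices(ga$genes, ga$truth, cfg)
  n2 <- sum(differential_flags(cm$mrna, cm$phase, fc_threshold = 2)$differential)
  n3 <- sum(differential_flags(cm$mrna, cm$phase, fc_threshold = 3)$differential)
  n4 <- sum(differential_flags(cm$mrna, cm$phase, fc_threshold = 4)$differential)
  expect_true(n4 <= n3 && n3 <= n2)
})

test_that("TE applies the pseudocount and responds monotonically", {
  pm <- matrix(c(49, 0, 100), 3, 1, dimnames = list(c("a", "b", "c"), "M"))
  pr <- matrix(c(99, 0, 100), 3, 1, dimnames = list(c("a", "b", "c"), "M"))
  te <- translation_efficiency(pr, pm)
  expect_equal(unname(te$te[, 1]), c(2, 1, 1))

  # strictly increasing in RPF, decreasing in mRNA
  expect_gt(translation_efficiency(pr + 10, pm)$te[1, 1], te$te[1, 1])
  expect_lt(translation_efficiency(pr, pm + 10)$te[1, 1], te$te[1, 1])

  # mRNA doubling with constant RPF drives delta-log2-TE towards -1
  pm2 <- cbind(M = 1e5, T = 2e5)
  pr2 <- cbind(M = 1e5, T = 1e5)
  te2 <- translation_efficiency(pr2, pm2)
  expect_equal(unname(log2(te2$te[, "T"] / te2$te[, "M"])), -1,
               tolerance = 1e-4)

  expect_error(translation_efficiency(pr, pm[1:2, , drop = FALSE]), "shape")
})

test_that("replicate collapsing averages normalized columns per phase", {
  m <- cbind(M_1 = c(1, 2), M_2 = c(3, 4), T_1 = c(5, 6), T_2 = c(7, 8))
  rownames(m) <- c("a", "b")
  pm <- collapse_replicates(m, c("M", "M", "T", "T"))
  expect_equal(pm, cbind(M = c(a = 2, b = 3), T = c(a = 6, b = 7)))
})
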