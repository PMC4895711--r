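test_that("position_sd uses the n-1 divisor and handles singletons", {
  expect_equal(position_sd(c(100, 114)), 9.9, tolerance = 0.05 / 9.9)
  expect_equal(position_sd(c(100, 114, 128)), 14.0, tolerance = 0.005)
  expect_equal(position_sd(100:128), 8.5, tolerance = 0.05 / 8.5)
  expect_equal(position_sd(500), 0)
  expect_error(position_sd(numeric(0)))
})

test_that("100-bp partition chains gaps and matches the transitive-closure oracle", {
  p <- make_profile(c(100, 150, 260), c(5, 5, 5))
  cl <- partition_candidates(p)
  expect_equal(lapply(cl, `[[`, "positions"), list(c(100L, 150L), 260L))

  p <- make_profile(c(100, 200, 300), c(5, 5, 5))
  expect_length(partition_candidates(p), 1L)

  expect_length(partition_candidates(make_profile(42, 3)), 1L)

  set.seed(1)
  for (rep in 1:50) {
    pos <- sort(sample.int(2000L, sample(2:15, 1)))
    got <- lapply(partition_candidates(make_profile(pos, rep(1L, length(pos)))),
                  `[[`, "positions")
    expect_equal(lapply(got, as.numeric), lapply(oracle_partition(pos), as.numeric))
  }
})

test_that("sd sub-clustering reproduces the narrated worked examples", {
  cl <- list(positions = c(100L, 114L, 128L),
             counts = c(5L, 9L, 4L), strand = "+")
  sub <- subcluster_by_sd(cl)
  expect_equal(lapply(sub, `[[`, "positions"), list(c(100L, 114L), 128L))

  run29 <- list(positions = 100:128, counts = rep(1L, 29), strand = "+")
  expect_length(subcluster_by_sd(run29), 1L)

  two <- list(positions = c(100L, 150L), counts = c(5L, 5L), strand = "+")
  expect_length(subcluster_by_sd(two), 2L)
})

test_that("sub-clustering matches the ordered-partition enumeration oracle", {
  set.seed(2)
  for (rep in 1:60) {
    n <- sample(2:9, 1)
    pos <- sort(sample.int(120L, n))
    cl <- list(positions = pos, counts = rep(1L, n), strand = "+")
    got <- lapply(subcluster_by_sd(cl), function(s) as.numeric(s$positions))
    expect_equal(got, lapply(oracle_subcluster(pos), as.numeric))
  }
})

test_that("partition and sub-clustering conserve positions", {
  set.seed(3)
  pos <- sort(sample.int(5000L, 200L))
  cnt <- rpois(200L, 4) + 1L
  prof <- make_profile(pos, cnt)
  cl <- partition_candidates(prof)
  expect_equal(sort(unlist(lapply(cl, `[[`, "positions"))), pos)
  sub <- unlist(lapply(cl, subcluster_by_sd), recursive = FALSE)
  expect_equal(sort(unlist(lapply(sub, `[[`, "positions"))), pos)
})

test_that("low-read clusters are removed at the stated threshold", {
  mk <- function(counts) list(positions = seq_along(counts), counts = counts,
                              strand = "+")
  expect_length(filter_min_reads(list(mk(c(1L, 1L)))), 0L)
  expect_length(filter_min_reads(list(mk(3L))), 1L)
  expect_length(filter_min_reads(list(mk(c(1L, 1L, 1L)))), 1L)
})

test_that("peak selection takes the maximum with a 5'-most tie-break", {
  sub <- list(list(positions = c(100L, 114L), counts = c(5L, 9L), strand = "+"))
  got <- select_subcluster_peaks(sub)
  expect_equal(got$position, 114L)
  expect_equal(got$height, 9L)

  tie_p <- list(list(positions = c(100L, 114L), counts = c(7L, 7L), strand = "+"))
  expect_equal(select_subcluster_peaks(tie_p)$position, 100L)
  tie_m <- list(list(positions = c(100L, 114L), counts = c(7L, 7L), strand = "-"))
  expect_equal(select_subcluster_peaks(tie_m)$position, 114L)
})

test_that("close candidate TSSs are pruned to the highest peak", {
  cand <- make_candidates(c(200L, 205L), c(10L, 7L))
  expect_equal(prune_close_tss(cand)$position, 200L)

  cand <- make_candidates(c(200L, 300L), c(10L, 7L))
  expect_equal(prune_close_tss(cand)$position, c(200L, 300L))

  single <- make_candidates(500L, 3L)
  expect_equal(prune_close_tss(single), single)
})

test_that("TEX- validation keeps peaks with support within +/-5 bp", {
  cand <- make_candidates(500L, 10L)
  near <- make_profile(503L, 1L, library = "TEX_minus")
  far <- make_profile(506L, 1L, library = "TEX_minus")
  none <- five_prime_profile(integer(0), integer(0), "+", "TEX_minus")
  expect_equal(nrow(validate_against_control(cand, near)), 1L)
  expect_true(validate_against_control(cand, near)$validated)
  expect_equal(nrow(validate_against_control(cand, far)), 0L)
  expect_equal(nrow(validate_against_control(cand, none)), 0L)
})

test_that("the composed caller executes the worked example end to end", {
  tex_plus <- make_profile(c(100L, 114L, 128L), c(5L, 9L, 4L))
  tex_minus <- make_profile(c(100L, 114L, 128L), c(2L, 3L, 2L),
                            library = "TEX_minus")
  # before pruning, both sub-cluster maxima are selected (114 and 128)...
  cl <- partition_candidates(tex_plus)
  sub <- filter_min_reads(subcluster_by_sd(cl[[1]]))
  expect_equal(select_subcluster_peaks(sub)$position, c(114L, 128L))
  # ...but sd(114,128) = 9.9 < 10, so pruning removes the lower peak
  called <- call_tss(tex_plus, tex_minus)
  expect_equal(called$position, 114L)
  expect_equal(called$height, 9L)
})

test_that("caller output is a subset of nonzero TEX+ positions and deterministic", {
  sim <- simulate_dataset(sim_config(seed = 5))
  a <- call_tss(sim$profiles$tex_plus, sim$profiles$tex_minus)
  b <- call_tss(sim$profiles$tex_plus, sim$profiles$tex_minus)
  expect_identical(a, b)
  for (s in c("+", "-")) {
    expect_true(all(a$position[a$strand == s] %in%
                      sim$profiles$tex_plus[[s]]$positions))
  }
})

test_that("raising min_reads or sd_threshold never yields more TSSs", {
  set.seed(6)
  for (rep in 1:20) {
    pos <- sort(sample.int(3000L, 60L))
    cnt <- rpois(60L, 5) + 1L
    tp <- make_profile(pos, cnt)
    tm <- make_profile(pos, pmax(1L, cnt %/% 2L), library = "TEX_minus")
    n_base <- nrow(call_tss(tp, tm))
    expect_lte(nrow(call_tss(tp, tm, min_reads = 6)), n_base)
    expect_lte(nrow(call_tss(tp, tm, sd_threshold = 25)), n_base)
  }
})

test_that("a smaller clustering gap never yields fewer clusters", {
  set.seed(7)
  pos <- sort(sample.int(5000L, 120L))
  prof <- make_profile(pos, rep(5L, 120L))
  expect_gte(length(partition_candidates(prof, cluster_gap = 50)),
             length(partition_candidates(prof, cluster_gap = 100)))
})
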