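fix <- make_test_library(4, seed = 41)          # 40 tiles
cfg <- cloning_config(seed = 41)
pool <- design_oligos(fix$library, cfg)
tcfg <- trim_config()
flank <- tcfg$five_prime_flank
cds1 <- pool$oligos$cds[1]

test_that("insert extraction: exact, mismatched, and rejected reads", {
  read <- paste0(flank, cds1, tcfg$three_prime_flank)
  expect_equal(trim_insert(read, tcfg)$insert, cds1)
  expect_true(is.na(trim_insert(read, tcfg)$reason))

  # a read with no flank at all
  r2 <- trim_insert(strrep("ACGT", 40), tcfg)
  expect_true(is.na(r2$insert))
  expect_equal(r2$reason, "no-flank")

  # one substitution inside the flank is tolerated at max_flank_mismatches = 1
  mflank <- flank
  substr(mflank, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(flank, 5, 5))[1]
  expect_equal(trim_insert(paste0(mflank, cds1), tcfg)$insert, cds1)
  strict <- trim_config(max_flank_mismatches = 0)
  expect_equal(trim_insert(paste0(mflank, cds1), strict)$reason, "no-flank")

  # flank found but the read ends before the insert does
  r3 <- trim_insert(paste0(flank, substr(cds1, 1, 40)), tcfg)
  expect_equal(r3$reason, "too-short")
})

test_that("tiered matching: exact, translated, near, and ambiguous inserts", {
  m <- match_inserts(cds1, fix$library, pool)
  expect_equal(m$tile_id, pool$oligos$tile_id[1])
  expect_equal(m$tier, 1L)

  # synonymous recoding of the same peptide: caught by the translation tier
  recoded <- reverse_translate(pool$oligos$peptide[2], seed = 999)
  if (recoded != pool$oligos$cds[2]) {
    m2 <- match_inserts(recoded, fix$library, pool)
    expect_equal(m2$tile_id, pool$oligos$tile_id[2])
    expect_equal(m2$tier, 2L)
  }

  # one nonsynonymous substitution: the unique Hamming-1 neighbour wins,
  # verified against a brute-force scan
  mut <- cds1
  substr(mut, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(cds1, 2, 2))[1]
  dists <- vapply(pool$oligos$cds, oracle_hamming, numeric(1), a = mut)
  expect_equal(sum(dists <= 1), 1L)
  m3 <- match_inserts(mut, fix$library, pool)
  expect_equal(m3$tile_id, pool$oligos$tile_id[which.min(dists)])
  expect_equal(m3$tier, 3L)

  # constructed tie: an insert equidistant from two designs is unmatched
  tie_pool <- pool
  tie_pool$oligos <- pool$oligos[1:2, ]
  a <- "AAATTT"; b <- "AAGTTC"
  tie_pool$oligos$cds <- c(a, b)                     # distance 2 apart
  tie_lib <- fix$library
  tie_lib$tiles <- fix$library$tiles[1:2, ]
  tie_lib$tiles$sequence <- translate_cds(c(a, b))   # KF / KF won't collide: check
  probe <- "AAATTC"                                  # 1 from each
  expect_equal(oracle_hamming(probe, a), 1)
  expect_equal(oracle_hamming(probe, b), 1)
  tie_lib$tiles$sequence <- c("XX1", "XX2")          # disable tier 2
  m4 <- match_inserts(probe, tie_lib, tie_pool)
  expect_true(is.na(m4$tile_id))
  expect_equal(m4$reason, "unmatched")

  # wrong length is categorized, not guessed
  m5 <- match_inserts(substr(cds1, 1, 50), fix$library, pool)
  expect_equal(m5$reason, "bad-length")
})

test_that("counting conserves reads and recovers simulator truth exactly when error-free", {
  act <- fix$library$tiles$tile_id[1:2]
  params <- screen_sim_params(n_cells = 4000, activator_ids = act,
                              n_reads_per_pool = 8000, seq_error_rate = 0,
                              seed = 51)
  dir <- withr::local_tempdir()
  sim <- simulate_screen(fix$library, pool, params, dir = dir)
  sheet <- data.frame(sample = c("gfp_pos", "presort"),
                      role = c("sorted", "naive"),
                      path = c(sim$paths[["sorted"]], sim$paths[["naive"]]))
  ct <- count_pools(sheet, fix$library, pool)

  # conservation: every read lands in exactly one category
  expect_equal(unname(ct$totals), ct$qc$reads_in)
  expect_equal(ct$qc$matched + ct$qc$rejected_no_flank +
                 ct$qc$rejected_too_short + ct$qc$rejected_bad_length +
                 ct$qc$rejected_unmatched,
               ct$qc$reads_in)

  # error-free pools match completely and equal the truth table
  expect_equal(ct$qc$matched, ct$qc$reads_in)
  truth_sorted <- sim$sorted$true_counts
  got <- ct$counts[truth_sorted$tile_id, "gfp_pos"]
  expect_equal(unname(got), truth_sorted$read_count)
  truth_naive <- sim$naive$true_counts
  expect_equal(unname(ct$counts[truth_naive$tile_id, "presort"]),
               truth_naive$read_count)

  # an empty FASTQ yields an all-zero column
  empty_fq <- file.path(dir, "empty.fastq")
  file.create(empty_fq)
  ct0 <- count_pools(list(s = sim$paths[["sorted"]], z = empty_fq),
                     fix$library, pool)
  expect_equal(unname(ct0$totals["z"]), 0L)
})

test_that("one-sided Fisher p agrees with independent enumeration and fisher.test", {
  # the worked 2x2 example
  p1 <- fisher_p_enrichment(10, 1, 100, 100)
  expect_equal(p1, oracle_hyper_tail(10, 1, 100, 100), tolerance = 1e-12)
  expect_equal(p1, fisher.test(matrix(c(10, 90, 1, 99), 2, byrow = TRUE),
                               alternative = "greater")$p.value,
               tolerance = 1e-9)

  # random tables across a range of margins
  set.seed(61)
  for (i in 1:80) {
    Ns <- sample(5:200, 1); Nn <- sample(5:200, 1)
    cs <- sample(0:min(Ns, 30), 1); cn <- sample(0:min(Nn, 30), 1)
    expect_equal(fisher_p_enrichment(cs, cn, Ns, Nn),
                 oracle_hyper_tail(cs, cn, Ns, Nn), tolerance = 1e-10)
  }
})

test_that("enrichment scoring: fold-change symmetry, BH monotonicity, ranking", {
  counts <- rbind(t1 = c(30L, 30L), t2 = c(50L, 5L), t3 = c(2L, 40L),
                  t4 = c(10L, 10L), unmatched = c(8L, 15L))
  colnames(counts) <- c("sorted", "naive")
  # equalize totals so t1's frequencies match exactly
  counts["t4", ] <- counts["t4", ] + c(0L, 7L)
  ct <- structure(list(counts = counts, totals = colSums(counts),
                       qc = NULL, roles = NULL), class = "count_table")
  res <- score_enrichment(ct)
  expect_equal(res$log2fc[res$tile_id == "t1"], 0)      # c_s=c_n, N_s=N_n
  expect_equal(res$total_sorted[1], 92L)                # unmatched excluded
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= 0))
  expect_true(all(res$q_value >= res$p_value))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_equal(res$tile_id[1], "t2")
  # hits require both the q and the fold-change gate
  expect_true(all(res$q_value[res$is_hit] < 0.05 & res$log2fc[res$is_hit] >= 1))

  zero <- ct
  zero$counts[, "naive"] <- 0L
  expect_error(score_enrichment(zero), "zero")
})

test_that("null screens produce no systematic excess of hits", {
  lib <- make_test_library(10, seed = 71)$library   # 100 tiles
  params <- screen_sim_params(n_cells = 4e4, activator_ids = character(0),
                              p_gfp_active = 0.05, p_gfp_background = 0.05,
                              seed = 72)
  a <- simulate_integration(params, lib)
  pools <- simulate_sort(a, params, seed = 73)
  ct <- count_from_pools(list(sorted = pools$sorted, naive = pools$naive), lib)
  res <- score_enrichment(ct, "sorted", "naive")
  frac <- mean(res$q_value < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))
})
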