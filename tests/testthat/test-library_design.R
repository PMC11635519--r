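test_that("worked examples: window placement under default parameters", {
  p <- tile_params()  # L = 32, v = 14, step 18

  # protein exactly one tile long -> a single window
  t32 <- tile_protein(protein_record("A", strrep("ACDEFGHK", 4)), p)
  expect_equal(nrow(t32), 1L)
  expect_equal(c(t32$start, t32$end), c(1L, 32L))
  expect_false(t32$is_terminal_anchor)

  # length 100: four regular windows plus a C-terminal-anchored one
  seq100 <- paste(sample(AA_STANDARD_TEST, 100, replace = TRUE), collapse = "")
  t100 <- tile_protein(protein_record("B", seq100), p)
  expect_equal(t100$start, c(1L, 19L, 37L, 55L, 69L))
  expect_equal(t100$end, c(32L, 50L, 68L, 86L, 100L))
  expect_equal(t100$is_terminal_anchor, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  # length 50: two windows, overlapping by exactly 14
  seq50 <- substr(seq100, 1, 50)
  t50 <- tile_protein(protein_record("C", seq50), p)
  expect_equal(t50$start, c(1L, 19L))
  expect_equal(t50$end, c(32L, 50L))
  expect_equal(t50$end[1] - t50$start[2] + 1L, 14L)

  # tiles are exact substrings of the parent
  expect_equal(t100$sequence, substring(seq100, t100$start, t100$end))
})

test_that("tile_protein agrees with brute-force window enumeration", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:500, 1)
    L <- sample(1:min(n, 60), 1)
    v <- if (L > 1) sample(0:(L - 1), 1) else 0L
    seqs <- paste(sample(AA_STANDARD_TEST, n, replace = TRUE), collapse = "")
    got <- tile_protein(protein_record("X", seqs),
                        tile_params(tile_length = L, overlap = v,
                                    short_protein_policy = "skip"))
    want <- oracle_tile_coords(n, L, v)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$is_terminal_anchor, want$anchored)
    # coverage + overlap invariants for proteins long enough to tile
    if (n >= L) {
      covered <- rep(FALSE, n)
      for (j in seq_len(nrow(got))) covered[got$start[j]:got$end[j]] <- TRUE
      expect_true(all(covered))
      if (nrow(got) > 1) {
        ov <- got$end[-nrow(got)] - got$start[-1] + 1L
        regular <- !got$is_terminal_anchor[-1]
        expect_true(all(ov[regular] == v))
        expect_true(all(ov >= v))
      }
    }
  }
})

test_that("proteome tiling: counts, ordering, dedupe, and error handling", {
  # 10 proteins of length 200: oracle gives 11 windows each (10 regular +
  # 1 anchored), 110 tiles in total
  prot <- random_proteome(10, c(200, 200), seed = 3)
  lib <- tile_proteome(prot)
  expect_equal(nrow(oracle_tile_coords(200, 32, 14)), 11L)
  expect_equal(nrow(lib$tiles), 110L)
  # deterministic ordering: proteome order then start
  expect_equal(lib$tiles$parent_id, rep(names(prot), each = 11))
  expect_true(all(tapply(lib$tiles$start, lib$tiles$parent_id, is.unsorted) == FALSE))

  # duplicate proteins under different ids: tiles collapse with merged provenance
  dup <- c(P1 = as.character(prot[[1]]), P2 = as.character(prot[[1]]))
  dlib <- tile_proteome(dup)
  expect_equal(nrow(dlib$tiles), 11L)
  expect_true(all(grepl("P1:", dlib$tiles$provenance)))
  expect_true(all(grepl("P2:", dlib$tiles$provenance)))

  # duplicate ids are an error naming the id
  expect_error(tile_proteome(c(P1 = "ACDEFGHIKL", P1 = "ACDEFGHIKL")), "P1")

  # empty proteome -> empty library
  expect_equal(nrow(tile_proteome(list())$tiles), 0L)
})

test_that("short proteins and non-standard residues are handled per policy", {
  short <- c(S1 = "MKTAYIAKQR")  # 10 aa < 32
  expect_message(lib <- tile_proteome(short), "skipped")
  expect_equal(nrow(lib$tiles), 0L)
  expect_equal(lib$qc$skipped_short, 1L)

  lib2 <- tile_proteome(short, tile_params(short_protein_policy = "emit_full_length"))
  expect_equal(nrow(lib2$tiles), 1L)
  expect_equal(lib2$tiles$sequence, "MKTAYIAKQR")

  # an X at position 40 falls in windows [19,50] and [37,68] only
  seqs <- paste(sample(AA_STANDARD_TEST, 100, replace = TRUE), collapse = "")
  substr(seqs, 40, 40) <- "X"
  t <- tile_protein(protein_record("N", seqs))
  expect_equal(attr(t, "qc")$dropped_nonstandard, 2L)
  expect_equal(t$start, c(1L, 55L, 69L))
})

test_that("coverage report: full coverage, depth range, epitope guarantee", {
  fix <- make_test_library(8, seed = 5)
  cov <- coverage_report(fix$library, fix$proteome)
  expect_equal(cov$fraction_covered, 1.0)
  expect_equal(cov$guaranteed_epitope_length, 15L)
  depths <- as.integer(names(cov$depth_histogram))
  expect_true(all(depths %in% 1:3))

  # every 15-mer of every source protein appears intact in >= 1 tile
  tiles <- fix$library$tiles$sequence
  for (seqs in as.character(fix$proteome)) {
    kmers <- unique(all_kmers(seqs, 15))
    hitall <- vapply(kmers, function(k) any(grepl(k, tiles, fixed = TRUE)),
                     logical(1))
    expect_true(all(hitall))
  }

  # overlap 0 guarantees only single-residue epitopes
  lib0 <- tile_proteome(fix$proteome, tile_params(overlap = 0))
  expect_equal(coverage_report(lib0, fix$proteome)$guaranteed_epitope_length, 1L)

  # mismatched proteome is rejected
  other <- random_proteome(2, c(60, 60), seed = 99)
  expect_error(coverage_report(fix$library, other), "mismatch")
})

test_that("library files round-trip and are byte-identical across runs", {
  fix <- make_test_library(3, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_library(fix$library, d1)
  write_library(tile_proteome(fix$proteome), d2)
  for (f in c("library.fasta", "library.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_library(d1)
  expect_equal(back$tiles[, c("tile_id", "parent_id", "start", "end",
                              "sequence", "is_terminal_anchor")],
               fix$library$tiles[, c("tile_id", "parent_id", "start", "end",
                                     "sequence", "is_terminal_anchor")])
  expect_equal(back$params$tile_length, 32L)
  idx <- library_index(back)
  expect_equal(unname(idx[fix$library$tiles$sequence]),
               fix$library$tiles$tile_id)
})
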