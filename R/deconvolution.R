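# Deconvolution: FASTQ pools -> per-tile counts -> ranked enrichment calls.

#' Trimming configuration
#'
#' Locates the constant region 5' of the insert and extracts a fixed-length
#' insert. Defaults match [cloning_config()]: the constant regions carried
#' by the screen's amplification adapters, and a 96 nt insert (32 codons).
#'
#' @param five_prime_flank constant sequence immediately 5' of the insert.
#' @param three_prime_flank constant sequence 3' of the insert (recorded
#'   for provenance; extraction is anchored on the 5' flank).
#' @param max_flank_mismatches substitutions tolerated when locating the
#'   5' flank.
#' @param insert_length expected insert length in nt (3 x tile length).
#' @return an object of class `trim_config`.
#' @export
trim_config <- function(five_prime_flank = cloning_config()$five_prime_arm,
                        three_prime_flank = cloning_config()$three_prime_arm,
                        max_flank_mismatches = 1L,
                        insert_length = 96L) {
  five_prime_flank <- toupper(five_prime_flank)
  if (!nzchar(five_prime_flank)) {
    stop("'five_prime_flank' must be non-empty", call. = FALSE)
  }
  structure(list(
    five_prime_flank = five_prime_flank,
    three_prime_flank = toupper(three_prime_flank),
    max_flank_mismatches = stopifnot_scalar_int(max_flank_mismatches,
                                                "max_flank_mismatches", min = 0L),
    insert_length = stopifnot_scalar_int(insert_length, "insert_length", min = 3L)
  ), class = "trim_config")
}

#' Extract the insert from one read
#'
#' Scalar convenience wrapper around [trim_reads()].
#'
#' @param read nucleotide string.
#' @param config a [trim_config()].
#' @return list with `insert` (string or `NA`) and `reason` (`NA` on
#'   success, else `"no-flank"` or `"too-short"`).
#' @export
trim_insert <- function(read, config = trim_config()) {
  if (!nzchar(read)) stop("read must be non-empty", call. = FALSE)
  res <- trim_reads(Biostrings::DNAStringSet(read), config)
  list(insert = res$insert[1], reason = res$reason[1])
}

#' Extract inserts from a set of reads
#'
#' Finds the leftmost occurrence of the 5' flank (exact first, then
#' allowing up to `max_flank_mismatches` substitutions) and takes the
#' following `insert_length` bases. Rejections are categorized, never
#' dropped silently: `"no-flank"` (flank not found) or `"too-short"`
#' (read ends before the insert does).
#'
#' @param reads a `DNAStringSet` (or character vector).
#' @param config a [trim_config()].
#' @return data.frame with one row per read: `insert` (NA when rejected)
#'   and `reason` (NA when accepted).
#' @export
trim_reads <- function(reads, config = trim_config()) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  n <- length(reads)
  flank <- config$five_prime_flank
  insert_start <- rep(NA_integer_, n)

  exact <- Biostrings::vmatchPattern(flank, reads)
  st <- Biostrings::startIndex(exact)
  has <- lengths(st) > 0L
  insert_start[has] <- vapply(st[has], min, integer(1)) + nchar(flank)

  if (config$max_flank_mismatches > 0L && any(!has)) {
    rest <- which(!has)
    fuzzy <- Biostrings::vmatchPattern(flank, reads[rest],
                                       max.mismatch = config$max_flank_mismatches,
                                       with.indels = FALSE)
    stf <- Biostrings::startIndex(fuzzy)
    hasf <- lengths(stf) > 0L
    insert_start[rest[hasf]] <- vapply(stf[hasf], min, integer(1)) + nchar(flank)
  }

  width <- Biostrings::width(reads)
  reason <- rep(NA_character_, n)
  reason[is.na(insert_start)] <- "no-flank"
  ok <- !is.na(insert_start)
  too_short <- ok & (insert_start + config$insert_length - 1L > width)
  reason[too_short] <- "too-short"
  ok <- ok & !too_short

  insert <- rep(NA_character_, n)
  if (any(ok)) {
    insert[ok] <- as.character(Biostrings::subseq(
      reads[ok], start = insert_start[ok], width = config$insert_length))
  }
  data.frame(insert = insert, reason = reason, stringsAsFactors = FALSE)
}

#' Match inserts back to the designed library
#'
#' Three tiers, most to least specific: (1) exact nucleotide match against
#' the designed coding sequences; (2) exact amino-acid match of the
#' translated insert against the peptide library (absorbs synonymous
#' divergence); (3) unique nearest neighbour within `max_nt_mismatches`
#' substitutions — a tie (two or more equally near designs) is reported
#' unmatched rather than guessed.
#'
#' @param inserts character vector of insert sequences (all of length
#'   3 x tile length; others are rejected `"bad-length"`).
#' @param library a `tile_library`.
#' @param oligo_pool the `oligo_pool` the screen was built with.
#' @param max_nt_mismatches tier-3 mismatch budget (default 1).
#' @return data.frame with one row per insert: `tile_id` (NA when
#'   unmatched), `tier` (1-3, NA), `reason` (`"bad-length"`,
#'   `"unmatched"`, or NA).
#' @export
match_inserts <- function(inserts, library, oligo_pool,
                          max_nt_mismatches = 1L) {
  stopifnot(inherits(library, "tile_library"), inherits(oligo_pool, "oligo_pool"))
  cds <- oligo_pool$oligos$cds
  cds_tile <- oligo_pool$oligos$tile_id
  pep_index <- library_index(library)
  insert_len <- nchar(cds[1])

  n <- length(inserts)
  tile <- rep(NA_character_, n)
  tier <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  badlen <- is.na(inserts) | nchar(inserts) != insert_len |
    grepl("[^ACGT]", inserts)
  reason[badlen] <- "bad-length"

  todo <- which(!badlen)
  # work on unique inserts: sequencing error patterns repeat heavily
  uq <- unique(inserts[todo])
  u_tile <- rep(NA_character_, length(uq))
  u_tier <- rep(NA_integer_, length(uq))

  m1 <- match(uq, cds)
  hit1 <- !is.na(m1)
  u_tile[hit1] <- cds_tile[m1[hit1]]
  u_tier[hit1] <- 1L

  rest <- which(!hit1)
  if (length(rest) > 0) {
    aa <- translate_cds(uq[rest])
    m2 <- pep_index[aa]
    hit2 <- !is.na(m2)
    u_tile[rest[hit2]] <- unname(m2[hit2])
    u_tier[rest[hit2]] <- 2L
    rest <- rest[!hit2]
  }
  if (length(rest) > 0 && max_nt_mismatches > 0) {
    hm <- hamming_nearest(uq[rest], cds, max_nt_mismatches)
    uniq3 <- !is.na(hm$idx)
    u_tile[rest[uniq3]] <- cds_tile[hm$idx[uniq3]]
    u_tier[rest[uniq3]] <- 3L
  }

  pos <- match(inserts[todo], uq)
  tile[todo] <- u_tile[pos]
  tier[todo] <- u_tier[pos]
  reason[!badlen & is.na(tile)] <- "unmatched"
  data.frame(tile_id = tile, tier = tier, reason = reason,
             stringsAsFactors = FALSE)
}

# For each query, the index of the unique cds within max_mm Hamming
# distance (NA when none or ambiguous). Byte-matrix comparison: one pass
# over the cds set, vectorized over queries.
hamming_nearest <- function(queries, cds, max_mm) {
  nq <- length(queries)
  if (nq == 0L) return(list(idx = integer(0)))
  w <- nchar(cds[1])
  qmat <- matrix(unlist(lapply(queries, charToRaw)), nrow = w)
  best <- rep(Inf, nq)
  best_idx <- rep(NA_integer_, nq)
  ambiguous <- logical(nq)
  for (j in seq_along(cds)) {
    d <- colSums(qmat != charToRaw(cds[j]))
    better <- d < best
    tie <- d == best & is.finite(best)
    ambiguous[tie] <- TRUE
    ambiguous[better] <- FALSE
    best_idx[better] <- j
    best[better] <- d[better]
  }
  ok <- best <= max_mm & !ambiguous
  list(idx = ifelse(ok, best_idx, NA_integer_), dist = best)
}

#' Count reads per tile across samples
#'
#' Runs trim + match on every sample and assembles the peptide-by-sample
#' count table, with an `unmatched` row so that each column sums to the
#' sample's read count (read conservation: every input read lands in
#' exactly one of matched / no-flank / too-short / bad-length / unmatched).
#'
#' @param samples named list/vector of FASTQ paths, or a sample sheet
#'   data.frame with columns `sample`, `role` (`"sorted"`/`"naive"`),
#'   `path`. Reads can also be passed directly as `DNAStringSet`s.
#' @param library a `tile_library`.
#' @param oligo_pool the matching `oligo_pool`.
#' @param trim a [trim_config()].
#' @param max_nt_mismatches tier-3 budget for [match_inserts()].
#' @return an object of class `count_table`: list with `counts` (integer
#'   matrix, rows = tile ids + `"unmatched"`, columns = samples), `totals`
#'   (per-sample read counts), `qc` (per-sample data.frame of reads in /
#'   trimmed / matched by tier / rejected by reason), and `roles` (named
#'   character vector when a sample sheet was supplied).
#' @export
count_pools <- function(samples, library, oligo_pool, trim = trim_config(),
                        max_nt_mismatches = 1L) {
  roles <- NULL
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample", "role", "path") %in% names(samples)))
    roles <- setNames(samples$role, samples$sample)
    samples <- setNames(as.list(samples$path), samples$sample)
  }
  if (is.character(samples)) samples <- as.list(samples)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be named", call. = FALSE)
  }
  if (length(samples) < 2L) {
    stop("need at least 2 samples (one sorted, one naive)", call. = FALSE)
  }

  tids <- library$tiles$tile_id
  counts <- matrix(0L, nrow = length(tids) + 1L, ncol = length(samples),
                   dimnames = list(c(tids, "unmatched"), names(samples)))
  qc <- vector("list", length(samples))

  for (s in seq_along(samples)) {
    reads <- samples[[s]]
    if (is.character(reads)) {
      reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    }
    trimmed <- trim_reads(reads, trim)
    ok <- is.na(trimmed$reason)
    matched <- match_inserts(trimmed$insert[ok], library, oligo_pool,
                             max_nt_mismatches)
    tab <- table(factor(matched$tile_id, levels = tids))
    counts[seq_along(tids), s] <- as.integer(tab)
    counts["unmatched", s] <- sum(!ok) + sum(is.na(matched$tile_id))
    qc[[s]] <- data.frame(
      sample = names(samples)[s],
      reads_in = length(reads),
      trimmed = sum(ok),
      matched = sum(!is.na(matched$tile_id)),
      matched_tier1 = sum(matched$tier == 1L, na.rm = TRUE),
      matched_tier2 = sum(matched$tier == 2L, na.rm = TRUE),
      matched_tier3 = sum(matched$tier == 3L, na.rm = TRUE),
      rejected_no_flank = sum(trimmed$reason == "no-flank", na.rm = TRUE),
      rejected_too_short = sum(trimmed$reason == "too-short", na.rm = TRUE),
      rejected_bad_length = sum(matched$reason == "bad-length", na.rm = TRUE),
      rejected_unmatched = sum(matched$reason == "unmatched", na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  structure(list(counts = counts,
                 totals = colSums(counts),
                 qc = do.call(rbind, qc),
                 roles = roles),
            class = "count_table")
}

#' Build a count table directly from simulated pools
#'
#' Bypasses read simulation and deconvolution: tabulates tile multisets
#' (e.g. `simulate_sort()` output) directly. Used for statistical
#' calibration studies where sequencing is not the question.
#'
#' @param pools named list of character vectors of tile ids.
#' @param library a `tile_library`.
#' @return a `count_table` (with an all-zero `unmatched` row).
#' @export
count_from_pools <- function(pools, library) {
  stopifnot(is.list(pools), !is.null(names(pools)),
            inherits(library, "tile_library"))
  tids <- library$tiles$tile_id
  counts <- vapply(pools, function(p) {
    as.integer(table(factor(p, levels = tids)))
  }, integer(length(tids)))
  counts <- rbind(counts, unmatched = 0L)
  rownames(counts) <- c(tids, "unmatched")
  structure(list(counts = counts, totals = colSums(counts),
                 qc = NULL, roles = NULL),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Count table: %d tiles x %d samples (totals: %s)\n",
              nrow(x$counts) - 1L, ncol(x$counts),
              paste(sprintf("%s=%d", colnames(x$counts), x$totals),
                    collapse = ", ")))
  invisible(x)
}

#' Score per-tile enrichment of the sorted pool over the naive pool
#'
#' For each tile with sorted count \eqn{c_s} of \eqn{N_s} matched reads
#' and naive count \eqn{c_n} of \eqn{N_n}:
#' \deqn{\log_2 FC = \log_2\frac{(c_s + a)/(N_s + 2a)}{(c_n + a)/(N_n + 2a)}}
#' with pseudocount \eqn{a}; the p-value is the one-sided Fisher exact
#' test (hypergeometric tail) for enrichment on the 2x2 table
#' \eqn{(c_s, N_s - c_s; c_n, N_n - c_n)}; q-values are Benjamini-Hochberg
#' over all tested tiles. A tile is a hit when `q < q_threshold` and
#' `log2fc >= fc_threshold`. The `unmatched` row is excluded from testing
#' and from the totals.
#'
#' @param table a `count_table`.
#' @param sorted_name,naive_name column names of the sorted and naive
#'   samples (defaults: taken from `table$roles` when available, else
#'   `"sorted"`/`"naive"`).
#' @param pseudocount additive pseudocount for the fold change (default 0.5).
#' @param q_threshold FDR threshold for hit calling (default 0.05).
#' @param fc_threshold minimum log2 fold change for hit calling (default 1).
#' @return data.frame of class `enrichment_result`, ranked by `(q, -log2fc)`:
#'   columns `tile_id`, `count_sorted`, `count_naive`, `total_sorted`,
#'   `total_naive`, `log2fc`, `p_value`, `q_value`, `is_hit`, `rank`.
#' @export
score_enrichment <- function(table, sorted_name = NULL, naive_name = NULL,
                             pseudocount = 0.5, q_threshold = 0.05,
                             fc_threshold = 1.0) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(sorted_name)) {
    sorted_name <- if (!is.null(table$roles)) {
      names(table$roles)[table$roles == "sorted"][1]
    } else "sorted"
  }
  if (is.null(naive_name)) {
    naive_name <- if (!is.null(table$roles)) {
      names(table$roles)[table$roles == "naive"][1]
    } else "naive"
  }
  cm <- table$counts
  stopifnot(sorted_name %in% colnames(cm), naive_name %in% colnames(cm))
  keep <- rownames(cm) != "unmatched"
  cs <- cm[keep, sorted_name]
  cn <- cm[keep, naive_name]
  Ns <- sum(cs)
  Nn <- sum(cn)
  if (Ns == 0L || Nn == 0L) {
    stop("zero matched reads in one of the pools", call. = FALSE)
  }

  log2fc <- log2(((cs + pseudocount) / (Ns + 2 * pseudocount)) /
                 ((cn + pseudocount) / (Nn + 2 * pseudocount)))
  p <- fisher_p_enrichment(cs, cn, Ns, Nn)
  q <- p.adjust(p, method = "BH")
  hit <- q < q_threshold & log2fc >= fc_threshold

  out <- data.frame(
    tile_id = rownames(cm)[keep],
    count_sorted = as.integer(cs), count_naive = as.integer(cn),
    total_sorted = as.integer(Ns), total_naive = as.integer(Nn),
    log2fc = log2fc, p_value = p, q_value = q, is_hit = hit,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q_value, -out$log2fc, out$p_value, out$tile_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' One-sided Fisher exact p for enrichment in the sorted pool
#'
#' Exact upper-tail hypergeometric probability
#' \eqn{P(X \ge c_s)} for \eqn{X \sim} Hypergeom(draws = \eqn{N_s},
#' successes = \eqn{c_s + c_n}, total = \eqn{N_s + N_n}) — identical to
#' `fisher.test(..., alternative = "greater")` on the 2x2 table.
#' Vectorized over tiles.
#'
#' @param cs,cn per-tile counts in the sorted and naive pools.
#' @param Ns,Nn pool totals.
#' @return numeric vector of p-values in (0, 1].
#' @export
fisher_p_enrichment <- function(cs, cn, Ns, Nn) {
  phyper(cs - 1, m = cs + cn, n = Ns + Nn - cs - cn, k = Ns,
         lower.tail = FALSE)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d tiles tested, %d hit(s) (q < threshold & log2fc filter)\n",
              nrow(x), sum(x$is_hit)))
  print.data.frame(head(x, 5))
  invisible(x)
}

#' Write deconvolution outputs
#'
#' Writes `counts.csv` (tile x sample), `enrichment.csv`, and a plain-text
#' `qc.txt` report into `dir`.
#'
#' @param table a `count_table`.
#' @param enrichment an `enrichment_result` (optional).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_deconvolution <- function(table, enrichment = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"))
  df <- data.frame(tile_id = rownames(table$counts), table$counts,
                   row.names = NULL, check.names = FALSE)
  con <- file(paths[["counts"]], open = "wb")
  write.csv(df, con, row.names = FALSE)
  close(con)
  if (!is.null(enrichment)) {
    paths[["enrichment"]] <- file.path(dir, "enrichment.csv")
    con <- file(paths[["enrichment"]], open = "wb")
    write.csv(as.data.frame(enrichment), con, row.names = FALSE)
    close(con)
  }
  if (!is.null(table$qc)) {
    paths[["qc"]] <- file.path(dir, "qc.txt")
    lines <- c("Deconvolution QC", "================",
               utils::capture.output(print(table$qc, row.names = FALSE)))
    writeLines(lines, paths[["qc"]])
  }
  invisible(paths)
}
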