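# Oligo design: reverse-translate peptide tiles into DNA, scrub the
# restriction sites used for vector cloning, and add Gibson assembly arms.

# Human codon-usage fractions (standard nuclear usage, per amino acid).
HUMAN_CODON_USAGE <- local({
  txt <- c(
    "A GCT 0.27", "A GCC 0.40", "A GCA 0.23", "A GCG 0.11",
    "R CGT 0.08", "R CGC 0.18", "R CGA 0.11", "R CGG 0.20", "R AGA 0.21", "R AGG 0.21",
    "N AAT 0.47", "N AAC 0.53",
    "D GAT 0.46", "D GAC 0.54",
    "C TGT 0.46", "C TGC 0.54",
    "Q CAA 0.27", "Q CAG 0.73",
    "E GAA 0.42", "E GAG 0.58",
    "G GGT 0.16", "G GGC 0.34", "G GGA 0.25", "G GGG 0.25",
    "H CAT 0.42", "H CAC 0.58",
    "I ATT 0.36", "I ATC 0.47", "I ATA 0.17",
    "L TTA 0.08", "L TTG 0.13", "L CTT 0.13", "L CTC 0.20", "L CTA 0.07", "L CTG 0.40",
    "K AAA 0.43", "K AAG 0.57",
    "M ATG 1.00",
    "F TTT 0.46", "F TTC 0.54",
    "P CCT 0.29", "P CCC 0.32", "P CCA 0.28", "P CCG 0.11",
    "S TCT 0.19", "S TCC 0.22", "S TCA 0.15", "S TCG 0.05", "S AGT 0.15", "S AGC 0.24",
    "T ACT 0.25", "T ACC 0.36", "T ACA 0.28", "T ACG 0.11",
    "W TGG 1.00",
    "Y TAT 0.44", "Y TAC 0.56",
    "V GTT 0.18", "V GTC 0.24", "V GTA 0.12", "V GTG 0.46"
  )
  parts <- do.call(rbind, strsplit(txt, " ", fixed = TRUE))
  data.frame(aa = parts[, 1], codon = parts[, 2],
             weight = as.numeric(parts[, 3]), stringsAsFactors = FALSE)
})

#' Codon table with usage weights
#'
#' A weighted codon table used for reverse translation. Weights are
#' normalized to sum to 1 within each amino acid, and every codon is
#' checked against the standard genetic code. The default is human
#' codon-usage frequencies; any table with the same columns can be
#' supplied (e.g. for a different expression host).
#'
#' @param usage data.frame with columns `aa` (one-letter amino acid),
#'   `codon` (DNA, 3 nt), `weight` (non-negative; normalized per aa).
#' @return an object of class `codon_table`: list of per-amino-acid
#'   data.frames, codons ordered by decreasing weight then alphabetically
#'   (a fixed order that downstream scrubbing relies on for determinism).
#' @examples
#' tab <- codon_table()
#' tab$codons[["W"]]
#' @export
codon_table <- function(usage = HUMAN_CODON_USAGE) {
  stopifnot(is.data.frame(usage),
            all(c("aa", "codon", "weight") %in% names(usage)))
  gc <- Biostrings::GENETIC_CODE
  back <- gc[usage$codon]
  if (any(is.na(back)) || !all(back == usage$aa)) {
    bad <- usage$codon[is.na(back) | back != usage$aa][1]
    stop(sprintf("codon '%s' does not translate to its stated amino acid", bad),
         call. = FALSE)
  }
  missing <- setdiff(AA_STANDARD, unique(usage$aa))
  if (length(missing) > 0) {
    stop(sprintf("codon table lacks amino acid(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  codons <- lapply(split(usage, usage$aa), function(d) {
    d <- d[order(-d$weight, d$codon), , drop = FALSE]
    d$weight <- d$weight / sum(d$weight)
    rownames(d) <- NULL
    d
  })
  structure(list(codons = codons), class = "codon_table")
}

#' Cloning configuration
#'
#' Assembly arms and forbidden restriction motifs for oligo design. The
#' default forbidden motifs are the BsrGI (`TGTACA`) and PstI (`CTGCAG`)
#' recognition sites used to open the destination vector; both are
#' scanned on both strands. Default arms are the constant regions carried
#' by the screen's amplification adapters immediately flanking the insert.
#'
#' @param five_prime_arm,three_prime_arm nucleotide strings prepended /
#'   appended to each coding sequence. Must not themselves contain a
#'   forbidden motif (checked here).
#' @param forbidden_motifs DNA motifs that must not occur anywhere in an
#'   emitted oligo, on either strand.
#' @param seed base RNG seed for codon sampling.
#' @param max_scrub_attempts per-oligo cap on scrubbing iterations before
#'   giving up with an error.
#' @return an object of class `cloning_config`.
#' @export
cloning_config <- function(five_prime_arm = "GCTTACCGTAACTTGAA",
                           three_prime_arm = "GACCTCGAGACAAATGGCAGTATTCATCC",
                           forbidden_motifs = c(BsrGI = "TGTACA", PstI = "CTGCAG"),
                           seed = 1L,
                           max_scrub_attempts = 100L) {
  five_prime_arm <- toupper(five_prime_arm)
  three_prime_arm <- toupper(three_prime_arm)
  forbidden_motifs <- toupper(forbidden_motifs)
  for (arm in c(five_prime_arm, three_prime_arm)) {
    if (nzchar(arm) && nrow(find_forbidden(arm, forbidden_motifs)) > 0) {
      stop("assembly arm contains a forbidden motif", call. = FALSE)
    }
  }
  structure(list(
    five_prime_arm = five_prime_arm,
    three_prime_arm = three_prime_arm,
    forbidden_motifs = forbidden_motifs,
    seed = stopifnot_scalar_int(seed, "seed"),
    max_scrub_attempts = stopifnot_scalar_int(max_scrub_attempts,
                                              "max_scrub_attempts", min = 1L)
  ), class = "cloning_config")
}

#' Reverse-translate a peptide
#'
#' Draws one codon per residue, weighted by the table's usage frequencies.
#' Weighted sampling (rather than always the top codon) avoids long exact
#' nucleotide repeats across overlapping tiles, which synthesis vendors
#' reject; a fixed seed keeps the draw deterministic.
#'
#' @param peptide amino-acid string (standard residues only).
#' @param table a [codon_table()].
#' @param seed RNG seed (or `NULL` to use the current stream).
#' @return nucleotide string of length `3 * nchar(peptide)`; translating
#'   it recovers `peptide` exactly.
#' @examples
#' reverse_translate("MW", seed = 1)  # forced: single-codon residues
#' @export
reverse_translate <- function(peptide, table = codon_table(), seed = NULL) {
  stopifnot(inherits(table, "codon_table"))
  peptide <- toupper(peptide)
  res <- strsplit(peptide, "")[[1]]
  bad <- which(!(res %in% AA_STANDARD))
  if (length(bad) > 0) {
    stop(sprintf("non-standard residue '%s' at position %d", res[bad[1]], bad[1]),
         call. = FALSE)
  }
  with_seed(seed, {
    codons <- vapply(res, function(a) {
      d <- table$codons[[a]]
      if (nrow(d) == 1L) d$codon else sample(d$codon, 1L, prob = d$weight)
    }, character(1))
    paste(codons, collapse = "")
  })
}

#' Translate a coding sequence
#'
#' @param cds nucleotide string(s), length divisible by 3.
#' @return amino-acid string(s).
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     no.init.codon = TRUE))
}

# Synonymous alternatives for a codon, in the table's deterministic order,
# excluding the codon itself.
synonymous_codons <- function(codon, table) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  alts <- table$codons[[aa]]$codon
  alts[alts != codon]
}

#' Remove forbidden motifs from a coding sequence by synonymous edits
#'
#' Greedy left-to-right scrubbing: the leftmost forbidden-motif occurrence
#' (either strand, including windows spanning the arm/insert junctions
#' when arms are supplied) is removed by an exhaustive local search over
#' synonymous replacements of the codons overlapping it — single-codon
#' edits first, then pairs — accepting the first replacement, in the
#' table's fixed codon order, that clears the occurrence without creating
#' a new one at the edited position. Deterministic; the translation is
#' unchanged.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @param config a [cloning_config()]; its arms define the junction
#'   context scanned (pass arms as `""` via a custom config to scrub the
#'   insert alone).
#' @param table a [codon_table()].
#' @return the scrubbed cds with attribute `"scrub_edits"` (number of
#'   codon substitutions applied; 0 when the input was already clean).
#' @examples
#' cfg <- cloning_config(five_prime_arm = "", three_prime_arm = "")
#' scrub_forbidden_sites("TGTACA", cfg)  # Cys-Thr, BsrGI site removed
#' @export
scrub_forbidden_sites <- function(cds, config = cloning_config(),
                                  table = codon_table()) {
  stopifnot(inherits(config, "cloning_config"), inherits(table, "codon_table"))
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("cds length must be divisible by 3", call. = FALSE)
  }
  arm5 <- config$five_prime_arm
  arm3 <- config$three_prime_arm
  offset <- nchar(arm5)
  edits <- 0L

  for (attempt in seq_len(config$max_scrub_attempts)) {
    full <- paste0(arm5, cds, arm3)
    hits <- find_forbidden(full, config$forbidden_motifs)
    if (nrow(hits) == 0L) {
      attr(cds, "scrub_edits") <- edits
      return(cds)
    }
    hit <- hits[1, ]
    # codons of the cds overlapped by this occurrence (1-based cds coords)
    cs <- hit$start - offset
    ce <- hit$end - offset
    codon_idx <- unique(pmax(1L, pmin(
      nchar(cds) %/% 3L,
      ((max(cs, 1L) - 1L) %/% 3L + 1L):((min(ce, nchar(cds)) - 1L) %/% 3L + 1L)
    )))
    if (ce < 1L || cs > nchar(cds)) {
      stop(sprintf("forbidden motif %s at %d-%d lies entirely in an assembly arm; cannot scrub",
                   hit$motif, hit$start, hit$end), call. = FALSE)
    }

    replacement <- find_scrub_replacement(cds, codon_idx, hit, offset,
                                          arm5, arm3, table, config)
    if (is.null(replacement)) {
      stop(sprintf("no synonymous assignment removes forbidden motif %s at window %d-%d",
                   hit$motif, hit$start, hit$end), call. = FALSE)
    }
    cds <- replacement$cds
    edits <- edits + replacement$n_edits
  }
  stop(sprintf("scrubbing did not converge within %d attempts",
               config$max_scrub_attempts), call. = FALSE)
}

# Exhaustive local search over synonymous replacements of `codon_idx`
# (singles, then pairs) clearing the current hit. Accepts the first
# candidate whose local neighbourhood is free of forbidden motifs.
find_scrub_replacement <- function(cds, codon_idx, hit, offset, arm5, arm3,
                                   table, config) {
  set_codon <- function(s, i, codon) {
    substr(s, 3L * i - 2L, 3L * i) <- codon
    s
  }
  # accept a candidate iff the leftmost forbidden occurrence moves strictly
  # right of the current hit: the edit cleared this occurrence without
  # re-creating one at or before it, and the outer left-to-right loop makes
  # progress on whatever remains
  clears <- function(cand) {
    h2 <- find_forbidden(paste0(arm5, cand, arm3), config$forbidden_motifs)
    nrow(h2) == 0L || min(h2$start) > hit$start
  }
  for (i in codon_idx) {
    from <- substr(cds, 3L * i - 2L, 3L * i)
    for (alt in synonymous_codons(from, table)) {
      cand <- set_codon(cds, i, alt)
      if (clears(cand)) return(list(cds = cand, n_edits = 1L))
    }
  }
  if (length(codon_idx) >= 2L) {
    pairs <- utils::combn(codon_idx, 2L)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      from_i <- substr(cds, 3L * i - 2L, 3L * i)
      from_j <- substr(cds, 3L * j - 2L, 3L * j)
      for (ai in synonymous_codons(from_i, table)) {
        for (aj in synonymous_codons(from_j, table)) {
          cand <- set_codon(set_codon(cds, i, ai), j, aj)
          if (clears(cand)) return(list(cds = cand, n_edits = 2L))
        }
      }
    }
  }
  NULL
}

#' Assemble the full clonable oligo for one coding sequence
#'
#' Concatenates arm + cds + arm, re-scans the junctions (a clean cds can
#' still form a forbidden site where it meets an arm), and scrubs if
#' needed.
#'
#' @param cds nucleotide string (ideally pre-scrubbed; junction-induced
#'   motifs are scrubbed here).
#' @param config a [cloning_config()].
#' @param table a [codon_table()] (for junction scrubbing).
#' @param tile_id optional identifier carried through to the result.
#' @return an object of class `oligo_design`: list with `tile_id`, `cds`,
#'   `oligo`, `scrub_edits`.
#' @export
assemble_oligo <- function(cds, config = cloning_config(),
                           table = codon_table(), tile_id = NA_character_) {
  prior <- attr(cds, "scrub_edits")
  if (is.null(prior)) prior <- 0L
  cds <- scrub_forbidden_sites(as.character(cds), config, table)
  edits <- prior + attr(cds, "scrub_edits")
  oligo <- paste0(config$five_prime_arm, as.character(cds),
                  config$three_prime_arm)
  stopifnot(nrow(find_forbidden(oligo, config$forbidden_motifs)) == 0L)
  structure(list(tile_id = tile_id, cds = as.character(cds), oligo = oligo,
                 scrub_edits = edits),
            class = "oligo_design")
}

#' Design the oligo pool for a tile library
#'
#' Reverse-translates every tile (per-tile seeds derived from
#' `config$seed`, so the pool is reproducible and insensitive to library
#' order changes elsewhere), scrubs forbidden motifs, and assembles the
#' full oligos.
#'
#' @param library a `tile_library`.
#' @param config a [cloning_config()].
#' @param table a [codon_table()].
#' @return an object of class `oligo_pool`: list with `oligos` (data.frame:
#'   `tile_id`, `peptide`, `cds`, `oligo`, `scrub_edits`) and `config`.
#' @export
design_oligos <- function(library, config = cloning_config(),
                          table = codon_table()) {
  stopifnot(inherits(library, "tile_library"))
  tiles <- library$tiles
  rows <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    cds <- reverse_translate(tiles$sequence[i], table,
                             seed = config$seed + i)
    od <- assemble_oligo(scrub_forbidden_sites(cds, config, table),
                         config, table, tile_id = tiles$tile_id[i])
    rows[[i]] <- data.frame(tile_id = od$tile_id,
                            peptide = tiles$sequence[i],
                            cds = od$cds, oligo = od$oligo,
                            scrub_edits = od$scrub_edits,
                            stringsAsFactors = FALSE)
  }
  oligos <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(oligos)) {
    oligos <- data.frame(tile_id = character(0), peptide = character(0),
                         cds = character(0), oligo = character(0),
                         scrub_edits = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(oligos = oligos, config = config), class = "oligo_pool")
}

#' @export
print.oligo_pool <- function(x, ...) {
  cat(sprintf("Oligo pool: %d oligo(s), %d with synonymous scrub edits\n",
              nrow(x$oligos), sum(x$oligos$scrub_edits > 0)))
  invisible(x)
}

#' Write an oligo pool to disk
#'
#' Writes `oligos.fasta` (full oligos) and `oligos.csv` into `dir`;
#' byte-deterministic for identical inputs.
#'
#' @param pool an `oligo_pool`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_oligos <- function(pool, dir) {
  stopifnot(inherits(pool, "oligo_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "oligos.fasta")
  csv <- file.path(dir, "oligos.csv")
  dna <- Biostrings::DNAStringSet(setNames(pool$oligos$oligo,
                                           pool$oligos$tile_id))
  Biostrings::writeXStringSet(dna, fa)
  con <- file(csv, open = "wb")
  on.exit(close(con), add = TRUE)
  write.csv(pool$oligos, con, row.names = FALSE)
  invisible(c(fasta = fa, csv = csv))
}
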