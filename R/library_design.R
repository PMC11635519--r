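# Library design: slice a proteome into fixed-length overlapping peptide
# tiles. Coordinates are 1-based inclusive residue positions throughout.

#' Tiling parameters
#'
#' Parameters controlling how proteins are sliced into peptide tiles.
#' Defaults are the platform's design values: 32-residue tiles with a
#' 14-residue overlap between neighbours, giving an 18-residue step and a
#' guarantee that every epitope of up to 15 residues appears intact on at
#' least one tile.
#'
#' @param tile_length tile length in residues (default 32).
#' @param overlap overlap between consecutive tiles, residues (default 14);
#'   must satisfy `0 <= overlap < tile_length`.
#' @param short_protein_policy what to do with proteins shorter than
#'   `tile_length`: `"skip"` (default; counted in QC) or
#'   `"emit_full_length"` (one tile spanning the whole protein).
#' @param dedupe collapse tiles with identical peptide sequence into a
#'   single library member with merged provenance (default `TRUE`).
#' @return an object of class `tile_params`; `step` is derived as
#'   `tile_length - overlap`.
#' @examples
#' tile_params()
#' tile_params(tile_length = 20, overlap = 5)
#' @export
tile_params <- function(tile_length = 32L, overlap = 14L,
                        short_protein_policy = c("skip", "emit_full_length"),
                        dedupe = TRUE) {
  tile_length <- stopifnot_scalar_int(tile_length, "tile_length", min = 1L)
  overlap <- stopifnot_scalar_int(overlap, "overlap", min = 0L)
  if (overlap >= tile_length) {
    stop("'overlap' must be strictly less than 'tile_length'", call. = FALSE)
  }
  structure(
    list(tile_length = tile_length, overlap = overlap,
         step = tile_length - overlap,
         short_protein_policy = match.arg(short_protein_policy),
         dedupe = isTRUE(dedupe)),
    class = "tile_params"
  )
}

#' @export
print.tile_params <- function(x, ...) {
  cat(sprintf(
    "Tile parameters: length %d aa, overlap %d aa (step %d), %s short proteins, dedupe=%s\n",
    x$tile_length, x$overlap, x$step, x$short_protein_policy, x$dedupe))
  invisible(x)
}

#' Protein record
#'
#' A single input protein: unique accession, amino-acid sequence, optional
#' free-text description.
#'
#' @param id accession string, unique within a proteome.
#' @param sequence amino-acid sequence (non-empty). Residues outside the 20
#'   standard letters are tolerated here and handled at tiling time.
#' @param description free text.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a non-empty string", call. = FALSE)
  }
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop(sprintf("protein '%s': sequence must be non-empty", id), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, description = description),
            class = "protein_record")
}

# Normalize the accepted proteome representations (AAStringSet, named
# character vector, list of protein_record) to a list of protein_record.
as_proteome <- function(proteome) {
  if (inherits(proteome, "AAStringSet")) {
    ids <- names(proteome)
    if (is.null(ids)) stop("proteome AAStringSet must be named", call. = FALSE)
    seqs <- as.character(proteome)
    return(Map(protein_record, ids, seqs))
  }
  if (is.character(proteome)) {
    ids <- names(proteome)
    if (is.null(ids)) stop("proteome character vector must be named", call. = FALSE)
    return(Map(protein_record, ids, proteome))
  }
  if (is.list(proteome)) {
    if (all(vapply(proteome, inherits, logical(1), "protein_record"))) {
      return(proteome)
    }
  }
  stop("unsupported proteome representation", call. = FALSE)
}

# Window start positions for a protein of length n: the regular grid
# 1, 1+step, ... plus, when the last regular window stops short of the
# C-terminus, one extra window anchored to end exactly there. Returns a
# list(starts, anchored) where anchored flags the extra window.
tile_starts <- function(n, tile_length, step) {
  if (n < tile_length) return(list(starts = integer(0), anchored = logical(0)))
  starts <- seq.int(1L, n - tile_length + 1L, by = step)
  anchored <- rep(FALSE, length(starts))
  if (starts[length(starts)] + tile_length - 1L < n) {
    starts <- c(starts, n - tile_length + 1L)
    anchored <- c(anchored, TRUE)
  }
  list(starts = as.integer(starts), anchored = anchored)
}

#' Slice one protein into peptide tiles
#'
#' Emits fixed-length windows starting at 1, 1 + step, 1 + 2*step, ...;
#' if the last regular window does not reach the C-terminus, one extra
#' window anchored to end exactly at the C-terminus is added (flagged
#' `is_terminal_anchor`), so every residue of a protein at least as long
#' as a tile is covered. Tiles containing non-standard residues (X, U, B,
#' Z, ...) cannot be synthesized and are dropped; the count of dropped
#' tiles is attached as attribute `"qc"`.
#'
#' @param protein a [protein_record()] (or anything `protein_record()`
#'   accepts via a named length-1 character vector).
#' @param params a [tile_params()] object.
#' @return a data.frame with columns `parent_id`, `start`, `end`,
#'   `sequence`, `is_terminal_anchor` (one row per tile, in coordinate
#'   order), with attribute `qc = list(dropped_nonstandard, skipped_short)`.
#' @examples
#' p <- protein_record("P1", strrep("ACDEFGHIKL", 10))
#' tile_protein(p, tile_params())
#' @export
tile_protein <- function(protein, params = tile_params()) {
  if (!inherits(protein, "protein_record")) {
    if (is.character(protein) && length(protein) == 1L && !is.null(names(protein))) {
      protein <- protein_record(names(protein), protein)
    } else {
      stop("'protein' must be a protein_record", call. = FALSE)
    }
  }
  stopifnot(inherits(params, "tile_params"))
  n <- nchar(protein$sequence)
  qc <- list(dropped_nonstandard = 0L, skipped_short = 0L)

  if (n < params$tile_length) {
    if (params$short_protein_policy == "skip") {
      qc$skipped_short <- 1L
      out <- empty_tiles(protein$id)
      attr(out, "qc") <- qc
      return(out)
    }
    starts <- 1L
    ends <- n
    anchored <- FALSE
  } else {
    ts <- tile_starts(n, params$tile_length, params$step)
    starts <- ts$starts
    ends <- starts + params$tile_length - 1L
    anchored <- ts$anchored
  }

  seqs <- substring(protein$sequence, starts, ends)
  ok <- !grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), seqs)
  qc$dropped_nonstandard <- sum(!ok)

  out <- data.frame(
    parent_id = rep(protein$id, sum(ok)),
    start = starts[ok], end = ends[ok], sequence = seqs[ok],
    is_terminal_anchor = anchored[ok],
    stringsAsFactors = FALSE
  )
  attr(out, "qc") <- qc
  out
}

empty_tiles <- function(id = character(0)) {
  data.frame(parent_id = character(0), start = integer(0), end = integer(0),
             sequence = character(0), is_terminal_anchor = logical(0),
             stringsAsFactors = FALSE)
}

#' Build a tile library from a proteome
#'
#' Applies [tile_protein()] to every protein, in proteome order, and
#' optionally collapses duplicate peptide sequences into one library member
#' whose `provenance` records every `(parent, start)` it arose from. Output
#' order is deterministic: proteome order, then start position; with
#' deduplication the first occurrence is the representative.
#'
#' @param proteome a named `AAStringSet`, a named character vector, or a
#'   list of [protein_record()]s; ids must be unique.
#' @param params a [tile_params()] object.
#' @return an object of class `tile_library`: a list with `tiles` (a
#'   data.frame with `tile_id`, `parent_id`, `start`, `end`, `sequence`,
#'   `is_terminal_anchor`, `provenance`), `params`, and `qc` counts.
#' @examples
#' prot <- c(P1 = strrep("MKTAYIAKQR", 10), P2 = strrep("GDSLAVVLQR", 8))
#' lib <- tile_proteome(prot, tile_params())
#' lib
#' @export
tile_proteome <- function(proteome, params = tile_params()) {
  proteome <- as_proteome(proteome)
  ids <- vapply(proteome, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate protein id '%s' in proteome", dup), call. = FALSE)
  }

  per <- lapply(proteome, tile_protein, params = params)
  qcs <- lapply(per, attr, "qc")
  qc <- list(
    n_proteins = length(proteome),
    dropped_nonstandard = sum(vapply(qcs, `[[`, integer(1), "dropped_nonstandard")),
    skipped_short = sum(vapply(qcs, `[[`, integer(1), "skipped_short"))
  )
  if (qc$skipped_short > 0L) {
    message(sprintf("%d protein(s) shorter than %d aa skipped (policy 'skip')",
                    qc$skipped_short, params$tile_length))
  }

  tiles <- if (length(per) > 0L) {
    do.call(rbind, c(per, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(tiles) || nrow(tiles) == 0L) {
    tiles <- empty_tiles()
  }
  tiles$provenance <- sprintf("%s:%d", tiles$parent_id, tiles$start)
  if (params$dedupe && nrow(tiles) > 0L) {
    first <- !duplicated(tiles$sequence)
    prov <- tapply(tiles$provenance, factor(tiles$sequence, levels = tiles$sequence[first]),
                   paste, collapse = ";")
    tiles <- tiles[first, , drop = FALSE]
    tiles$provenance <- as.character(prov[tiles$sequence])
    rownames(tiles) <- NULL
  }
  tiles <- cbind(
    tile_id = sprintf("%s|%d-%d", tiles$parent_id, tiles$start, tiles$end),
    tiles
  )
  qc$n_tiles <- nrow(tiles)

  structure(list(tiles = tiles, params = params, qc = qc),
            class = "tile_library")
}

#' @export
print.tile_library <- function(x, ...) {
  cat(sprintf("Tile library: %d tiles from %d protein(s) (L=%d, overlap=%d)\n",
              nrow(x$tiles), x$qc$n_proteins, x$params$tile_length,
              x$params$overlap))
  if (x$qc$dropped_nonstandard > 0 || x$qc$skipped_short > 0) {
    cat(sprintf("  QC: %d tile(s) dropped (non-standard residues), %d short protein(s) skipped\n",
                x$qc$dropped_nonstandard, x$qc$skipped_short))
  }
  if (nrow(x$tiles) > 0) print(head(x$tiles, 4))
  invisible(x)
}

#' Look up tiles by peptide sequence
#'
#' @param library a `tile_library`.
#' @return a named character vector mapping peptide sequence to `tile_id`,
#'   covering every tile in the library.
#' @export
library_index <- function(library) {
  stopifnot(inherits(library, "tile_library"))
  setNames(library$tiles$tile_id, library$tiles$sequence)
}

#' Coverage report for a tile library
#'
#' Per-residue coverage statistics of the library over its source proteome:
#' depth histogram, fraction of residues covered, and the guaranteed
#' epitope length — the largest `k` such that every k-mer of every source
#' protein (of length >= tile length) is fully contained in at least one
#' tile, which equals `overlap + 1` for this tiling scheme.
#'
#' @param library a `tile_library` built from `proteome`.
#' @param proteome the proteome the library was built from (same
#'   representations as [tile_proteome()]).
#' @return an object of class `coverage_stats`: list with `per_protein`
#'   (data.frame: `parent_id`, `length`, `fraction_covered`, `min_depth`,
#'   `max_depth`), `depth_histogram` (residue counts by depth, depth 0 =
#'   uncovered), `fraction_covered` overall, and
#'   `guaranteed_epitope_length`.
#' @export
coverage_report <- function(library, proteome) {
  stopifnot(inherits(library, "tile_library"))
  proteome <- as_proteome(proteome)
  ids <- vapply(proteome, `[[`, character(1), "id")
  seqs <- setNames(vapply(proteome, `[[`, character(1), "sequence"), ids)

  tiles <- library$tiles
  unknown <- setdiff(tiles$parent_id, ids)
  if (length(unknown) > 0) {
    stop(sprintf("library/proteome mismatch: parent '%s' not in proteome",
                 unknown[1]), call. = FALSE)
  }
  # Tiles must be substrings of their named parent at the stated coordinates;
  # provenance entries cover deduplicated copies on other parents.
  claimed <- substring(seqs[tiles$parent_id], tiles$start, tiles$end)
  if (!all(claimed == tiles$sequence)) {
    bad <- which(claimed != tiles$sequence)[1]
    stop(sprintf("library/proteome mismatch: tile '%s' does not match parent sequence",
                 tiles$tile_id[bad]), call. = FALSE)
  }

  # Depth per residue, counting every provenance placement (deduplicated
  # tiles still cover the residues of all their source positions).
  prov <- strsplit(tiles$provenance, ";", fixed = TRUE)
  widths <- tiles$end - tiles$start + 1L
  placements <- data.frame(
    parent = sub(":[0-9]+$", "", unlist(prov)),
    start = as.integer(sub("^.*:", "", unlist(prov))),
    width = rep(widths, lengths(prov)),
    stringsAsFactors = FALSE
  )

  per <- lapply(ids, function(id) {
    n <- nchar(seqs[[id]])
    depth <- integer(n)
    pl <- placements[placements$parent == id, , drop = FALSE]
    if (nrow(pl) > 0) {
      for (j in seq_len(nrow(pl))) {
        idx <- pl$start[j]:(pl$start[j] + pl$width[j] - 1L)
        depth[idx] <- depth[idx] + 1L
      }
    }
    list(depth = depth,
         row = data.frame(parent_id = id, length = n,
                          fraction_covered = mean(depth > 0),
                          min_depth = min(depth), max_depth = max(depth),
                          stringsAsFactors = FALSE))
  })
  all_depths <- unlist(lapply(per, `[[`, "depth"))
  per_protein <- do.call(rbind, lapply(per, `[[`, "row"))
  rownames(per_protein) <- NULL

  structure(list(
    per_protein = per_protein,
    depth_histogram = table(depth = all_depths),
    fraction_covered = mean(all_depths > 0),
    guaranteed_epitope_length = library$params$overlap + 1L
  ), class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("Coverage: %.4f of residues covered; guaranteed epitope length %d aa\n",
              x$fraction_covered, x$guaranteed_epitope_length))
  print(x$depth_histogram)
  invisible(x)
}
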