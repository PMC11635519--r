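# Reading and writing tile libraries. FASTA headers are `parent|start-end`
# with 1-based inclusive residue coordinates; the CSV carries the same
# coordinates plus provenance, with a header comment stating the convention.

#' Read a proteome from multi-FASTA
#'
#' @param path path to a (multi-)FASTA file of amino-acid sequences.
#' @return a named `AAStringSet` (names are the accessions, i.e. the first
#'   whitespace-delimited token of each header).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(aa))) {
    stop("duplicate protein ids in FASTA", call. = FALSE)
  }
  aa
}

#' Write a tile library to disk
#'
#' Writes `library.fasta` (peptides, headers `>parent|start-end`) and
#' `library.csv` (tile_id, parent, start, end, sequence, anchored,
#' provenance; coordinates 1-based inclusive) plus `library_qc.csv` into
#' `dir`. Output is byte-deterministic for identical inputs.
#'
#' @param library a `tile_library`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "tile_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "library.fasta")
  csv <- file.path(dir, "library.csv")
  qc <- file.path(dir, "library_qc.csv")

  aa <- Biostrings::AAStringSet(setNames(library$tiles$sequence,
                                         library$tiles$tile_id))
  Biostrings::writeXStringSet(aa, fa)

  con <- file(csv, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    "# coordinates: 1-based inclusive residue positions on the parent protein",
    sprintf("# tile_length=%d overlap=%d step=%d",
            library$params$tile_length, library$params$overlap,
            library$params$step)
  ), con)
  write.csv(library$tiles, con, row.names = FALSE)

  qcdf <- data.frame(metric = names(library$qc),
                     value = unlist(library$qc), row.names = NULL)
  write.csv(qcdf, qc, row.names = FALSE)
  invisible(c(fasta = fa, csv = csv, qc = qc))
}

#' Read a tile library written by [write_library()]
#'
#' @param dir directory containing `library.csv`.
#' @return a `tile_library` (parameters recovered from the CSV header).
#' @export
read_library <- function(dir) {
  csv <- file.path(dir, "library.csv")
  hdr <- readLines(csv, n = 2L)
  m <- regmatches(hdr[2], regexec("tile_length=(\\d+) overlap=(\\d+)", hdr[2]))[[1]]
  params <- tile_params(tile_length = as.integer(m[2]), overlap = as.integer(m[3]))
  tiles <- read.csv(csv, comment.char = "#", stringsAsFactors = FALSE)
  tiles$is_terminal_anchor <- as.logical(tiles$is_terminal_anchor)
  structure(list(tiles = tiles, params = params,
                 qc = list(n_proteins = NA_integer_,
                           dropped_nonstandard = NA_integer_,
                           skipped_short = NA_integer_,
                           n_tiles = nrow(tiles))),
            class = "tile_library")
}

#' Generate a synthetic proteome
#'
#' Random amino-acid sequences used as a stand-in input proteome for
#' testing and simulation (the screens this package models run on a real
#' secretome FASTA). Residues are drawn i.i.d. from the 20 standard amino
#' acids with uniform frequencies; lengths are drawn uniformly from
#' `length_range`.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer vector of length 2, min and max protein
#'   length in residues.
#' @param seed RNG seed (or `NULL` to use the current stream).
#' @return a named `AAStringSet` with ids `SYNP0001`, `SYNP0002`, ...
#' @examples
#' random_proteome(3, c(40, 60), seed = 1)
#' @export
random_proteome <- function(n_proteins, length_range = c(60L, 600L), seed = NULL) {
  n_proteins <- stopifnot_scalar_int(n_proteins, "n_proteins", min = 1L)
  stopifnot(length(length_range) == 2L, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  with_seed(seed, {
    # sample.int over the range width: sample(x, ...) on a scalar range
    # would silently draw from 1:x
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
                 replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::AAStringSet(setNames(seqs, sprintf("SYNP%04d", seq_len(n_proteins))))
  })
}
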