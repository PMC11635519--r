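# Internal helpers shared across modules.

# The 20 standard amino acids; tiles containing anything else cannot be
# synthesized and are dropped at design time.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed. If
#' `seed` is `NULL` the code runs on the current stream (used by simulators
#' nested inside an outer seeded block).
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Scalar validators: terse on purpose, they guard every public constructor.
stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  }
  if (!is.null(min) && x < min) {
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  }
  as.integer(x)
}

stopifnot_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All (possibly overlapping) start positions of `motif` in `seq`.
# Brute-force substring scan: exact, handles self-overlapping motifs,
# and sequences here are short (one oligo at a time).
find_motif_starts <- function(seq, motif) {
  n <- nchar(seq)
  w <- nchar(motif)
  if (n < w) return(integer(0))
  at <- seq_len(n - w + 1L)
  at[substring(seq, at, at + w - 1L) == motif]
}

# Occurrences of any forbidden motif on either strand, reported in
# forward-strand coordinates as a data.frame(start, end, motif).
find_forbidden <- function(seq, motifs) {
  motifs <- unique(c(motifs, reverse_complement(motifs)))
  hits <- lapply(motifs, function(m) {
    s <- find_motif_starts(seq, m)
    if (length(s) == 0L) return(NULL)
    data.frame(start = s, end = s + nchar(m) - 1L, motif = m,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), stringsAsFactors = FALSE))
  }
  hits[order(hits$start, hits$end), , drop = FALSE]
}
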