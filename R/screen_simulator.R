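# Pooled-screen simulator: lentiviral integration at low MOI, reporter
# driven FACS gating, PCR overdispersion and sequencing errors. Gives the
# deconvolution statistics a ground truth to be tested against.

#' Screen simulation parameters
#'
#' The generative model of a pooled sort-seq screen. Defaults are the
#' platform's operating point: MOI 0.3 (about one integration per infected
#' cell), a strongly activating reporter (90% GFP-positive for cells
#' carrying an activator tile, 1% background), mild PCR overdispersion,
#' 150 bp single-end reads at a 0.1% substitution error rate.
#'
#' @param n_cells number of cells exposed to virus.
#' @param moi mean lentiviral integrations per cell (Poisson rate; > 0).
#' @param activator_ids tile ids of the planted activators.
#' @param p_gfp_active probability a cell carrying >= 1 activator tile is
#'   GFP-positive.
#' @param p_gfp_background GFP-positive probability otherwise (reporter
#'   leak); must not exceed `p_gfp_active`.
#' @param pcr_dispersion amplification overdispersion: each tile's pool
#'   frequency is multiplied by a mean-1 gamma factor with variance
#'   `pcr_dispersion` (squared CV of per-tile PCR efficiency) before reads
#'   are drawn; 0 = plain multinomial.
#' @param n_reads_per_pool reads sequenced per pool.
#' @param seq_error_rate per-base substitution probability.
#' @param read_length read length in bases (default 150).
#' @param seed RNG seed for the whole simulation.
#' @return an object of class `screen_sim_params`.
#' @export
screen_sim_params <- function(n_cells = 1e5, moi = 0.3,
                              activator_ids = character(0),
                              p_gfp_active = 0.9, p_gfp_background = 0.01,
                              pcr_dispersion = 0.01,
                              n_reads_per_pool = 1e5,
                              seq_error_rate = 0.001,
                              read_length = 150L, seed = 1L) {
  if (moi <= 0) stop("'moi' must be > 0", call. = FALSE)
  p_gfp_active <- stopifnot_prob(p_gfp_active, "p_gfp_active")
  p_gfp_background <- stopifnot_prob(p_gfp_background, "p_gfp_background")
  if (p_gfp_background > p_gfp_active) {
    stop("'p_gfp_background' must not exceed 'p_gfp_active'", call. = FALSE)
  }
  if (pcr_dispersion < 0) stop("'pcr_dispersion' must be >= 0", call. = FALSE)
  seq_error_rate <- stopifnot_prob(seq_error_rate, "seq_error_rate")
  structure(list(
    n_cells = stopifnot_scalar_int(n_cells, "n_cells", min = 1L),
    moi = as.numeric(moi),
    activator_ids = as.character(activator_ids),
    p_gfp_active = p_gfp_active, p_gfp_background = p_gfp_background,
    pcr_dispersion = as.numeric(pcr_dispersion),
    n_reads_per_pool = stopifnot_scalar_int(n_reads_per_pool,
                                            "n_reads_per_pool", min = 1L),
    seq_error_rate = seq_error_rate,
    read_length = stopifnot_scalar_int(read_length, "read_length", min = 1L),
    seed = stopifnot_scalar_int(seed, "seed")
  ), class = "screen_sim_params")
}

#' Simulate lentiviral integration
#'
#' Each cell receives `Poisson(moi)` integrations; tiles are drawn with
#' replacement, uniformly by default or according to `weights` (e.g. a
#' skewed plasmid pool).
#'
#' @param params a [screen_sim_params()].
#' @param library a `tile_library` (non-empty).
#' @param weights optional per-tile abundance weights (recycled over
#'   `library$tiles`); default uniform.
#' @param seed RNG seed (default `params$seed`; `NULL` = current stream).
#' @return an object of class `cell_assignments`: list with `n_cells`,
#'   `integrations` (per-cell counts), and the flat vectors `cell` /
#'   `tile_id` listing every integration event.
#' @export
simulate_integration <- function(params, library, weights = NULL,
                                 seed = params$seed) {
  stopifnot(inherits(params, "screen_sim_params"),
            inherits(library, "tile_library"))
  tids <- library$tiles$tile_id
  if (length(tids) == 0L) stop("library is empty", call. = FALSE)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(tids), all(weights >= 0))
  }
  with_seed(seed, {
    k <- rpois(params$n_cells, params$moi)
    total <- sum(k)
    drawn <- if (is.null(weights)) {
      sample.int(length(tids), total, replace = TRUE)
    } else {
      sample.int(length(tids), total, replace = TRUE, prob = weights)
    }
    structure(list(
      n_cells = params$n_cells,
      integrations = k,
      cell = rep.int(seq_along(k), k),
      tile_id = tids[drawn]
    ), class = "cell_assignments")
  })
}

#' @export
print.cell_assignments <- function(x, ...) {
  cat(sprintf("Cell assignments: %d cells, %d infected (%.3f), %d integration events\n",
              x$n_cells, sum(x$integrations > 0),
              mean(x$integrations > 0), length(x$tile_id)))
  invisible(x)
}

#' Simulate the FACS sort
#'
#' A cell is GFP-positive with probability `p_gfp_active` if any of its
#' integrated tiles is an activator, `p_gfp_background` otherwise
#' (dominant reporter activation). The sorted pool is the multiset of
#' tiles carried by GFP-positive cells; the naive pool is the multiset
#' carried by all infected cells (the pre-sort reference).
#'
#' @param assignments a `cell_assignments` from [simulate_integration()].
#' @param params a [screen_sim_params()].
#' @param seed RNG seed (`NULL` = current stream).
#' @return list with `sorted` and `naive` (character vectors of tile ids,
#'   with multiplicity) and `gfp_positive` (per-cell logical).
#' @export
simulate_sort <- function(assignments, params, seed = NULL) {
  stopifnot(inherits(assignments, "cell_assignments"),
            inherits(params, "screen_sim_params"))
  with_seed(seed, {
    carries <- logical(assignments$n_cells)
    is_act <- assignments$tile_id %in% params$activator_ids
    carries[unique(assignments$cell[is_act])] <- TRUE
    p <- ifelse(carries, params$p_gfp_active, params$p_gfp_background)
    gfp <- runif(assignments$n_cells) < p
    list(sorted = assignments$tile_id[gfp[assignments$cell]],
         naive = assignments$tile_id,
         gfp_positive = gfp)
  })
}

# Overdispersed multinomial read counts: each tile's frequency is jittered
# by a multiplicative gamma amplification factor with mean 1 and variance
# phi (PCR efficiency noise), then reads are drawn multinomially from the
# renormalized frequencies. phi -> 0 recovers the plain multinomial; the
# per-tile coefficient of variation sqrt(phi) does not depend on how many
# tiles share the pool.
overdispersed_counts <- function(pool_counts, n_reads, phi) {
  p <- pool_counts / sum(pool_counts)
  if (phi > 0) {
    g <- rgamma(length(p), shape = 1 / phi, rate = 1 / phi)
    w <- p * g
    if (sum(w) == 0) w <- p
    p <- w / sum(w)
  }
  drop(rmultinom(1L, n_reads, p))
}

#' Simulate sequencing reads for one pool
#'
#' Per-tile read counts are drawn from an overdispersed multinomial over
#' the pool's tile frequencies (gamma amplification noise with variance
#' `pcr_dispersion`); each read is the
#' arm-flanked insert truncated or right-padded (with `A`, emulating
#' read-through into downstream vector sequence) to `read_length`, with
#' i.i.d. substitution errors at `seq_error_rate`.
#'
#' @param pool character vector of tile ids with multiplicity (from
#'   [simulate_sort()]).
#' @param oligo_pool an `oligo_pool` covering every tile in `pool`.
#' @param params a [screen_sim_params()].
#' @param seed RNG seed (`NULL` = current stream).
#' @return list with `reads` (a `DNAStringSet`) and `true_counts`
#'   (data.frame `tile_id`, `pool_count`, `read_count`).
#' @export
simulate_reads <- function(pool, oligo_pool, params, seed = NULL) {
  stopifnot(inherits(oligo_pool, "oligo_pool"),
            inherits(params, "screen_sim_params"))
  if (length(pool) == 0L) stop("pool is empty", call. = FALSE)
  ol <- oligo_pool$oligos
  missing <- setdiff(unique(pool), ol$tile_id)
  if (length(missing) > 0) {
    stop(sprintf("no oligo design for tile '%s'", missing[1]), call. = FALSE)
  }
  insert_offset <- nchar(oligo_pool$config$five_prime_arm)
  insert_len <- nchar(ol$cds[1])
  if (params$read_length < insert_offset + insert_len) {
    stop(sprintf("read_length %d cannot cover the insert (offset %d + %d nt)",
                 params$read_length, insert_offset, insert_len), call. = FALSE)
  }

  with_seed(seed, {
    tab <- table(pool)
    counts <- overdispersed_counts(as.numeric(tab), params$n_reads_per_pool,
                                   params$pcr_dispersion)
    tile_ids <- names(tab)
    templates <- ol$oligo[match(tile_ids, ol$tile_id)]
    templates <- vapply(templates, function(s) {
      if (nchar(s) >= params$read_length) {
        substr(s, 1L, params$read_length)
      } else {
        paste0(s, strrep("A", params$read_length - nchar(s)))
      }
    }, character(1), USE.NAMES = FALSE)

    reads <- rep.int(templates, counts)
    reads <- inject_errors(reads, params$seq_error_rate)
    names(reads) <- sprintf("read%07d %s", seq_along(reads),
                            rep.int(tile_ids, counts))
    list(reads = Biostrings::DNAStringSet(reads),
         true_counts = data.frame(tile_id = tile_ids,
                                  pool_count = as.integer(tab),
                                  read_count = as.integer(counts),
                                  stringsAsFactors = FALSE))
  })
}

# i.i.d. substitutions at rate e; each error substitutes a uniformly drawn
# different base.
inject_errors <- function(reads, e) {
  if (e <= 0 || length(reads) == 0L) return(reads)
  width <- nchar(reads[1])
  n_err <- rbinom(length(reads), width, e)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(width, n_err[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write reads as FASTQ
#'
#' Phred+33 FASTQ with constant quality "I" (Q40); base-call quality
#' modeling is out of scope for this simulator.
#'
#' @param reads a `DNAStringSet`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(rep(strrep("I", if (length(reads)) Biostrings::width(reads)[1] else 0L),
                                     length(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Run the full screen simulation
#'
#' Integration, sort, and sequencing of both pools; writes
#' `sorted.fastq`, `naive.fastq` and a truth table `truth.csv` (tile,
#' pool, pool count, read count, activator flag) into `dir` when given.
#'
#' @param library a `tile_library`.
#' @param oligo_pool an `oligo_pool` for that library.
#' @param params a [screen_sim_params()].
#' @param dir optional output directory for FASTQ + truth CSV.
#' @return list with `pools` (from [simulate_sort()]), `sorted`, `naive`
#'   (each a [simulate_reads()] result), `truth` (combined truth table),
#'   and `paths` (when `dir` was given).
#' @export
simulate_screen <- function(library, oligo_pool, params, dir = NULL) {
  with_seed(params$seed, {
    assign <- simulate_integration(params, library, seed = NULL)
    pools <- simulate_sort(assign, params, seed = NULL)
    sorted <- simulate_reads(pools$sorted, oligo_pool, params, seed = NULL)
    naive <- simulate_reads(pools$naive, oligo_pool, params, seed = NULL)
    truth <- rbind(
      cbind(pool = "sorted", sorted$true_counts),
      cbind(pool = "naive", naive$true_counts)
    )
    truth$is_activator <- truth$tile_id %in% params$activator_ids
    out <- list(pools = pools, sorted = sorted, naive = naive, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(sorted = file.path(dir, "sorted.fastq"),
                 naive = file.path(dir, "naive.fastq"),
                 truth = file.path(dir, "truth.csv"))
      write_fastq(sorted$reads, paths[["sorted"]])
      write_fastq(naive$reads, paths[["naive"]])
      con <- file(paths[["truth"]], open = "wb")
      write.csv(truth, con, row.names = FALSE)
      close(con)
      out$paths <- paths
    }
    out
  })
}
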