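# Independent oracles and small fixtures shared across tests. These stay
# deliberately naive: their value is being obviously correct, not fast.

AA_STANDARD_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Brute-force window enumeration for tiling a protein of length n with
# tile length L and overlap v: walk the start positions one step at a
# time, then append a C-terminal-anchored window if the walk stopped
# short of the end.
oracle_tile_coords <- function(n, L, v) {
  s <- L - v
  if (n < L) {
    return(data.frame(start = integer(0), end = integer(0),
                      anchored = logical(0)))
  }
  starts <- integer(0)
  st <- 1L
  while (st + L - 1L <= n) {
    starts <- c(starts, st)
    st <- st + s
  }
  anchored <- rep(FALSE, length(starts))
  if (starts[length(starts)] + L - 1L < n) {
    starts <- c(starts, n - L + 1L)
    anchored <- c(anchored, TRUE)
  }
  data.frame(start = starts, end = starts + L - 1L, anchored = anchored)
}

# Upper-tail hypergeometric probability P(X >= cs) by direct summation of
# the point masses via log-binomials (independent of stats::phyper and of
# fisher.test).
oracle_hyper_tail <- function(cs, cn, Ns, Nn) {
  m <- cs + cn
  N <- Ns + Nn
  ks <- cs:min(m, Ns)
  ks <- ks[m - ks <= Nn]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(m, ks) + lchoose(N - m, Ns - ks) - lchoose(N, Ns)))
}

# Hamming distance between equal-length strings, by character comparison.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# A small proteome sized to give exactly 10 tiles per protein under the
# default parameters (length 194: ten windows, the last ending on the
# C-terminus, so no anchored tile and no duplicate risk beyond chance).
make_test_library <- function(n_proteins, seed, protein_length = 194L) {
  prot <- random_proteome(n_proteins, c(protein_length, protein_length),
                          seed = seed)
  list(proteome = prot, library = tile_proteome(prot))
}

# All k-mers of a string.
all_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}
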