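# secretile

Computational toolkit for pooled surface-display screens that search a
proteome for peptide activators of G-protein-coupled receptors (GPCRs).

In this screen design, a proteome — typically the human secretome — is
sliced into fixed-length overlapping peptide tiles. Each tile is encoded as
a DNA oligo, cloned into a lentiviral vector, and displayed on the surface
of reporter cells carrying a cAMP response element (CRE) driving GFP. A
peptide that activates the target GPCR raises intracellular cAMP, lights up
the reporter, and its cell is recovered by FACS; deep sequencing of the
sorted and unsorted (naive) pools then reveals which peptides are enriched
among responders. Validated hits are quantified by HTRF cAMP dose-response
assays. `secretile` implements every computational step of that arc, plus a
screen simulator so the statistics are testable end to end on synthetic
data.

## What it computes

**Tiling.** A protein of length $n$ is cut into windows of length $L = 32$
residues starting at $1, 1+s, 1+2s, \dots$ with step $s = L - v$ and
overlap $v = 14$; if the last regular window stops short of the C-terminus
an extra window anchored at the C-terminus is added. Every substring of
length $\le v + 1 = 15$ of any source protein is then guaranteed to appear
intact in at least one tile, so no epitope up to that size is split across
tile boundaries.

**Oligo design.** Tiles are reverse-translated with human codon-usage
weights and scrubbed of the BsrGI (`TGTACA`) and PstI (`CTGCAG`)
recognition sites used to open the destination vector — on both strands,
including across the Gibson-arm junctions — by greedy left-to-right
synonymous substitution.

**Screen model and deconvolution.** Integration counts per cell are
Poisson(MOI), with MOI 0.3 so that most infected cells carry a single
tile; GFP positivity is Bernoulli per cell (activator carriers vs
background); counts acquire PCR overdispersion and reads acquire
substitution errors. Deconvolution trims reads at the constant region,
matches inserts back to the designed library (exact nucleotide, then exact
amino acid, then unique 1-mismatch), and tests each tile's sorted vs naive
counts with the one-sided Fisher exact test

$$p = P(X \ge c_s), \quad X \sim \mathrm{Hypergeom}(N_s + N_n,\; c_s + c_n,\; N_s)$$

with Benjamini–Hochberg FDR control and a pseudocounted
$\log_2$ fold-change ranking.

**Dose-response.** HTRF cAMP curves are fitted with the four-parameter
logistic

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + (\mathrm{EC_{50}}/x)^{h}}$$

by multi-start Levenberg–Marquardt least squares with $\mathrm{EC_{50}}$
parameterized on the log10 scale.

## Worked example

```r
library(secretile)

# 1. design a tile library from a (here: synthetic) proteome
proteome <- random_proteome(20, c(100, 400), seed = 1)
lib <- tile_proteome(proteome)            # 288 tiles of 32 aa, 14 aa overlap

# 2. realize it as clonable oligos
pool <- design_oligos(lib, cloning_config(seed = 7))
#> Oligo pool: 288 oligo(s), 20 with synonymous scrub edits

# 3. simulate a screen with two planted activators
activators <- lib$tiles$tile_id[c(10, 120)]
params <- screen_sim_params(n_cells = 2e4, activator_ids = activators,
                            n_reads_per_pool = 5e4, seed = 42)
sim <- simulate_screen(lib, pool, params, dir = tempfile())

# 4. deconvolve the FASTQ pools and score enrichment
sheet <- data.frame(sample = c("gfp_pos", "presort"),
                    role   = c("sorted", "naive"),
                    path   = c(sim$paths[["sorted"]], sim$paths[["naive"]]))
counts <- count_pools(sheet, lib, pool)
res <- score_enrichment(counts)
head(as.data.frame(res), 3)
#>            tile_id count_sorted count_naive   log2fc       q_value is_hit
#> 1 SYNP0001|163-194         7649         123 5.952145  0.000000e+00   TRUE
#> 2  SYNP0008|73-104         6582         155 5.403012  0.000000e+00   TRUE
#> 3 SYNP0009|145-176         1056         195 2.433415 3.510571e-143   TRUE
```

The two planted activators rank first and second: each drew thousands of
sorted-pool reads against ~150 naive reads, a 5–6 log2-unit enrichment at
essentially zero FDR. (The third row is a passenger tile co-integrated
with activators — visible but clearly separated.)

```r
# 5. fit a dose-response curve for a validated hit
truth <- fourpl_params(bottom = 0, top = 100, ec50 = 260, hill = 1)
doses <- 10^seq(log10(260) - 2, log10(260) + 2, length.out = 8)
curve <- simulate_curve(truth, doses, cv = 0.05, n_replicates = 3, seed = 1)
fit_4pl(curve)
#> 4PL fit (n=24): EC50 = 268.1 (SE 23.1), hill = 0.989, bottom = 0.1766,
#>   top = 101.1, RSS = 246.2
```

A single 24-point curve at 5% noise recovers the generative EC50 of
260 nM within its standard error.

A command-line wrapper with the same steps is installed as
`exec/secretile` (`secretile design|oligos|simulate|deconvolve|ec50`).

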