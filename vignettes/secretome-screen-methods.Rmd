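---
title: "Methods: peptide tiling screens, from library design to EC50"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide tiling screens, from library design to EC50}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretile)
```

This vignette records the models, parameter choices, and numerical
decisions behind `secretile`. It is written for a user who wants to know
*why* the package behaves the way it does, not just what its functions
return.

## The screening platform being modeled

A pooled surface-display screen for GPCR-activating peptides works in five
computational stages, and the package mirrors them one to one:

1. slice a proteome into fixed-length overlapping peptide **tiles**;
2. encode each tile as a clonable **oligo**;
3. (in silico only) **simulate** the pooled lentiviral screen;
4. **deconvolve** sequencing pools into counts and enrichment calls;
5. fit **dose-response** curves to validation data.

## Tiling

`tile_protein()` emits windows of `tile_length` residues starting at
$1, 1+s, 1+2s, \dots$ with step $s = L - v$. Defaults are $L = 32$ and
$v = 14$ ($s = 18$): 32-mers are long enough to carry secondary-structure
elements yet short enough for reliable synthesis, and a 14-residue overlap
guarantees that every epitope of up to $v + 1 = 15$ residues appears
intact in at least one tile, including epitopes spanning a tile boundary.

Design choices that were genuinely open:

* **Final window.** When the last regular window stops short of the
  C-terminus, we emit one extra window *anchored to end exactly at the
  C-terminus* (flagged `is_terminal_anchor`) rather than padding or
  truncating. Synthesis requires a fixed tile length; padding would
  invent residues and truncation would lose C-terminal coverage. The
  anchored pair overlaps by at least $v$, never less.
* **Coordinates** are 1-based inclusive residue positions, the biological
  convention; every output file states this in its header.
* **Short proteins** (length $< L$) are skipped with a QC count by
  default; `short_protein_policy = "emit_full_length"` keeps them as
  single full-length (shorter) tiles for completeness studies.
* **Non-standard residues** (X, U, B, Z, ...) cannot be synthesized, so
  any window containing one is dropped and counted in the QC report —
  the remaining windows of the protein are kept.
* **Deduplication** collapses tiles with identical amino-acid sequence
  (the level at which the displayed library is unique) while recording
  every `(parent, start)` provenance, so coverage accounting still sees
  all source positions.

The published screen this design follows reports a library of 92,918
unique 32-mers over the human secretome; the source proteome is not
distributed, so that count is documentation, not a reproducible quantity.
What the package guarantees instead — and tests exhaustively — is that
tiling is a pure, deterministic function of the input proteome, agrees
with brute-force window enumeration for arbitrary $(n, L, v)$, and
delivers the 15-mer containment guarantee on any input.

## Oligo design

`reverse_translate()` draws one codon per residue, weighted by human
codon-usage frequencies. Weighted sampling — rather than always taking
the most-used codon — is deliberate: neighbouring tiles share 14 of 32
residues, and deterministic max-usage encoding would generate long exact
nucleotide repeats across the pool, which synthesis vendors reject. A
fixed per-tile seed (derived from `cloning_config()$seed`) keeps the pool
reproducible. The codon table is configurable for other expression hosts.

`scrub_forbidden_sites()` removes the restriction sites used to open the
destination vector (BsrGI `TGTACA`, PstI `CTGCAG` by default; both happen
to be palindromic, but both strands are scanned regardless, so
non-palindromic motifs are handled too). The algorithm is greedy
left-to-right: find the leftmost forbidden occurrence — including windows
spanning the arm/insert junctions — then exhaustively try synonymous
replacements of the codons it overlaps, single codons first, then pairs,
in a fixed order (decreasing usage, then alphabetical). A candidate is
accepted when the leftmost remaining occurrence moves strictly rightward,
which guarantees progress and hence termination; `max_scrub_attempts`
caps pathological inputs. Some junctions are genuinely unfixable (an arm
ending `TGTA` against any His or Gln codon, which all begin `CA`), and
the function reports these as errors rather than silently emitting a
cleavable oligo.

The arm sequences flanking the insert in the original screen are not
fully published; `cloning_config()` defaults to the constant regions
carried by its amplification adapters immediately flanking the insert,
and both arms are ordinary configuration.

## Screen simulator

The simulator generates data with the statistical structure the
deconvolution statistics assume, so those statistics can be tested
end to end with a known truth:

* **Integration**: per-cell counts are Poisson(MOI) with MOI 0.3 — the
  screen's operating point, chosen so most infected cells carry one
  integration (the infected fraction is $1 - e^{-0.3} \approx 0.259$ and
  $\approx 86\%$ of infected cells are single-integration; both
  closed-form values are recovered by the simulator within sampling
  error). Tiles are drawn uniformly unless per-tile abundance weights
  are supplied (e.g. to emulate a skewed plasmid pool).
* **Sorting**: GFP positivity is a per-cell Bernoulli —
  `p_gfp_active = 0.9` for cells carrying at least one activator tile
  (dominant reporter activation; the model is silent on multi-integration
  epistasis, so "any activator suffices" is the simplest faithful rule),
  `p_gfp_background = 0.01` otherwise (reporter leak and gate
  imperfection). A binary gate, not a fluorescence intensity model: the
  screen sorts a GFP-positive population, and the downstream statistics
  see only membership.
* **Naive pool**: the tiles of all infected cells (the pre-sort
  population). A plasmid-library reference can be emulated by counting a
  synthetic pool drawn directly from the library with chosen weights.
* **Amplification noise**: each tile's pool frequency is multiplied by an
  independent gamma factor with mean 1 and variance `pcr_dispersion`
  before multinomial read sampling. This makes the per-tile
  overdispersion (CV $=\sqrt{\phi}$, default $\phi = 0.01$, i.e. 10%
  amplification CV) independent of how many tiles share the pool — a
  Dirichlet parameterized as $\alpha_i \propto p_i$ would instead explode
  the noise as libraries grow — and recovers the plain multinomial as
  $\phi \to 0$.
* **Reads**: the arm-flanked insert, truncated or right-padded with `A`
  (emulating read-through into constant downstream sequence) to 150 bases,
  with i.i.d. substitutions at `seq_error_rate` (default $10^{-3}$).
  Quality strings are constant; base-call quality modeling, paired ends
  and index hopping are out of scope.

Everything is bit-reproducible under a fixed seed.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: selection bottlenecks and growth competition
between infection and sorting, position-dependent sequencing error,
chimeric PCR products, cross-well contamination, and any biology in which
display level or peptide folding modulates activation. The simulator
validates the *statistics*, not the biology.

## Deconvolution

`trim_reads()` anchors on the 5' constant region (exact match first, then
up to `max_flank_mismatches = 1` substitutions) and extracts the
following 96 nt. Rejections are data, not errors: every input read is
accounted for as matched or as exactly one of `no-flank`, `too-short`,
`bad-length`, `unmatched` — the QC report and the `unmatched` count-table
row make the accounting exact.

`match_inserts()` uses three tiers, ordered for specificity: exact
nucleotide match against the designed coding sequences; exact amino-acid
match of the translated insert (absorbing synonymous divergence between
the synthesized pool and any re-derived encoding); unique nearest
neighbour within 1 nucleotide mismatch. An ambiguous near-match (two or
more equally close designs) is deliberately discarded rather than
fractionally assigned: deterministic and conservative.

`score_enrichment()` implements the hit-calling computation. The original
platform description never specifies one, so the package's choices follow
standard pooled-screen practice, all exposed as arguments:

* frequency $\log_2$ fold change with pseudocount $a = 0.5$:
  $\log_2 \frac{(c_s + a)/(N_s + 2a)}{(c_n + a)/(N_n + 2a)}$;
* one-sided Fisher exact test for enrichment, computed as the
  hypergeometric upper tail (`phyper`); equivalent to
  `fisher.test(alternative = "greater")` and checked in the tests against
  an independent log-binomial enumeration;
* Benjamini–Hochberg FDR across all tested tiles;
* a tile is a hit when $q < 0.05$ **and** $\log_2\mathrm{FC} \ge 1$; the
  fold-change gate keeps statistically significant but tiny effects (at
  deep coverage) out of the hit list.

"Comparison against the human genome" in the platform description is
implemented as matching reads to the *designed library* — the library
members are the only sequences that can legitimately appear between the
constant regions, and genome alignment would only re-derive them.

The sorted pool is a subset of the cells behind the naive pool, so the
two columns of the 2x2 table are not strictly independent; the effect is
a slightly conservative test, confirmed by the null-calibration test
(equal GFP probabilities, 1,000 tiles), where the $q < 0.05$ fraction
stays at or below its nominal level.

## Dose-response

`htrf_ratio()` follows the HTRF kit convention,
$\mathrm{ratio} = 10^4 \cdot \mathrm{em}_{665}/\mathrm{em}_{620}$; fits
accept raw or normalized responses, since the 4PL EC50 is invariant to
response scaling (a property the tests assert to $10^{-8}$ relative).

`fit_4pl()` minimizes least squares of
$y = b + (t - b) / (1 + 10^{h (\log_{10}\mathrm{EC_{50}} - \log_{10} x)})$.
Numerical choices:

* **EC50 on the log10 scale** — the standard dose-response
  parameterization; it makes the optimization landscape near-quadratic
  and keeps EC50 positive by construction.
* **Multi-start**: asymptotes seeded from the mean responses at the
  extreme doses *in both orientations* (so descending/inhibition curves
  need no special casing), $\log_{10}\mathrm{EC_{50}}$ on a 3-point grid
  over the observed dose range, Hill slope in $\{0.5, 1, 2\}$; the best
  converged start by residual sum of squares wins. Levenberg–Marquardt
  (`minpack.lm::nlsLM`) with tight tolerances (`ftol = ptol = 1e-14`)
  so that equivalent problems converge to identical optima.
* **Bounds**: $\log_{10}\mathrm{EC_{50}}$ is confined to the observed
  dose range widened by 3 decades per side — estimates far outside the
  measured range are extrapolation, not measurement.
* **Degenerate inputs**: constant responses and designs with fewer than
  5 distinct concentrations are refused with explicit errors;
  non-convergence from every start returns `converged = FALSE` rather
  than a fabricated estimate.

`simulate_curve()` applies multiplicative Gaussian noise
($y = \mu (1 + \mathcal{N}(0, cv))$), matching how plate-reader CVs are
usually quoted. `ec50_recovery_study()` wraps the simulate-refit loop;
its default design — 8 doses log-spaced over 4 decades centered on the
generative EC50, 3 replicates per dose, 5% CV, 200 curves — is a
realistic validation-assay layout, and at that design the
$\log_{10}\mathrm{EC_{50}}$ estimator is unbiased to within 0.02 and the
median fitted EC50 falls within 5% of truth at every potency tested
(0.54, 260, 344.9 and 488.2 nM, the potencies reported for GLP-1 and the
three discovered GLP-1R agonist peptides).

## Validation scale

The test suite exercises the pipeline at the sizes the statistics need,
kept modest because they are sufficient: tiling oracle equivalence over
1,000 random parameterizations (protein length up to 500); the epitope
guarantee over a 50-protein synthetic proteome; Poisson statistics at
$10^5$ cells; exact-test agreement over an exhaustive grid of 2x2 tables
with pool totals up to 200; an end-to-end screen of 1,000 tiles with 5
planted activators, $10^5$ cells and $10^5$ reads per pool (all five
activators are required to rank in the top 10 by $q$); and 200-curve
EC50 recovery at each reported potency.

## Known limitations

* Tiling treats the proteome as given; secretome curation (signal-peptide
  prediction, isoform selection) is upstream of this package.
* Oligo design scrubs restriction motifs only; vendor-style synthesis
  scoring (GC windows, homopolymers, hairpins) is not implemented.
* The enrichment model is two-pool (one sorted, one naive); replicate
  sorts and multi-round selection need external aggregation.
* Fisher's exact test conditions on totals and ignores biological
  replicate variance; with replicated screens a count-model framework
  (e.g. negative binomial) would be preferable.
* 4PL fitting reports asymptotic standard errors; profile or bootstrap
  intervals are not implemented.
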