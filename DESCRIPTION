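Package: secretile
Title: Peptide Tiling Libraries and Sort-Seq Deconvolution for GPCR Activator Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled surface-display screens that hunt for peptide
    activators of G-protein-coupled receptors. Covers the full computational
    arc of such a screen: slicing a proteome into fixed-length overlapping
    peptide tiles with coverage guarantees, reverse-translating tiles into
    clonable oligos free of the restriction sites used for vector assembly,
    simulating a pooled lentiviral sort-seq screen (Poisson integration at
    low multiplicity of infection, reporter-driven FACS gating, amplification
    and sequencing noise), deconvolving sorted and naive sequencing pools
    into per-peptide counts with exact-test enrichment calls under FDR
    control, and quantifying validated hits by four-parameter logistic
    EC50 fitting of HTRF cAMP dose-response data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
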