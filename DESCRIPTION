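Package: lactylomics
Title: Protein-Abundance-Corrected Lactylome Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of lysine-lactylation (Kla)
    proteomics data from label-free experiments. Implements sample
    normalization, feature centering and correction of modification-site
    abundance by parent-protein abundance; assumption-gated two-group
    differential testing (Shapiro-Wilk and Brown-Forsythe gates selecting
    Student's or Welch's t-test) with Benjamini-Hochberg false discovery
    rate control and fold-change thresholding; site cataloguing and
    flanking-window extraction; positional amino-acid frequency analysis
    and greedy motif-x style motif search; MCODE molecular-complex
    detection on protein-protein interaction graphs; hypergeometric
    over-representation analysis and preranked gene-set enrichment
    analysis. A synthetic-data generator emulating the statistical
    structure of a cardiac lactylome study (3 vs 3 label-free design,
    heavy-tailed sites-per-protein distribution, spiked site- and
    protein-level fold changes, missing values) supports end-to-end
    testing and power exploration at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    car,
    igraph,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
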