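Package: ptmenrich
Title: Proximity Enrichment of Post-Translational Modifications Near Disease Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses ProteomeScout-like protein annotation flat files and UniProt
    humsavar-style variant index files into an annotated proteome container, and
    tests whether pathogenic missense mutations are enriched within a linear-sequence
    window of post-translational modification (PTM) sites. Implements study-bias
    control (restriction to proteins carrying at least one pathogenic mutation),
    residue-unique counting with OR-collapse of multi-mutation residues, one-sided
    Fisher's exact tests per modification type with Benjamini-Hochberg correction,
    amino-acid composition bias diagnostics, and composition-matched random-foreground
    resampling controls. A synthetic-proteome generator with a tunable
    PTM-pathogenicity co-localization effect provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, Software, StatisticalMethod, SNP
RoxygenNote: 7.3.3
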