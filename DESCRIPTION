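Package: uorfsort
Title: Sort-Seq Analysis of Upstream ORF Coding-Variant Reporter Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel reporter assays of upstream open
    reading frame (uORF) coding variants measured by fluorescence-activated
    sorting and sequencing (sort-seq). Enumerates degenerate (IUPAC) codon
    libraries with paired start-codon-mutant controls, simulates the full
    assay (cell sorting into fluorescence bins, per-bin plasmid DNA
    sequencing, unsorted DNA/RNA sequencing) with planted codon and dicodon
    effects, merges paired-end reads and counts perfect matches to the
    designed references, estimates per-variant reporter expression as the
    cell-count-normalized bin-weighted average of measured fluorescence
    ratios, computes paired AUG/AGG regulatory effects at the protein, RNA
    and translation-efficiency level, tests codon-presence and
    dicodon-order effects with multiple-testing correction, scores variants
    against codon-optimality (nTE) tables, and fits cross-validated lasso
    regressions on codon-identity-by-position indicator encodings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    glmnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
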