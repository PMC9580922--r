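Package: hsdetect
Title: Identification, Annotation and Visualization of Highly Similar
    Duplicated Genes in Eukaryotic Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects highly similar duplicated genes (HSDs) in a eukaryotic
    proteome from an all-vs-all protein similarity search. Parses 12-column
    tabular alignment reports and 13-column InterProScan annotations, filters
    gene pairs by pairwise amino-acid identity, protein length variance and
    E-value, clusters duplicates by transitive linkage into HSD groups,
    classifies groups by Pfam domain-profile agreement (true, incomplete,
    space), sweeps thresholds over an identity-by-length grid with capturing
    value and performance score statistics, aggregates HSDs under KEGG
    pathway functional categories across species, and renders heatmaps.
    Includes a synthetic-data generator with planted duplicate families for
    fully offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ggplot2,
    patchwork,
    jsonlite,
    rlang,
    Biostrings,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
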