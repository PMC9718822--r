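Package: orthometa
Title: Cross-Species Ortholog Meta-Analysis of Stress Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing bulk brain RNA-seq responses to
    chronic stress across human, rat and zebrafish. Provides a synthetic-data
    generator with planted ground truth emulating a three-species
    control/stress/antidepressant design, strict readers and writers for the
    standard formats involved (count tables, GMT gene sets, STRING-like edge
    lists, JASPAR position frequency matrices, FASTA), one-to-one ortholog
    resolution, a negative-binomial Wald differential-expression test with
    median-of-ratios normalization, GAGE-style gene-set enrichment with
    up/down/bidirectional modes, Fisher p-value meta-analysis with
    direction-concordance filtering, promoter motif scanning with
    dual-criterion transcription-factor binding-site contrasts, and
    protein-protein-interaction network analysis (maximal cliques, ribosomal
    clique filtering, degree/betweenness/BottleNeck/MNC/DMNC hub scoring and
    the DMNC-then-MNC double screening scheme). Four orchestrated experiment
    drivers compose these stages into per-species, pooled, meta-analytic and
    clique-based cross-species analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
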