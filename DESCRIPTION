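Package: dialfq
Title: Label-Free Quantification and Downstream Analysis for DIA Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the quantitative stage of a data-independent
    acquisition (DIA) proteomics experiment, starting from a
    precursor-by-sample intensity table: MaxLFQ-style protein rollup via
    pairwise median log-ratios and least squares, peptide-intensity
    summing for proteins with extreme fold changes, Welch/ANOVA
    differential testing with permutation-based FDR and
    experiment-specific significance cascades, left-censored imputation
    for volcano visualization, Gene Ontology Fisher enrichment against
    the detected background, and significance-weighted quantitative term
    summaries. A synthetic-data module generates peptide-level datasets
    and toy ontologies with known ground truth so the whole pipeline is
    testable without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, GO,
    Software
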