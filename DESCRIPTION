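Package: ligandkit
Title: Post-Identification Analysis of HLA Ligandome Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for immunopeptidomics identification tables:
    harmonized strong/weak HLA-binder classification from multi-predictor
    percentile ranks and SYFPEITHI scores, replicate-level quality gating on
    binder fraction and peptide length mode, dataset-level global FDR
    estimation, Jaccard similarity and hierarchical clustering of samples,
    position-wise source-protein coverage and hotspot calling, tissue yield
    versus gene-expression modeling, Fisher-exact gene-set enrichment,
    tumor-versus-benign target prioritization, normalized spectral contrast
    angle validation of synthetic peptide spectra, retention-time
    prediction-interval evaluation, and k-means clustering of z-scored MS1
    trajectories. A bundled synthetic-data generator produces peptide tables,
    rank scores, proteomes, fragment spectra and time series with planted
    structure so the whole pipeline runs end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
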