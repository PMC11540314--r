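Package: duoQTL
Title: Joint Allelic and Dosage QTL Mapping in Interspecific F1 Hybrid
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci in an interspecific
    F1 hybrid population that segregates both natural allelic variation
    (the two haplotypes within each outbred parent) and induced dosage
    variation (large paternal deletions and insertions).  Implements
    parental haplotype phasing from a deep-coverage progeny subset,
    low-coverage binned genotyping, read-depth based dosage calling,
    flanking-marker imputation onto a common marker list, single-channel
    QTL scans with genome-wide max-|t| permutation thresholds, and a
    combined 10-state model with pairwise permutation tests,
    Benjamini-Hochberg adjustment and six-group QTL classification.
    Includes a synthetic-data generator with planted QTLs and a truth
    ledger so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'duoQTL-package.R'
    'utils.R'
    'classes.R'
    'io.R'
    'simulate.R'
    'snp_select.R'
    'phasing.R'
    'genotyping.R'
    'dosage.R'
    'integrate.R'
    'qtl_single.R'
    'qtl_combined.R'
    'pipeline.R'
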