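Package: methcausal
Title: Integrative DNA Methylation and Gene Expression Causal Network Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for paired DNA-methylation and gene-expression
    cohorts that identifies key regulator genes whose promoter methylation
    cis-regulates their own expression and thereby trans-regulates many downstream
    genes.  Implements iterative cross-omics sample matching, probe-to-gene
    promoter mapping, covariate adjustment, nonparametric cis/trans association
    scans, a residual-based trio causality test with permutation false-discovery
    rates, scale-free key-regulator detection, and hypergeometric screening of
    regulator downstream sets against disease-severity expression signatures.
    Includes a synthetic-data generator with planted causal structure for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
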