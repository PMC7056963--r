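Package: cgsea
Title: Chemical Gene Set Enrichment Analysis for Complex Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the association of chemicals with complex diseases or
    traits from genome-wide summary statistics alone. Each chemical is
    represented by the set of genes it interacts with (parsed from
    Comparative Toxicogenomics Database chemical-gene interaction files),
    and enrichment of that set at the top of a gene list ranked by
    transcriptome-wide association study (TWAS) Z-scores - or any gene-level
    association statistic - is measured with a weighted
    Kolmogorov-Smirnov-like running-sum statistic. Significance is assessed
    by gene-label permutation: enrichment scores are standardized against
    their permutation null (normalized enrichment score, NES) and assigned
    upper-tail empirical P values with an add-one correction, plus optional
    Benjamini-Hochberg false discovery rates. Includes parsers for the CTD
    chem_gene_ixns dialect and FUSION TWAS output, a reproducible
    end-to-end pipeline with run manifests, and a synthetic-fixture
    generator with planted enrichment signals for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
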