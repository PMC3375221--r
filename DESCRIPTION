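Package: regdiverge
Title: Screening Regulatory Regions for Lineage-Specific Substitution Rate
    Heterogeneity and Decomposing Their Functional Divergence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and functionally dissecting divergence of
    regulatory regions between closely related yeast species. Implements a
    branch-specific likelihood ratio screen for heterogeneity in the ratio of
    the noncoding substitution rate to the genome-wide fourfold-degenerate
    (silent) rate under the HKY85 model with a Felsenstein pruning likelihood;
    Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction, a
    sliding-window scan and parametric Monte-Carlo confidence intervals;
    extraction of a sulfite-dependent growth-delay phenotype from plate-reader
    curves with nonparametric group comparisons; additive and pairwise-epistatic
    mixed-model decomposition of chimeric-allele phenotypes with batch random
    intercepts, likelihood-ratio R-squared and per-region percent
    contributions; per-gene expression ANOVA with allele-by-time interactions,
    coding/noncoding effect-source classification and a permutation-based
    false discovery rate; and fully seeded synthetic-data generators for every
    stage so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
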