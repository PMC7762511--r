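Package: mathsurv
Title: Mutant-Allele Tumor Heterogeneity Scoring and Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies intra-tumoral heterogeneity from somatic variant
    allele fractions using the MATH statistic (100 x scaled median absolute
    deviation / median of per-sample VAFs), stratifies a cohort into MATH
    tertiles, and relates the strata to overall survival via Kaplan-Meier
    curves, k-group log-rank tests and Cox proportional-hazards models fit
    on the partial likelihood. Downstream characterization includes
    two-phenotype gene-set enrichment analysis with a phenotype-permutation
    null, single-sample (ssGSEA-style) immune-cell scoring with
    Mann-Whitney group comparison, and somatic-mutation summaries with
    pairwise Fisher co-occurrence tests. A synthetic-cohort generator with
    recorded ground truth (subclone allele fractions, survival hazards,
    planted expression shifts) makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
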