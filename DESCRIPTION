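Package: deltamed
Title: Latent Dementia Phenotype Construction and Serum-Protein Mediation
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a latent dementia phenotype ("delta") as the shared
    variance of cognitive performance and everyday function, scores
    subjects on it, and screens a multiplex serum-protein panel for
    mediators of the APOE e4 allele's prospective effect on the phenotype.
    Includes a compact covariance-structure (SEM) engine with maximum
    likelihood and full-information maximum likelihood estimation, fit
    indices, factor-score weights and determinacy, multi-group fits with
    chi-square difference tests; immunoassay panel quality control
    (duplicate reconciliation, below-detection LDD/2 substitution,
    outlier deletion, log-normalization, batch adjustment); product-of-
    coefficients (Sobel) mediation inference with split-half replication;
    and a synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
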