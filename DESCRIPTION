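Package: cerebmorph
Title: Deformation-Based Brain Morphometry and Cross-Experiment Convergence
    Analysis for Larval Zebrafish CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes and validates regional brain-volume phenotypes in larval
    zebrafish CRISPR (crispant) cohorts from elastic-registration displacement
    fields: log-Jacobian-determinant (LJD) voxel-volume maps, voxelwise t and
    two-way (genotype x batch) ANOVA statistic maps, cluster-extent and
    bilateral-symmetry filtering of p-value maps into region masks, and
    atlas-division / mask volumetrics with bootstrap group comparisons. Also
    provides the cross-experiment differential-expression convergence
    statistic (expression filtering, Benjamini-Hochberg FDR, sign-concordant
    overlap, hypergeometric test) and CRISPRstat-style fragment-analysis
    quantification of guide-RNA cutting efficiency. A synthetic-data module
    generates labeled bilaterally symmetric atlas brains, cohorts of smooth
    random warps with implanted regional atrophy, negative-binomial count
    tables with known shared differential expression, and electropherograms
    with known wildtype peak fraction, so the full pipeline is testable
    without any imaging or sequencing downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
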