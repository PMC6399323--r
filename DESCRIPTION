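Package: ccmiqtl
Title: Post-Infarction Remodeling Traits and Haplotype QTL Mapping for
    Collaborative Cross Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing variation in myocardial infarction outcome
    across Collaborative Cross recombinant inbred mouse strains: derivation of
    left-ventricular remodeling traits (delta-EF, LV dilation, rupture
    survival) from per-animal echocardiography records; quantification of
    infarct-scar collagen content and fiber orientation from paired
    polarized/brightfield histology images with axial circular statistics; an
    eight-founder haplotype hidden Markov model; kinship-adjusted linear
    mixed-model genome scans with permutation significance thresholds,
    two-LOD-drop support intervals, founder-effect estimates and candidate SNP
    prioritization; and expression-trait correlation on the GeneNetwork 2Z+8
    scale. Includes a synthetic-cohort generator with planted ground truth
    (mosaic founder genomes, founder-effect QTL, von Mises fiber images,
    trait-correlated transcripts) used to validate every stage end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
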