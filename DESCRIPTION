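Package: wormlamin
Title: Phenotyping and Pathogenicity Scoring of C. elegans Lamin Variant Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative phenotyping of Caenorhabditis elegans
    strains carrying missense variants of the lamin gene lmn-1, modelling
    human LMNA striated-muscle laminopathies. Converts per-animal assay
    measurements (brood size, embryonic lethality, swimming motility,
    hypodermal nuclear migration, nuclear morphology, nuclear-envelope
    fluorescence) into per-variant pathogenicity score cards with a
    severity classification. Includes a seeded synthetic-data generator
    (including rendered swim videos with ground truth), a swim-video
    tracker and body-bend counter, the per-assay statistical comparisons
    (one-way ANOVA with Dunnett or Tukey correction, chi-squared
    defect-fraction tests, Benjamini-Hochberg adjustment, Student's t
    tests, corrected total nuclear fluorescence), readers and writers for
    tidy assay tables and a sectioned workbook layout, and a command-line
    pipeline (simulate, analyze, score, report).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    multcomp,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    mvtnorm,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
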