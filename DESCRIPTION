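Package: adjuscreen
Title: Machine-Learning-Assisted Vaccine Adjuvant Screening from Multiblock
    In Vitro Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening vaccine adjuvant candidates by integrating
    in vitro immunoprofiles (human and mouse cytokine panels and flow-cytometric
    nanoparticle scatter profiles) with in vivo adjuvanticity endpoints.
    Implements endpoint titer interpolation and fold-change preprocessing,
    16-population FSC/SSC gating with blank subtraction, regularized canonical
    correlation analysis, sparse multiblock partial least squares and its
    discriminant variant with cross-validated tuning, principal component
    discrimination, and one- and two-step biomarker threshold screens with
    separation statistics. Includes a synthetic cohort generator with planted
    positive and negative latent signals for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), mixOmics, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
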