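Package: capsquant
Title: Restriction-Site Discrimination of Paralogous Transcripts and
    Growth-Based Transporter Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for two desk-scale procedures used in the functional
    characterisation of near-identical paralogous transporter genes. First, a
    CAPS-style (cleaved amplified polymorphic sequence) workflow: scan
    homologous coding sequences for restriction-site polymorphisms, predict
    digest fragment patterns, identify diagnostic gel bands that uniquely
    fingerprint each variant, and convert band densitometry into per-variant
    relative transcript abundances with reference-gene normalisation and
    Bonferroni-corrected group comparisons. Second, a growth-constant (kG)
    workflow: estimate a heterologously expressed transporter's apparent
    substrate affinity from the growth curves of complemented yeast, by
    exponential-phase fitting, conversion to growth rates, and
    Michaelis-Menten fitting of the rate-versus-substrate isotherm, together
    with the transport-limitation validity checks. A seeded synthetic-data
    module generates paralog sequence sets with controlled cut-site geometry,
    simulated gel lanes, and mechanistic growth curves, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
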