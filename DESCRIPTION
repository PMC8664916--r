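Package: drivesim
Title: Population Dynamics and Cross Statistics for CRISPR Gene Drive Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-structured, daily-timestep stochastic and deterministic
    simulation of CRISPR gene drive systems (Y-, X- and autosomally linked
    split drives, X-shredder sex-ratio distorters, and homing-based
    suppression drives) in a two-patch mosquito metapopulation. Inheritance
    is encoded as genotype-indexed offspring-distribution tensors
    ("inheritance cubes") built from explicit germline models of cleavage,
    homology-directed repair and resistance allele formation. Includes
    summary metrics for modification and suppression interventions (window
    of protection, carrier frequency, elimination probability, rebound
    time), exact enumeration of F1 cross outcomes under lethal biallelic
    mosaicism for sex-sorting crosses, chi-squared goodness-of-fit analysis
    of observed cross counts, and synthetic data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
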