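Package: myomass
Title: Body-Mass-Associated Sequence Variation in Myosin II Orthologues
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects amino-acid positions in an orthologue protein alignment
    whose variation tracks species body mass rather than phylogenetic clade.
    Provides reference-based sequence-identity-versus-mass robust (least
    absolute deviation) regression with a mass-perturbation bootstrap,
    per-column site profiling with exact Mann-Whitney and Fisher tests under
    Bonferroni control, logistic transition-mass estimation with
    separation-robust (Jeffreys-prior) fitting, Felsenstein phylogenetically
    independent contrasts, a detachment-limited actomyosin crossbridge
    kinetic model (V0 = d/tau, k-ADP = 1/tau) with transient-fitting
    utilities, and a synthetic-data generator with planted site classes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
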