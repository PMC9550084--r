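Package: fodm
Title: Fuzzy Oil Drop Model with Environment Modification for Protein
    Hydrophobicity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how closely the hydrophobicity distribution of a
    protein structural unit (chain, domain or complex) matches the
    idealized micelle-like distribution of a 3D Gaussian hydrophobic
    core. Computes theoretical (T), observed (O, Levitt pairwise
    interactions), uniform (R) and environment-modified (M) per-residue
    hydrophobicity profiles, the Kullback-Leibler relative-distance
    statistic RD, the optimal environment coefficient K, and classifies
    intrinsically disordered regions as FOD-ordered or FOD-unordered
    relative to their structural unit. Includes a synthetic point-cloud
    generator with controlled hydrophobicity arrangements for validation,
    disulfide-bond fragment profiling, and cohort-level classification
    with K-range segmentation and regression reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
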