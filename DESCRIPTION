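Package: pqreg
Title: Phylogenetic Quantile Regression and Trait Trade-Off Analysis for Woody Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of stress-resistance trait trade-offs in
    woody plants. Curates species-level frost resistance (LT50/LT0, including logistic
    fits to raw electrolyte-leakage curves) and drought resistance (xylem embolism
    P50) from heterogeneous measurement tables; estimates phylogenetic signal
    (Blomberg's K with permutation tests, Pagel's lambda by maximum likelihood) and
    Brownian-motion ancestral states; fits Bayesian mixed-effects quantile regressions
    with an asymmetric Laplace likelihood, optional phylogenetic random effects,
    highest-density intervals and region-of-practical-equivalence decisions; summarises
    species climate ranges from occurrences and gridded layers; and simulates all of
    these data types with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    minpack.lm,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
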