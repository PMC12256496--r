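Package: dartnam
Title: Bioactivity-Exposure Ratio Evaluation of a DART NAM Toolbox
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for next-generation risk assessment (NGRA) of
    developmental and reproductive toxicity (DART) without new animal data.
    Implements confusion-matrix evaluation of binary in-silico hazard calls;
    harmonization of heterogeneous pharmacokinetic literature records into
    concentration-dose ratios with N-weighted population means and standard
    deviations, 95th-percentile toxicokinetic variability factors (TKVF) and
    inter-population fold differences; per-platform point-of-departure (PoD)
    estimation from concentration-response data (Bayesian Hill IC50 fitting,
    Williams trend prefilter with six-model benchmark-dose estimation,
    four/five-parameter log-logistic developmental toxicity potential,
    hierarchical row-effect viability PoDs with concentration dependency
    scores, and Dunnett-based LOEC calling with steroidogenesis carry-over
    interpretation); aggregation of PoDs and population Cmax estimates into
    bioactivity:exposure ratios (BER) scored for protectiveness and utility
    against benchmark risk labels; a descriptor-filter/PCA/t-SNE chemical
    space pipeline; and seeded synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    multcomp,
    jsonlite
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
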