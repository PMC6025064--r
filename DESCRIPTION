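Package: tdol
Title: Temporal Drivers of Liking for Multi-Attribute Time-Intensity Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Time-resolved relative-importance analysis of sensory attributes
    for consumer liking ("temporal drivers of liking") from multi-attribute
    time-intensity (MATI) data. Implements non-additive importance measures:
    Choquet-integral capacity (fuzzy measure) identification by constrained
    least squares with Shapley values and pairwise interaction indices, and
    the LMG variance-decomposition statistic for consumer and just-about-right
    data. Importance trajectories are smoothed with penalized B-splines into
    differentiable functional curves whose first and second derivatives
    describe the dynamics of attribute importance. Includes a synthetic MATI
    data generator with known ground truth, delimited-text readers/writers,
    and a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    quadprog,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
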