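Package: evotraj
Title: Selection-Mode Inference from Time-Resolved Mutation-Frequency
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistics for within-host experimental evolution from
    time-resolved mutation-frequency trajectories. Implements the p-tau
    selection test (frequency propagator G(x), sojourn-time spectrum T(x),
    and the summary statistics p = G(xf)/G(xm) and tau = T(xf)/T(xm)) that
    discriminates periodic selective sweeps, clonal interference, and
    diversifying (negative frequency-dependent) selection; supporting
    trajectory statistics (selective-sweep calling, mutation accumulation
    M(t) and its per-generation rate, dN/dS counts, cross-host parallelism,
    frequency-change correlation tests for negative frequency-dependent
    selection, Muller-plot lineage nesting); max-slope estimators for
    bacterial growth and prophage induction rates from OD600 kinetics; and
    two Wright-Fisher simulators (beneficial-mutation directional selection
    and consumer-resource ecotype competition) that generate trajectory data
    with pool-seq style sampling noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
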