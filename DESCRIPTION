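Package: BitterCircuit
Title: Quantification of Bitter-Taste Behavior, Calcium Responses, and
    Downstream Circuit Tracing in Drosophila
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing optogenetic bitter-taste experiments in
    Drosophila and the synaptic circuitry downstream of second-order bitter
    projection neurons. Implements quadrant preference indices and
    stimulus-locked kinematic responses from tracked arena trajectories,
    sip/burst/bout segmentation of closed-loop feeding assays with
    proboscis-extension suppression indices, deltaF/F ON/OFF response
    metrics with habituation profiles for calcium imaging, an
    effect-strength classification of genotype screens (ANOVA gate,
    Dunnett many-to-one comparisons, min-of-two-controls effect sizes),
    and threshold-based layered tracing of weighted synaptic connectomes
    (downstream layers, top-target ranking, subtype interconnection
    motifs, region-projection fractions with laterality, feedback
    detection, and bounded weighted path search). Seeded simulators with
    recorded ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    mvtnorm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'calcium.R'
    'classify.R'
    'feeding.R'
    'io.R'
    'locomotor.R'
    'pipeline.R'
    'protocol.R'
    'simulate-arena.R'
    'simulate-calcium.R'
    'simulate-circuit.R'
    'simulate-feeding.R'
    'tracing.R'
    'utils.R'
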