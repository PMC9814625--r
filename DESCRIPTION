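Package: contextflux
Title: Transcriptome-Contextualized Metabolic Modeling and Discriminative
    Reaction Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis pipeline for finding metabolic
    reactions that are used differently by two patient groups. Genome-scale
    metabolic models (COBRA-JSON or SBML L3/FBC) are contextualized per
    patient with transcript-weighted parsimonious flux balance analysis:
    reactions unsupported by a sample's transcriptome and unable to carry
    flux near the parsimonious optimum are pruned, and feasible flux vectors
    are drawn from the remaining solution polytope by hit-and-run sampling.
    Repeated random-forest classification of the sampled fluxes with
    patient-level train/test splits and class-balancing under-sampling
    yields an aggregated ranking of discriminative reactions, which are then
    compared between groups with the Mann-Whitney U test and grouped into
    subsystem families. A synthetic-data module generates toy metabolic
    networks and two-group transcriptomic cohorts with planted differential
    pathways for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ggplot2,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
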