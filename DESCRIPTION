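Package: spongehif
Title: Presence-Absence Profiling of the HIF Pathway and Sponge Hypoxia
    Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether an animal lineage carries a working
    hypoxia-inducible factor (HIF) pathway, and for characterizing sponge
    behaviour under low oxygen. Implements reciprocal-best-hit homolog
    selection from BLAST tabular output, species-overlap orthology
    classification on gene trees with presence/homolog/secondary-loss
    calls, PFAM-style domain-architecture filtering, oxygen-dependent
    degradation (ODD) degron motif scanning with analytical and
    permutation chance-occurrence nulls, seawater oxygen solubility and
    air-saturation conversions, contraction-event detection from
    projected-area time series, Poisson log-linear contraction-rate
    models, and contraction-coupled oxygen-uptake analysis. A synthetic
    data module generates gene families by duplication-loss simulation,
    proteomes with planted degrons, and stepped-oxygen behavioural
    experiments with known truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    EBImage,
    jsonlite,
    phangorn,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
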