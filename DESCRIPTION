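Package: plastiscan
Title: Past-Cue Expression Plasticity and Its Fate During Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects how ancestral expression plasticity to a past
    environmental cue (salinity) shapes adaptation to a novel cue (zinc)
    in paired coastal/mine ecotype populations. Provides a compact
    negative-binomial differential-expression engine, the full catalog of
    plasticity, divergence and cross-experiment contrasts, classification
    of genes into preadaptive-plasticity, cue-transfer, genetic-adoption
    and genetic-assimilation categories, randomization and proportion
    tests against chance expectations, and PST-FST screening of adaptive
    expression divergence. A synthetic count-matrix generator with planted
    gene classes makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
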