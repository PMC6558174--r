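Package: stagecomp
Title: Cross-Species Comparison of Plant Development Stage Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing gene expression across plant development
    stages and species using stage-ontology annotations. Parses development
    stage ontologies in OBO flat-file format and reasons over typed relations
    (subclass closure, temporal ordering via precedes/preceded_by,
    stage-structure participation inference), reads and filters GAF-style
    gene-association files by evidence code, builds cross-species homolog
    clusters from pairwise similarity tables by reciprocal best hits with a
    mutual-overlap filter and in-paralog assignment, computes stage overlap
    and uniqueness statistics within and between species, and performs
    slim-mapped one-sided Fisher term enrichment with Benjamini-Yekutieli
    adjustment and cross-set comparison tables. Includes seeded synthetic
    fixture generators emulating the statistical structure of real
    stage-annotation data, and an end-to-end workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
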