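Package: bcrflow
Title: Longitudinal B-Cell Receptor Repertoire Analysis Across Blood and
    Gut Tissue Compartments
Version: 0.1.0
Authors@R: person("bcrflow", "maintainers", email = "bcrflow@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing annotated immunoglobulin heavy-chain
    rearrangement tables from longitudinal blood and intestinal-mucosa
    samples. Implements clonal grouping by V/J gene and CDR3 amino-acid
    identity, somatic-hypermutation profiling, germline-rooted lineage
    trees built from nested V-region mutation sets, a 0-1 "clumpiness"
    metric of tissue-label mixing within lineages, Hill-number diversity
    and evenness, clone-size cosine similarity between repertoires,
    time-bracketed clone dynamics (sign tests, rank-sum comparisons),
    normalized chimerism area-under-curve summaries, and a fully
    deterministic synthetic repertoire generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
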