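Package: ciliome
Title: Seed-Centric Protein-Protein Interaction Networks for Cilia Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles seed-centric protein-protein interaction (PPI) networks
    that combine curated ("known") and computationally predicted ("novel")
    interactions, and runs the downstream analyses used in cilia interactome
    studies: node-role classification (seed, known interactor, novel
    interactor), per-seed interaction summaries, hypergeometric
    over-representation of annotation terms in network neighborhoods,
    disease-interactome and differential-expression overlap statistics,
    expression-direction concordance between disease and developmental fold
    changes, average shortest-path statistics with random-gene-set nulls, and
    drug-target stratification by ATC category. Includes seeded synthetic-data
    generators with planted ground truth for every input shape, and a packaged
    transcription of a published cilia gene interaction table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
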