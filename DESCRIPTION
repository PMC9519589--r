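Package: meptrace
Title: Lineage-Tree Analytics and Fate Modeling for Time-Lapse Imaged
    Hematopoietic Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing single-cell time-lapse tracking of clonally
    growing hematopoietic progenitor colonies, built around bipotent
    megakaryocytic-erythroid progenitors (MEPs). Reconstructs lineage trees
    from per-frame track tables, infers cell fates by back-propagating
    terminal lineage-marker identity, classifies division outcomes
    (expansion, maintenance, exhaustion), computes per-cell motility and
    lifespan metrics, tabulates per-generation population kinetics, clusters
    behavioral phenotypes (PCA, silhouette-guided k selection, k-means), and
    fits a nonhomogeneous Markov model of division outcome versus generation
    by maximum likelihood with delta-method and bootstrap confidence
    intervals. A seeded stochastic colony simulator emulating the acquisition
    schedule, state-dependent cycle times, death, motility and marker onset
    of such experiments makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
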