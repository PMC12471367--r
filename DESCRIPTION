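Package: amprofiler
Title: Screening, Annotation and Semi-Quantification of Amphidinol
    LC-MS/MS Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for discovering and profiling amphidinol polyketides in
    dinoflagellate extracts from tandem mass spectrometry peak lists.
    Implements three-mode screening (selected reaction monitoring, neutral
    loss and full scan), a rule engine that interprets collision-induced
    dissociation spectra of sodium-adduct precursors via diagnostic neutral
    losses (120 Da sulfation, 392/398/426 Da lipophilic-arm cleavage, 58 Da
    di-gamma-hydroxy-carbonyl fragment pairs, 218/200 Da hydrophilic-terminus
    losses), semi-quantification against a luteophanol-D standard with
    limit-of-detection handling, brine-shrimp mortality statistics, and
    multivariate ordination and clustering of strain chemotype profiles.
    Includes a synthetic-data generator that emulates the fragmentation
    grammar for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
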