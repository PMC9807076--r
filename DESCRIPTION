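Package: safeflow
Title: Safe and Complete Flow Decomposition Paths for RNA Splice Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing flow decompositions of weighted directed
    acyclic graphs arising as RNA splice graphs. Implements the excess-flow
    characterization of w-safe paths with linear-time verification, a
    two-pointer enumeration of all maximal safe paths from an arbitrary flow
    decomposition with a concise (windowed) representation and substring
    deduplication, baseline decomposition heuristics (greedy-width and
    minimum-edge peeling), safe baselines (unitigs and extended unitigs),
    funnel detection, transcript-superposition instance simulation with
    lognormal abundances, and the weighted precision / maximum relative
    coverage / F-score evaluation metrics in node and base units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
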