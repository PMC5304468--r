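Package: causalplanr
Title: Experiment Planning with Causal Graphs and Research Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computer-aided experiment planning toward causal
    discovery. Represents published findings as research maps (evidence
    graphs whose edges carry experiment records and scores), translates
    them into weighted causal-structure constraints, recovers the
    equivalence class of causal graphs consistent with the constraints,
    quantifies the underdetermination of that class (graph counts,
    degrees of freedom, edge entropy), and ranks candidate experiments
    by the uncertainty they would remove or the evidence they would add
    under the integration principles of consistency and convergence.
    Includes exact d-separation with intervention surgery, exhaustive
    enumeration of small graph spaces, a weighted constraint optimizer,
    a closed-loop planning simulator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
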