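Package: drugrepo
Title: Drug Repurposing Scores from Chemical Structure, Target Overlap and
    Network Proximity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate compounds for repurposing against diseases by
    combining three components: Tanimoto similarity between ECFP4 structural
    fingerprints of the candidate and a disease's approved drugs, the overlap
    coefficient between their potent drug-target interaction profiles (OCTS),
    and a compound-disease score (CDS) derived from min-max-normalized average
    shortest-path distances between compound targets and disease genes in a
    protein-protein interaction network. The composite score is the mean of
    the three components. Includes readers for the five tabular inputs
    (compounds, bioactivities, PPI edges, disease-gene associations, approved
    indications), significance and hit-ratio evaluation statistics, a seeded
    synthetic-fixture generator with planted repurposing structure, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
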