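Package: ismanp
Title: Interpretive Structural Modeling and Analytic Network Process for
    Risk-Factor Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Structures and weights expert-elicited risk-factor systems, as
    used in injury epidemiology (Haddon-matrix framed studies). Provides
    questionnaire reliability and structural-validity statistics (Cronbach's
    alpha, Kaiser-Meyer-Olkin sampling adequacy, Bartlett's test of
    sphericity) and exploratory factor analysis by principal-component
    extraction with varimax rotation; interpretive structural modeling (ISM):
    adjacency construction from V/A/X/O relation codes, Boolean reachability
    closure, reachable/antecedent set analysis, level partitioning and
    hierarchy digraph export; and analytic network process (ANP) weighting:
    Saaty judgment matrices, eigenvector priorities, consistency ratios,
    supermatrix assembly, cluster weighting and the limit supermatrix.
    Includes deterministic synthetic-data generators for every input and
    fixtures transcribed from a published ISM-ANP analysis of drowning risk
    factors in preschool children.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
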