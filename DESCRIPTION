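Package: vaxforum
Title: Rule-Based Detection of Vaccination-Schedule Adherence and
    Adverse-Event Mentions in Parenting-Forum Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested re-implementation of a rule-based text-mining
    pipeline for parenting-forum corpora: it filters comments that state
    the author's childhood vaccination scheduling behaviour, classifies
    each as following the recommended or an alternative schedule,
    retrieves mentions of adverse events following immunization (AEFI)
    together with the experiencing subject and reaction type, aggregates
    comment labels to users, screens user features (interest groups,
    shared URL domains, geography) with odds ratios and Fisher's exact
    test, and quantifies homophily on the directed weighted
    commenter-to-author interaction network. A synthetic forum-corpus
    generator with exact ground-truth labels makes every stage testable
    without access to platform data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    datasets,
    yaml,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
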