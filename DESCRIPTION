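Package: iconcord
Title: Inter-Alignment Agreement for Compositional Icon Terminologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate the agreement between two independently
    produced alignments of hierarchical medical terminologies to a
    compositional iconic language. Icons are modelled as sets of
    primitives drawn from a shallow rooted hierarchy; pairs of concepts
    linked across terminologies are compared with three metrics: binary
    concordance, the crude Dice similarity coefficient over primitive
    sets, and a semantic Dice coefficient that replaces exact overlap
    with best-match Lin information-content similarities. Includes the
    closest-ancestor icon inheritance procedure for poly-hierarchies,
    stratified agreement summaries with confidence intervals and
    Fisher/Wilcoxon tests, a worst-case sensitivity analysis for
    excluded pairs, and a seedable synthetic-world generator with a
    controlled per-pair discordance rate for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
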