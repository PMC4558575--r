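Package: cophyr
Title: Cophylogenetic Analysis of Host-Parasite Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cophylogenetic analysis of host-parasite tanglegrams,
    built around the study system of Lake Tanganyika tropheine cichlids and
    their Cichlidogyrus monogenean gill parasites. Provides distance-threshold
    species delimitation of parasite haplotypes, event-based host-parasite
    tree reconciliation (cospeciation, sorting, duplication, host-switch)
    with parameter-adaptive event-cost estimation, a distance-based
    permutation test of phylogenetic congruence, lineages-through-time
    diversification-rate-shift testing, and a synthetic tanglegram generator
    with known event histories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
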