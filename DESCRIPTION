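Package: sinephylo
Title: Retrophylogenomics from SINE Presence/Absence Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of retroelement (SINE)
    insertion presence/absence data. Filters MELT-style genotype calls
    into a binary insertion matrix; infers trees by Dollo parsimony with
    bootstrap and majority-rule consensus, and by neighbor joining;
    classifies loci discordant with a species tree and attributes them to
    ancestral nodes where incomplete lineage sorting or introgression
    likely occurred; exports one-bipartition gene trees with per-branch
    quartet support; tests quartets for the asymmetric minority-pattern
    excess expected under introgression but not under lineage sorting
    alone; and simulates homoplasy-free insertion matrices under the
    multispecies coalescent with optional introgression pulses.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
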