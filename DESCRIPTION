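Package: crekit
Title: Microevolution Analysis of Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("crekit", "maintainers", email = "crekit@example.org", role = c("aut", "cre"))
Description: Tools for studying microevolution of cis-regulatory DNA from
    multi-species, multi-haplotype alignments. Computes within-species
    diversity and neutrality statistics (nucleotide diversity, Watterson's
    theta, Tajima's D, Fu and Li's D and D*, haplotype diversity), a
    per-position conservation index, four independent transcription-factor
    binding-site (TFBS) annotation schemes (exact-site scan, position-weight
    matrix scan with core-similarity cutoff, DNase-I footprint tracks, and
    phylogenetic footprinting against a distant outgroup), parsimony-based
    cataloguing of fixed and polymorphic substitutions with TFBS
    gain/loss/change accounting, and the binding-site adaptation of the
    McDonald-Kreitman test together with relative-rate estimators. A
    forward simulator with planted motifs and per-site rate multipliers
    provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
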