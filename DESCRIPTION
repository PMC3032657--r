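Package: popgenld
Title: Candidate-Gene Diversity and Linkage-Disequilibrium Analysis for
    Outcrossing Plant Populations
Version: 0.1.0
Authors@R:
    person("Population Genetics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for candidate-gene and microsatellite population-genetics
    surveys of outcrossing plants genotyped by gamete capture (one phased
    haploid gene fragment per line). Implements polymorphic-site calling with
    indels treated as single binary sites, nucleotide and haplotype diversity,
    Tajima's D with the beta-distribution significance approximation,
    counting-based dN/dS (Nei-Gojobori 1986) with a codon-bootstrap neutrality
    test, SSR summaries (polymorphic information content with bootstrap
    confidence intervals, rarefaction-based allelic richness, private alleles),
    pairwise r2 linkage disequilibrium with Fisher's exact significance,
    Hill-Weir decay-curve fitting with an empirical unlinked-marker threshold
    and LD-extent estimation, DICE similarity, principal co-ordinate analysis,
    and two-level AMOVA with permutation testing. A forward-time Wright-Fisher
    simulator with intra-genic recombination generates study-shaped synthetic
    data with known ground truth, and a pipeline driver reproduces the survey's
    report tables end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
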