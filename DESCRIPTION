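Package: somaticlift
Title: Somatic Variant Filtering and Cross-Species Ortholog Lifting for
    Tumor/Normal Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-level somatic mutation analysis in paired
    tumor/normal exomes of a non-human species, with cross-species
    interpretation against human cancer knowledge. Implements a
    decision-tree somatic filter (region class, population allele
    frequency, panel of normals, read depth, deamination-artifact
    surrogate), transcript-level coding consequence annotation, an affine
    gap Smith-Waterman protein aligner with Karlin-Altschul E-values used
    to accept orthologs and lift mutated residue positions into human
    coordinates, and cohort statistics (recurrence, case frequencies,
    mutation burden per megabase, hotspot tallies, gene set
    over-representation). Includes a seeded simulator of FFPE-style
    tumor/normal variant cohorts with planted hotspot drivers, passenger
    load, shared germline polymorphisms and low-VAF deamination artifacts,
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
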