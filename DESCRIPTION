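Package: lariatrace
Title: Split-Read Detection of Intron Lariats in Stranded RNA-Seq
Version: 0.1.0
Authors@R:
    person("lariatrace", "developers", email = "lariatrace@example.org",
           role = c("aut", "cre"))
Description: Detects branchpoint-spanning (lariat) reads in paired-end
    stranded RNA-seq. Builds a database of exclusively intronic regions from a
    GTF annotation, extracts 20 nt 5' splice-site and 250 nt 3' splice-site
    intronic fragments, scans genome-unmapped reads for exact 5' splice-site
    hits, trims the unique molecular identifier and the matched splice-site
    sequence, aligns the retained 3'-intronic segment back to the 3'
    splice-site fragments with a semi-global aligner, applies mismatch/indel,
    gene/strand consistency and mate-orientation filters, and reports
    branchpoint calls and per-sample lariats-per-million. Includes a seeded
    synthetic-data generator (genome, annotation, background mRNA pairs and
    planted lariat-junction reads with a truth table) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
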