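Package: hemiscan
Title: Coverage-Based Sex Scaffold Identification and Genome-Paper Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for identifying a hemizygous (X) scaffold in a
    male chromosome-scale genome assembly from binned, GC-normalized long-read
    depth of coverage, and for the companion computations of a genome report:
    unique best-hit placement of conserved X-linked marker genes with an exact
    binomial test against the length-proportional null, assembly contiguity
    statistics (N50/L50, GC content), phylogenomic supermatrix curation
    (missingness and occupancy filters, neighbor-joining screens for branch
    outliers and paralogous loci, partitioned concatenation), and per-transcript
    intron statistics from a GFF3 annotation. Seeded synthetic-data generators
    emit every input the pipeline consumes together with ground truth, so the
    whole workflow is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
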