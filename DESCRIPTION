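Package: circbin
Title: Circular Genome Recovery from Metagenome Bins by Iterative Read
    Baiting and Contig Extension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers complete circular genomes from metagenome bins by
    iterating k-mer based recruitment of read pairs ("baiting") with
    read-coherent consensus extension and merging of the bin's contigs,
    detecting the three loop outcomes (circularization, idempotence, chaos).
    Circularity is decided from an exact terminal repeat that out-measures
    every other repeat in the contig, corroborated by outward-facing
    paired-end reads at the contig ends.  Finished genomes are screened with
    non-coding RNA completeness gates (16S/23S/5S rRNA, a full set of tRNA
    isotypes, RNase P RNA with a relaxed covariance-model bit-score cutoff)
    and a coverage-evenness rule, and their ribosomal RNA gene arrangement is
    classified into linked and unlinked operon layouts.  Includes a
    synthetic-data module that simulates small circular genomes, planted
    repeats, wraparound paired-end libraries and multi-genome communities so
    the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
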