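Package: ctfrag
Title: Allele-Specific Fragment-Length Analysis of Circulating Tumor DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-aware fragment-length (fragmentomics) analysis of
    cell-free DNA sequencing data at cancer hotspot loci. From aligned
    paired-end reads, fragments overlapping each hotspot are extracted, insert
    sizes are recovered from the template-length field, and each fragment is
    typed as mutant or wild-type by CIGAR-aware base lookup at the variant
    position. Per-allele fragment-length profiles (modal peaks, medians),
    mutant allele frequency (MAF), frequency binning, and a
    Short/Long/Normal/Other sample description are computed, and in-silico
    size gates quantify how fragment-size selection changes the MAF. A seeded
    synthetic-data generator writes aligned paired-end SAM plus reference
    FASTA for arbitrary per-allele length models, and a Poisson occupancy
    model quantifies droplet digital PCR counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
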