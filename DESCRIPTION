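Package: poolscan
Title: Bulked-Segregant Mapping of Recessive Mutations from Pooled
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mapping-by-sequencing of recessive mutations from an F2
    incross with phenotypically pooled individuals (bulked segregant
    analysis). Discovers strain-diagnostic SNP markers in the
    wildtype-sibling pool, computes the mutant-pool allele-frequency
    profile, smooths it with a sliding window of neighboring loci, and
    calls the linkage interval as the genome-wide homozygosity peak.
    Candidate lesions inside the interval are triaged by coding
    consequence (missense, nonsense, frameshift) against gene models and
    by reduced expression between pools. Includes a forward-genetic cross
    simulator (meiotic recombination, pooling, read sampling with
    sequencing error) that provides ground truth for parameter-recovery
    testing, plus VCF/GFF3/FASTA/BED/TSV interchange and a command-line
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
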