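Package: coreindel
Title: Core InDel Marker Design and Subgenome Specificity Screening for
    Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds co-dominant PCR marker sets from multi-sample InDel
    calls on a polyploid reference. Provides GATK-style hard filtering and
    vcftools-style cohort site filtering of VCF records, marker candidacy
    filtering (bi-allelic, length difference, heterozygosity and minor
    allele frequency rules), flanking-template extraction and exhaustive
    primer-pair enumeration under printed design constraints with an
    internal nearest-neighbor melting-temperature engine, in-silico
    specificity screening of every primer against all homologous subgenome
    copies with target/allelic/off-target classification, core marker set
    assembly with density statistics, in-silico PAGE band prediction, and
    minimal discriminating marker subsets for per-sample molecular IDs.
    Includes a deterministic synthetic-data generator emulating
    near-identical subgenome copies, implanted InDels and diploid-style
    genotype calls, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    stats,
    stringi,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
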