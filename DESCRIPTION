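Package: asmarbiter
Title: Arbitrating Short-Read Genome Assemblies Against a Reference Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for comparing a de Bruijn short-read genome
    assembly against an established reference assembly of the same organism:
    contiguity statistics (N50/N90 with community exclusion conventions),
    scaffold-to-contig splitting at placeholder N runs, length-cutoff trimming
    and trimming sweeps scored by gene recovery, validation of placeholder gap
    sizes through whole-genome alignment of adjacent contigs, detection of
    contigs spanning multiple contigs of the other assembly, rough chromosome
    painting by alignment chaining, BUSCO-style gene recovery scoring,
    classification of heterozygosity bubbles (SNP/indel/mixed) from a
    fork-annotated FASTA dialect, detection of separately assembled haplotype
    contig pairs, partitioning of per-contig variant density into monomorphic
    and polymorphic compartments, and low-complexity masking with permutation
    enrichment tests. Includes a fully deterministic truth-annotated simulator
    so that every pipeline stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
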