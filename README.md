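# asmarbiter

Tools for arbitrating between genome assemblies: given a cheap short-read
de Bruijn assembly and an established reference assembly of the same
organism, `asmarbiter` quantifies where each one wins and whether the
cheap one is good enough for gene-based work.

It was built around a recurring question in insect genomics: assemblies
from a single PCR-free short-read library are affordable for the many
medically and agriculturally important species that will never get
long-read budgets, but they come with caveats — modest contiguity,
fixed-size placeholder gaps, heterozygosity artifacts — that need to be
measured, not assumed. The package covers:

* **Contiguity statistics** — N50/N90 and friends with the standard
  exclusion conventions (scaffolds < 1 kb, contigs < 200 bp), where Nx is
  the largest length *L* such that sequences ≥ *L* hold ≥ *x*% of total
  bases. Contig statistics are always derived by splitting scaffolds at
  placeholder N runs, so scaffold and contig blocks describe one input.
* **Length-cutoff trimming** and a cutoff sweep scored by gene recovery,
  to pick a trimming threshold on evidence.
* **Placeholder-gap validation** — split scaffolds at their N runs, reduce
  contig-to-reference alignments to unambiguous 1:1 pairings, and measure
  the separation between adjacent component contigs on the reference
  (half-open: abutment = 0, overlap < 0) against the fixed placeholder.
* **Spanning-contig detection** — contigs of one assembly whose alignments
  cover ≥ 90% of two or more contigs of the other, plus extraction of the
  intervening sequence and a permutation test for low-complexity
  enrichment in it.
* **Chromosome painting** — rough contig-to-chromosome assignment by the
  highest-scoring chain of collinear, nearly contiguous alignments.
* **Gene recovery** — BUSCO-style scoring with a declared greedy rule:
  hits ranked by score are accepted iff they add ≥ 20 novel gene bases;
  coverage is the accepted union, "pieces" the accepted-hit count;
  complete / duplicated / fragmented / missing categories.
* **Heterozygosity** — classification of de Bruijn "bubbles"
  (`single_snp` / `single_indel` / `mixed` / `oversize` at a 12.5 kb cap)
  from a documented fork-annotated FASTA dialect (`{ALT1|ALT2}`, one
  branch possibly empty), bubble flattening, detection of separately
  assembled haplotype contig pairs, and partitioning of assembly bp into
  zero-variant and variable compartments with SNPs/kb and bases-per-SNP
  spacing (`round(1000/rate)`).
* **A deterministic truth-annotated simulator** that generates genomes,
  placeholder-gapped assemblies, partitioned heterozygosity, planted
  genes, planted low-complexity tracts, haplotype duplicates, and exact
  truth alignment tables — so the whole pipeline is testable with no
  sequencing data.

Inputs are standard files: FASTA, PAF or nucmer `show-coords -T` tables,
a VCF v4 column subset (`CHROM POS ID REF ALT`), and BED3+. All internal
coordinates are 0-based half-open.

## Worked example

Simulate a 2 Mb study — assembly with 100-bp placeholder gaps, a 39%
monomorphic compartment at 3.66 SNPs/kb elsewhere, 40 planted genes, 4
haplotype-duplicate pairs — then run the main analyses:

```r
library(asmarbiter)
st <- simulate_study(genome_length = 2e6, n_chromosomes = 2, n_genes = 40,
                     hap_dup = list(count = 4, divergence = 0.02),
                     seed = 424242)

assembly_report(st$scaffolds)
#>     level n_sequences   n50  n90 mean_length max_length total_length
#>  scaffold         142 17977 7070    13982.56      65577      1985524
#>    contig         244  8997 5249     8095.59      11986      1975324

seps <- adjacent_separation(split_scaffolds(st$scaffolds), st$truth_alns)
head(seps[, c("left_contig", "right_contig", "separation", "placeholder_len")], 3)
#>  left_contig right_contig separation placeholder_len
#>       scf1.1       scf1.2        331             100
#>       scf3.1       scf3.2        190             100
#>       scf3.2       scf3.3        344             100

p <- partition_variant_density(st$het$variants, nchar(st$scaffolds))
sprintf("zero-variant: %.1f%%  rate: %.2f SNPs/kb  spacing: %d bp",
        p$zero_fraction, p$variable_rate, p$spacing)
#> "zero-variant: 37.9%  rate: 3.84 SNPs/kb  spacing: 261 bp"

s <- summarize_recovery(gene_recovery_table(st$features$hits))
sprintf("gene recovery: %.1f%% in %.3f pieces", s$mean_recovery_pct, s$mean_pieces)
#> "gene recovery: 100.0% in 1.000 pieces"

detect_haplotype_pairs(st$features$self_alns, lengths = nchar(st$assembly))
#>  contig_a    contig_b cov_a cov_b mean_identity length_ratio
#>    scf121 scf121_hap2     1     1      98.02721            1
#>    ...
```

Reading the numbers: every separation is the measured distance on the
truth genome between contigs that the assembly joined with a fixed 100-N
placeholder — here the placeholders stand in for real gaps of ~0–500 bp.
The zero-variant fraction lands near the 39% target (contig granularity
makes it approximate, and the realized value is recorded in the truth),
and the variable-compartment rate of 3.84/kb is the SNP rate plus the
planted indel rate. Planted genes are recovered completely in single
pieces, and exactly the four planted haplotype pairs are detected.

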