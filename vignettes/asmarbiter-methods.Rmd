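---
title: "Arbitrating short-read assemblies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating short-read assemblies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmarbiter)
```

# What this package computes

`asmarbiter` evaluates a de Bruijn short-read genome assembly against an
established reference assembly of the same organism. The comparison it
operationalizes was designed for a mosquito-scale genome (a few hundred Mb)
assembled from a single PCR-free short-read library, where the open
questions are: how contiguous is the cheap assembly, are its fixed-size
placeholder gaps honest, how much of the gene set does it recover, and how
does template heterozygosity shape it. Every analysis consumes standard
files (FASTA, PAF or nucmer `show-coords -T` tables, a VCF column subset,
BED), so the package slots in after any aligner/caller and never runs one
itself.

All internal coordinates are 0-based half-open. 1-based inclusive
coordinates exist only at file boundaries (`show-coords`, VCF) and are
converted on read and restored on write. This single-convention rule is
load-bearing: separations, interval unions and gap accounting are all
plain end-minus-start arithmetic with no off-by-one cases.

# Contiguity statistics

`nx_stat(lengths, x)` returns the largest length *L* such that sequences
of length ≥ *L* contain at least *x*% of total bases; ties resolve by the
sequence whose inclusion first reaches the threshold (cumulative ≥, not >),
the dominant community definition. An exhaustive oracle (check every
candidate length) backs this in the tests.

`assembly_report()` reports scaffold and contig blocks from one scaffold
input. Contigs are always derived by splitting scaffolds at placeholder N
runs — never read from a second file — so the two blocks are guaranteed to
describe the same sequence set. The exclusion conventions (scaffolds
< 1000 bp and contigs < 200 bp excluded from statistics) follow the
reference-assembly comparison this package was built for; both are
parameters. Note the asymmetry: the scaffold filter does not propagate to
the contig block, so a 900 bp scaffold excluded from scaffold statistics
still contributes its contigs.

`split_scaffolds()` treats an internal N run of length ≥ `min_n_run`
(default 10 bp) as a gap; shorter runs are ordinary ambiguous bases and
stay inside contigs. The assemblies this targets write gaps as exactly
100 Ns, so any threshold ≤ 100 reproduces their structure; 10 separates
"gap" from incidental Ns. Terminal N runs bridge nothing and are trimmed
silently.

# Trimming and the cutoff sweep

`trim_assembly()` removes records strictly shorter than the cutoff
(default 2000 bp, i.e. a 2000 bp record survives a 2 kb trim), and
`cutoff_sweep()` scores a cutoff ladder (default 1–5 kb) by re-running
gene recovery on the hits that survive each trim. One deliberate
definition: sweep means are taken over the *full* gene universe, counting
a gene lost to trimming as coverage 0 and 0 pieces. A mean over recovered
genes only is not monotone in the cutoff (dropping a clean single-piece
gene can raise the mean), and the sweep's purpose is a monotone
cost-of-trimming curve. The cohort summary `summarize_recovery()` keeps
the conventional definition — mean pieces over recovered genes — since it
mirrors how gene-recovery benchmarks are quoted.

# Placeholder-gap validation

Fixed-size placeholder gaps claim "a small gap of unknown size here".
To audit them, scaffolds are split into component contigs, the contigs are
aligned to a reference, alignments are reduced to unambiguous 1:1 pairings,
and `adjacent_separation()` measures the distance on the reference between
the footprints of each adjacent contig pair. In half-open coordinates
abutment gives exactly 0 and overlap is negative; the sign convention is
ours, chosen so that "separation equals true gap size" is an exact
identity on simulated truth.

The 1:1 reduction quantifies "unambiguous": the best target by summed
aligned bp is kept only if the runner-up has < `dominance` (0.5) times its
aligned bp and it covers ≥ `min_query_cov` (0.5) of the query, and a
target claimed by two queries disqualifies both. These numbers are
judgment calls, so they are function arguments and are echoed into every
CLI output header. The one-query-per-target rule exists for contig-scale
references; against chromosome-scale references every contig legitimately
claims the same target, so `unique_targets = FALSE` disables just that
rule. Pairs whose hits disagree in target, strand, or collinear order are
skipped and counted rather than guessed at.

# Spanning contigs and painting

`find_spanning()` calls a target contig "spanned" when one query's
alignments cover ≥ `span_cov` of it; 0.9 operationalizes "spanning the
entirety" while tolerating clipped alignment ends. Requiring ≥ 2 spanned
targets per query makes the count a statement about relative contiguity.
The count is invariant to alignment record order and to splitting an
alignment into abutting pieces (tested), because only coverage unions
enter the decision. `extract_unspanned_intervals()` then returns the query
sequence between consecutive spanned targets — the sequence one assembler
reconstructed where the other broke — ready for low-complexity enrichment.

`paint_chromosomes()` assigns each contig to the chromosome carrying its
maximum-score chain of collinear same-strand alignments. Chaining requires
strictly advancing query and target coordinates (strand-adjusted) with
gaps ≤ `max_join` (100 kb) on both; inversions therefore break chains,
which is the desired behavior for a rough mapping scheme. Score ties are
broken deterministically (lexicographically smallest chromosome, then
leftmost start) and flagged `ambiguous` rather than resolved silently.

# Gene recovery

`score_gene_recovery()` replaces opaque hit post-processing with one
declared rule: rank hits by score (ties: longer gene interval, then
subject id), accept a hit iff it adds ≥ `min_novel` (20 bp) uncovered gene
bases, report covered fraction and accepted-hit count ("pieces"). The
20 bp guard keeps micro-overlapping hits from inflating piece counts; it
is exposed as an argument. Duplication is called from per-subject coverage
over *all* hits (two subjects each singly covering ≥ 0.95), because the
greedy acceptance would otherwise hide a perfect second copy as
"nothing novel". Completeness thresholds (0.95 complete / 0.2 fragmented)
are this package's own; callers supply CDS-only gene models — UTR trimming
is out of scope by construction of the inputs.

Appending a hit that ranks last in acceptance order can only grow coverage
and pieces, and the tests assert exactly that form of monotonicity. A
higher-scoring late addition may legitimately *reorder* acceptance and
lower final coverage (it claims bases first and leaves its overlaps below
the novelty floor), so monotonicity under arbitrary insertion is not
claimed.

# Heterozygosity

The bubble dialect — FASTA with inline `{ALT1|ALT2}` forks, one branch
possibly empty — is defined by this package, with a documented grammar,
because the upstream assembler's on-disk bubble format is not specified
anywhere we could follow. A converter is needed for real assembler output;
the grammar makes the classifier testable in the meantime. Forks with more
than two branches are rejected and counted, not interpreted.

`classify_bubble()` sorts branch pairs into `single_snp` (equal length,
exactly one mismatch), `single_indel` (length difference *d*, longest
common prefix + suffix ≥ shorter length, i.e. one contiguous indel of
length *d*), `mixed`, or `oversize` (longer branch > 12.5 kb, the
tractability cap; applying the cap to the longer branch is our reading).
The prefix/suffix criterion is linear-time and deterministic; the test
suite proves it equivalent to an exhaustive edit-script enumeration on
thousands of seeded pairs.

`partition_variant_density()` assumes contigs absent from the variant
table are homozygous, reports the zero-variant fraction of assembly bp,
the variant rate over the remaining bp, and the implied spacing
`round(1000 / rate)` with halves away from zero — with a rate of 3.66/kb
this yields 273 bases per SNP (1000/3.66 = 273.2).

`detect_haplotype_pairs()` quantifies "two contigs that are really one
locus": union coverage ≥ 0.9 on both, mean identity ≥ 95%, length ratio
≤ 1.25. All three are arguments; the defaults encode "nearly all the
length of both" and "similarly sized" as testable numbers.

# Low complexity and enrichment

`low_complexity_mask()` is a declared, self-contained masker: dinucleotide
Shannon entropy over non-overlapping 64 bp windows, masking below 1.2 bits
(homopolymer 0 bits, perfect dinucleotide repeat 1 bit, random ≈ 4 bits —
so the threshold separates the repeat regime from sequence that is merely
AT-rich). It stands where an external repeat annotator would run in a full
analysis; externally produced annotations are consumed via BED unchanged.
`interval_enrichment()` compares masked fractions inside target intervals
versus the whole genome and attaches a permutation p-value from
length-matched uniformly placed intervals, `(1 + hits) / (1 + n_perm)` so
it is never zero. It takes per-sequence lengths rather than one genome
total so permuted intervals respect sequence ends.

# The simulator and what it does (not) show

The generator's defaults are the study conditions the analyses assume, not
tuning knobs: placeholder gaps of exactly 100 Ns whose true sizes are
uniform on [0, 500] bp (the regime where "the vast majority of gaps are
under 500 bp"), a 39% zero-variant compartment with 3.66 SNPs/kb on the
rest, i.i.d. 45% GC sequence, planted 1.5 kb genes, and haplotype
duplicates at 2% divergence. Fragmentation draws contig lengths uniform on
[0.5, 1.5] × 8 kb, turns each junction into a gap with probability 0.5,
and emits a quarter of scaffolds reverse-complemented so minus-strand
logic is exercised end to end. Every stage is deterministic given its
seed and leaves caller RNG untouched.

Truth alignments are emitted exactly from placements (optionally degraded
by a substitution-rate noise parameter), so cross-module checks are sharp:
separations equal drawn gap sizes exactly, painting reproduces placements
for every contig, planted variants classify to their true type, planted
pairs are recovered with precision and recall 1. What passing these checks
does *not* show: behavior under alignment noise, repeat-induced ambiguous
mappings, real indel alignment artifacts, or base-composition structure
beyond planted tracts — i.i.d. sequence has no transposons, no satellite
arrays, no GC gradients. The simulator validates the arithmetic and the
contracts, not the biology.

Problem sizes in the shipped tests are chosen to keep the full suite in a
couple of minutes on one CPU: a shared 2 Mb end-to-end study, fifty 5 Mb
genomes for the gap-recovery sweep, and 48 Mb of variable-compartment
sequence for the heterozygosity-spacing check. The 48 Mb figure comes from
the sampling arithmetic: the spacing check asks for ±2 bp around 273
(±0.73% on the rate), and at 48 Mb the Poisson standard error on the
recovered rate (~0.24%) makes that a ≥3σ band; at the minimal 2 Mb the
standard error (~1.2%) would exceed the band itself.

# Degenerate inputs and numerical conventions

* Empty files parse to empty tables; writers of canonical files round-trip
  byte-identically.
* Alignment rows whose interval is empty after normalization are rejected
  with a warning, not an error; duplicate FASTA ids, non-IUPAC characters,
  unbalanced fork markup, VCF `POS < 1` and BED `start ≥ end` are errors.
* An all-N scaffold yields zero contigs plus a warning; an assembly fully
  removed by filters yields a zero-filled report plus a warning.
* A cohort with no recovered genes reports mean pieces as `NA`; a genome
  with no masked sequence reports the enrichment ratio as `NA`; an
  assembly with no variable contigs reports rate and spacing as `NA`.
* Lowercase and RNA input are normalized on read (uppercase, U→T) so
  soft-masking case cannot silently change results.

# Known limitations

* The package consumes alignments; it never computes them. Its judgments
  inherit whatever systematic errors the upstream aligner makes.
* The bubble dialect is this package's own; real assembler bubble files
  need conversion.
* The piece-counting rule is declared rather than reverse-engineered from
  any particular benchmark tool; absolute piece counts are comparable
  within this package, not across tools.
* `reduce_one_to_one` resolves ambiguity by dropping, never by splitting a
  query across targets; chimeric contigs are therefore skipped, and the
  skip count is the only trace they leave.
* No rearrangement calling: inversions merely break painting chains.
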