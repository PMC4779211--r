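test_that("simulator output is deterministic given the seed", {
  g1 <- simulate_genome(5e4, 2, lc_tracts = list(count = 2, length = 500),
                        seed = 123)
  g2 <- simulate_genome(5e4, 2, lc_tracts = list(count = 2, length = 500),
                        seed = 123)
  expect_identical(g1, g2)
  g3 <- simulate_genome(5e4, 2, seed = 124)
  expect_false(identical(g1$genome, g3$genome))

  a1 <- fragment_into_assembly(g1, mean_contig = 3000, seed = 5)
  a2 <- fragment_into_assembly(g2, mean_contig = 3000, seed = 5)
  expect_identical(a1, a2)

  # written files are byte-identical across runs with one seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a1$scaffolds, f1)
  write_fasta(a2$scaffolds, f2)
  expect_identical(readLines(f1), readLines(f2))

  v1 <- inject_variants(a1$scaffolds, seed = 9)
  v2 <- inject_variants(a2$scaffolds, seed = 9)
  expect_identical(v1, v2)
})

test_that("simulated genomes have the requested size and GC", {
  g <- simulate_genome(1e5, 3, gc = 0.6, seed = 2)
  expect_identical(sum(nchar(g$genome)), 100000L)
  expect_length(g$genome, 3)
  gc_obs <- sum(vapply(strsplit(g$genome, ""), function(x)
    sum(x %in% c("G", "C")), 0L)) / 1e5
  expect_lt(abs(gc_obs - 0.6), 0.02)
  expect_error(simulate_genome(1e4, 1,
                               lc_tracts = list(count = 100, length = 2000),
                               seed = 1), "exceed")
})

test_that("fragmentation conserves bp and emits exact placeholder runs", {
  g <- simulate_genome(1e6, 2, seed = 31)
  asm <- fragment_into_assembly(g, seed = 32)
  pl <- asm$truth$placements
  expect_equal(sum(pl$end - pl$start) + sum(asm$truth$gaps$true_size),
               sum(nchar(g$genome)))
  # placements tile each chromosome without overlap
  for (ch in names(g$genome)) {
    p <- pl[pl$chrom == ch, ]
    p <- p[order(p$start), ]
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  # every intra-scaffold N run is exactly the placeholder length
  runs <- gregexpr("N+", asm$scaffolds)
  for (r in runs) {
    if (r[1] != -1) expect_true(all(attr(r, "match.length") == 100L))
  }
  # splitting recovers the truth contigs by name and sequence length
  sp <- split_scaffolds(asm$scaffolds)
  expect_setequal(names(sp$contigs), pl$contig_id)
  expect_identical(unname(nchar(sp$contigs[pl$contig_id])),
                   pl$end - pl$start)
})

test_that("truth alignments round-trip through PAF and repaint placements", {
  st <- small_study()
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(st$truth_alns, f)
  back <- read_alignments(f, "paf")
  expect_equal(back[, names(back) != "tags"],
               st$truth_alns[, names(st$truth_alns) != "tags"])

  pa <- paint_chromosomes(st$truth_alns)
  pl <- st$truth$placements
  expect_identical(nrow(pa), nrow(pl))
  idx <- match(pl$contig_id, pa$contig_id)
  expect_identical(pa$chromosome[idx], pl$chrom)
  expect_identical(pa$start[idx], pl$start)
  expect_identical(pa$end[idx], pl$end)
  expect_identical(pa$strand[idx], pl$strand)

  # noisy emission stays parseable and flags lower identity
  noisy <- emit_truth_alignments(st$truth, noise = 0.05, seed = 4)
  expect_true(all(noisy$identity < 100))
  expect_gte(nrow(noisy), nrow(st$truth_alns))
})

test_that("variant injection matches its own truth records", {
  st <- small_study()
  het <- st$het
  # compartment accounting: zero-variant bp + variable bp = total bp
  expect_equal(sum(het$compartments$length),
               sum(nchar(st$scaffolds)))
  zero_ids <- het$compartments$contig_id[het$compartments$compartment == "zero"]
  expect_false(any(het$variants$contig_id %in% zero_ids))
  # the variant table and the bubble lines agree fork-for-fork
  n_forks <- sum(vapply(het$lines, function(l) nrow(l$forks), 0L))
  expect_identical(n_forks, nrow(het$variants))
  # flattening the first branch of every line reproduces the contigs
  flat <- vapply(het$lines, function(l) flatten_bubbles(l, "first")[[1]], "")
  names(flat) <- vapply(het$lines, function(l) l$line_id, "")
  expect_identical(flat[names(st$scaffolds)], st$scaffolds)

  # zero_fraction 1 plants nothing
  v0 <- inject_variants(st$scaffolds[1:5], zero_fraction = 1, seed = 3)
  expect_identical(nrow(v0$variants), 0L)
  expect_true(all(vapply(v0$lines, function(l) nrow(l$forks), 0L) == 0L))

  expect_error(inject_variants(st$scaffolds[1:2], snp_rate = 2000,
                               indel_rate = 0, seed = 1), "per base")
})

test_that("every planted SNP and indel classifies to its true type", {
  st <- small_study()
  cls <- classify_bubbles(st$het$lines)
  # fork order within a line follows position order, as does the truth table
  truth <- st$het$variants
  key_cls <- paste(cls$line_id, cls$fork_index)
  by_line <- split(seq_len(nrow(truth)), truth$contig_id)
  truth$fork_index <- NA_integer_
  for (id in names(by_line)) {
    idx <- by_line[[id]]
    truth$fork_index[idx[order(truth$pos[idx])]] <- seq_along(idx)
  }
  m <- merge(cls, truth,
             by.x = c("line_id", "fork_index"),
             by.y = c("contig_id", "fork_index"))
  expect_identical(nrow(m), nrow(truth))
  expect_true(all(m$class[m$type == "snp"] == "single_snp"))
  expect_true(all(m$class[m$type %in% c("del", "ins")] == "single_indel"))
})

test_that("planted haplotype pairs are recovered exactly", {
  st <- small_study()
  hp <- detect_haplotype_pairs(st$features$self_alns,
                               lengths = nchar(st$assembly))
  got <- paste(hp$contig_a, hp$contig_b)
  want <- paste(st$features$hap_pairs$contig_a, st$features$hap_pairs$contig_b)
  expect_setequal(got, want)

  # no-op planting leaves the assembly unchanged
  p0 <- plant_features(st$scaffolds[1:4], n_genes = 0,
                       hap_dup = list(count = 0, divergence = 0), seed = 1)
  expect_identical(p0$assembly, st$scaffolds[1:4])
  expect_error(plant_features(st$scaffolds[1:2], n_genes = 50, seed = 1),
               "capacity")
})
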