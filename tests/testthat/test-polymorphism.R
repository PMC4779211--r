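test_that("classify_bubble identifies SNPs, indels, mixed and oversize", {
  expect_identical(classify_bubble("A", "C"), "single_snp")
  expect_identical(classify_bubble("ACGT", "ACGGT"), "single_indel")
  expect_identical(classify_bubble("ATA", "GTG"), "mixed")
  expect_identical(classify_bubble(strrep("A", 13000), "A"), "oversize")
  expect_identical(classify_bubble("ACG", ""), "single_indel")
  expect_identical(classify_bubble("AAAA", "AA"), "single_indel")
  expect_identical(classify_bubble("ACGT", "TGCA"), "mixed")
  expect_error(classify_bubble("A", "A"), "identical")
  # the cap applies to the longer branch: at exactly the cap, not oversize
  expect_identical(classify_bubble(strrep("A", 100), "A", size_cap = 100),
                   "single_indel")
})

test_that("classify_bubble agrees with the edit-script oracle", {
  set.seed(90125)
  n_checked <- 0
  while (n_checked < 2000) {
    a <- random_branch(12); b <- random_branch(12)
    if (a == b) next
    expect_identical(classify_bubble(a, b), oracle_bubble(a, b),
                     info = paste(a, b))
    n_checked <- n_checked + 1
  }
})

test_that("flatten_bubbles follows policy and conserves length", {
  bl <- bubble_line("l", c("AA", "TT"),
                    data.frame(branch_a = "C", branch_b = "G"))
  expect_identical(unname(flatten_bubbles(bl, "first")), "AACTT")
  expect_identical(unname(flatten_bubbles(bl, "second")), "AAGTT")
  expect_identical(names(flatten_bubbles(bl, "first")), "l")

  blg <- bubble_line("g", c("AA", "TT"),
                     data.frame(branch_a = "ACG", branch_b = ""))
  expect_identical(nchar(flatten_bubbles(blg, "first")[[1]]), 7L)
  expect_identical(nchar(flatten_bubbles(blg, "second")[[1]]), 4L)

  # random policy is reproducible and respects the seed
  bl2 <- bubble_line("r", c("A", "C", "G", "T", "A"),
                     data.frame(branch_a = rep("T", 4), branch_b = rep("G", 4)))
  expect_identical(flatten_bubbles(bl2, "random", seed = 3),
                   flatten_bubbles(bl2, "random", seed = 3))
  # flatten length identity for all policies
  for (pol in c("first", "second", "random")) {
    s <- flatten_bubbles(bl2, pol)
    chosen_len <- nchar(s[[1]]) - sum(nchar(bl2$blocks))
    expect_true(chosen_len >= 0 && chosen_len <= sum(nchar(bl2$forks$branch_a)))
  }
})

test_that("detect_haplotype_pairs applies coverage/identity/ratio gates", {
  lens <- c(c1 = 10000, c2 = 10200, c3 = 30000, c4 = 10000)
  alns <- rbind(
    alignment_records("c1", 0, 9600, "c2", 200, 9900, "+",
                      identity = 98, aln_len = 9600),
    alignment_records("c4", 0, 10000, "c3", 0, 10000, "+",
                      identity = 99, aln_len = 10000),
    alignment_records("c1", 0, 10000, "c1", 0, 10000, "+",
                      identity = 100, aln_len = 10000))
  hp <- detect_haplotype_pairs(alns, lengths = lens)
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$contig_a, "c1")
  expect_identical(hp$contig_b, "c2")
  expect_gte(hp$cov_a, 0.9)
  # c4-in-c3 containment rejected on the length ratio, self-hit excluded
  expect_false(any(hp$contig_b == "c3"))
  expect_error(detect_haplotype_pairs(alns, lengths = lens[-1]), "missing")
})

test_that("partition_variant_density splits bp and derives spacing", {
  lens <- c(A = 10000, B = 10000)
  vars <- data.frame(contig_id = rep("B", 40), pos = seq(100, 4000, 100),
                     ref = "A", alt = "T")
  p <- partition_variant_density(vars, lens)
  expect_equal(p$zero_fraction, 50.0)
  expect_equal(p$variable_rate, 4.0)
  expect_identical(p$spacing, 250L)
  expect_equal(sum(p$per_contig$length[p$per_contig$n_variants == 0]) +
                 sum(p$per_contig$length[p$per_contig$n_variants > 0]),
               sum(lens))

  p0 <- partition_variant_density(vars[0, ], lens)
  expect_equal(p0$zero_fraction, 100.0)
  expect_true(is.na(p0$variable_rate) && is.na(p0$spacing))

  # 3.66 variants/kb implies one every 273 bases (1000/3.66 = 273.2)
  v366 <- data.frame(contig_id = "C", pos = seq_len(3660), ref = "A",
                     alt = "T")
  p366 <- partition_variant_density(v366, c(C = 1e6))
  expect_equal(p366$variable_rate, 3.66)
  expect_identical(p366$spacing, 273L)

  expect_error(partition_variant_density(vars, c(A = 10000)), "unknown contig")
})

test_that("low_complexity_mask flags repeats and spares random sequence", {
  at <- stats::setNames(strrep("AT", 200), "at")
  m <- low_complexity_mask(at)
  expect_identical(nrow(m), 1L)
  expect_gte(m$end - m$start, 384 - 64)  # nearly the whole 400 bp

  homo <- stats::setNames(strrep("A", 64), "a")
  expect_identical(nrow(low_complexity_mask(homo)), 1L)

  set.seed(8)
  rand <- stats::setNames(paste(sample(c("A", "C", "G", "T"), 10000,
                                       replace = TRUE), collapse = ""), "r")
  mr <- low_complexity_mask(rand)
  expect_lt(sum(mr$end - mr$start), 0.05 * 10000)

  expect_identical(nrow(low_complexity_mask(stats::setNames("ACGT", "s"))), 0L)
})

test_that("planted low-complexity tracts are recovered by the masker", {
  g <- simulate_genome(2e5, 1, lc_tracts = list(count = 3, length = 2000),
                       seed = 55)
  m <- low_complexity_mask_all(g$genome)
  for (i in seq_len(nrow(g$truth$lc_tracts))) {
    tr <- g$truth$lc_tracts[i, ]
    ms <- m[m$seq_id == tr$seq_id, ]
    ov <- sum(pmax(0, pmin(ms$end, tr$end) - pmax(ms$start, tr$start)))
    expect_gte(ov, 0.9 * (tr$end - tr$start))
  }
})

test_that("interval_enrichment computes ratio and permutation p-value", {
  # genome 100 kb with 10 kb masked; 5 kb of targets carrying 2 kb of mask
  masked <- intervals("chr", seq(0, 9000, 1000) * 10, seq(0, 9000, 1000) * 10 + 1000)
  targets <- intervals("chr", c(0, 20000), c(2500, 22500))
  en <- interval_enrichment(masked, targets, c(chr = 100000), n_perm = 200,
                            seed = 9)
  expect_equal(en$genome_frac, 0.1)
  expect_equal(en$target_frac, 0.4)
  expect_equal(en$ratio, 4.0)
  expect_lte(en$p_value, 0.05)

  # strongly enriched targets (fully masked) reach p <= 0.01 at n_perm = 1000
  en2 <- interval_enrichment(masked,
                             intervals("chr", c(0, 10000, 20000, 30000),
                                       c(1000, 11000, 21000, 31000)),
                             c(chr = 100000), n_perm = 1000, seed = 10)
  expect_lte(en2$p_value, 0.01)

  # null targets: ratio near 1, p not extreme
  null_t <- intervals("chr", seq(500, 90500, 10000), seq(500, 90500, 10000) + 5000)
  en3 <- interval_enrichment(masked, null_t, c(chr = 100000), n_perm = 500,
                             seed = 11)
  expect_lt(abs(en3$ratio - 1), 0.35)
  expect_gt(en3$p_value, 0.05)

  # no masked sequence at all: ratio reported absent
  en4 <- interval_enrichment(masked[0, ], targets, c(chr = 100000),
                             n_perm = 50, seed = 12)
  expect_true(is.na(en4$ratio))
})
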