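mk_aln <- function(q, qs, qe, t, ts, te, strand = "+", identity = 100,
                   q_len = NA_integer_, t_len = NA_integer_) {
  alignment_records(query_id = q, q_start = qs, q_end = qe, target_id = t,
                    t_start = ts, t_end = te, strand = strand,
                    identity = identity, q_len = q_len, t_len = t_len)
}

test_that("filter_alignments enforces both thresholds", {
  a <- rbind(mk_aln("q", 0, 400, "t", 0, 400, identity = 99),
             mk_aln("q", 0, 600, "t", 0, 600, identity = 85),
             mk_aln("q", 0, 600, "t", 0, 600, identity = 95))
  f <- filter_alignments(a)
  expect_identical(nrow(f), 1L)
  expect_equal(f$identity, 95)
})

test_that("reduce_one_to_one keeps dominant covered pairings only", {
  a <- rbind(
    mk_aln("q1", 0, 5000, "t1", 0, 5000, q_len = 6000),   # dominant, 83% cov
    mk_aln("q1", 100, 400, "t2", 0, 300, q_len = 6000),   # 300 < 0.5 * 5000
    mk_aln("q2", 0, 2000, "t3", 0, 2000, q_len = 2500),   # ambiguous vs t4
    mk_aln("q2", 0, 1900, "t4", 0, 1900, q_len = 2500),
    mk_aln("q3", 0, 1000, "t5", 0, 1000, q_len = 1000))   # single full hit
  r <- reduce_one_to_one(a)
  pairs <- attr(r, "pairs")
  expect_setequal(pairs$query_id, c("q1", "q3"))
  expect_identical(pairs$target_id[pairs$query_id == "q1"], "t1")
  # at most one target per query, one query per target
  expect_false(anyDuplicated(pairs$query_id) > 0)
  expect_false(anyDuplicated(pairs$target_id) > 0)
})

test_that("reduce_one_to_one drops low-coverage and contested claims", {
  low <- mk_aln("q1", 0, 400, "t1", 0, 400, q_len = 1000)  # 40% < 50%
  expect_identical(nrow(reduce_one_to_one(low)), 0L)
  contested <- rbind(mk_aln("qa", 0, 900, "t1", 0, 900, q_len = 1000),
                     mk_aln("qb", 0, 900, "t1", 1000, 1900, q_len = 1000))
  expect_identical(nrow(reduce_one_to_one(contested)), 0L)
  expect_identical(nrow(reduce_one_to_one(contested, unique_targets = FALSE)),
                   2L)
})

mk_split <- function(left, right, scaffold = "s1", gap_len = 100L) {
  list(contigs = NULL,
       gaps = data.frame(scaffold_id = scaffold, start = 0L,
                         end = gap_len, length = gap_len,
                         left_contig = left, right_contig = right,
                         stringsAsFactors = FALSE))
}

test_that("adjacent_separation measures half-open target distance", {
  sp <- mk_split("s1.1", "s1.2")
  oto <- rbind(mk_aln("s1.1", 0, 1000, "T", 1000, 2000),
               mk_aln("s1.2", 0, 850, "T", 2150, 3000))
  out <- adjacent_separation(sp, oto)
  expect_identical(out$separation, 150L)
  expect_identical(out$placeholder_len, 100L)

  # abutting blocks separate by exactly 0
  oto0 <- rbind(mk_aln("s1.1", 0, 1000, "T", 1000, 2000),
                mk_aln("s1.2", 0, 1000, "T", 2000, 3000))
  expect_identical(adjacent_separation(sp, oto0)$separation, 0L)

  # minus strand reverses the target order of the pair
  otom <- rbind(mk_aln("s1.1", 0, 850, "T", 2150, 3000, strand = "-"),
                mk_aln("s1.2", 0, 1000, "T", 1000, 2000, strand = "-"))
  expect_identical(adjacent_separation(sp, otom)$separation, 150L)
})

test_that("adjacent_separation skips target/strand/collinearity violations", {
  sp <- mk_split("s1.1", "s1.2")
  mixed_target <- rbind(mk_aln("s1.1", 0, 1000, "T1", 0, 1000),
                        mk_aln("s1.2", 0, 1000, "T2", 0, 1000))
  out <- adjacent_separation(sp, mixed_target)
  expect_identical(nrow(out), 0L)
  expect_identical(attr(out, "n_skipped"), 1L)
  # anti-collinear order on the plus strand is skipped too
  backwards <- rbind(mk_aln("s1.1", 0, 1000, "T", 2000, 3000),
                     mk_aln("s1.2", 0, 1000, "T", 0, 1000))
  expect_identical(attr(adjacent_separation(sp, backwards), "n_skipped"), 1L)
})

test_that("find_spanning applies the coverage threshold per target", {
  tl <- c(T1 = 1000, T2 = 1000)
  a <- rbind(mk_aln("Q", 0, 950, "T1", 0, 950),
             mk_aln("Q", 1100, 2020, "T2", 40, 960))
  sp <- find_spanning(a, target_lengths = tl)
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$target_id[order(sp$rank)], c("T1", "T2"))

  a2 <- rbind(mk_aln("Q", 0, 950, "T1", 0, 950),
              mk_aln("Q", 1100, 1600, "T2", 0, 500))
  expect_identical(nrow(find_spanning(a2, target_lengths = tl)), 0L)
  expect_error(find_spanning(a, target_lengths = c(T1 = 1000)), "missing")
})

test_that("spanning count is invariant to row order and block splitting", {
  tl <- stats::setNames(rep(1000, 8), paste0("T", 1:8))
  rows <- lapply(1:8, function(i) {
    mk_aln("Q", (i - 1) * 1100, (i - 1) * 1100 + 1000, paste0("T", i), 0, 1000)
  })
  a <- do.call(rbind, rows)
  sp <- find_spanning(a, target_lengths = tl)
  expect_identical(nrow(sp), 8L)
  # shuffle rows
  sp2 <- find_spanning(a[sample(nrow(a)), ], target_lengths = tl)
  expect_identical(nrow(sp2), 8L)
  # split the first alignment into two abutting pieces
  split1 <- rbind(mk_aln("Q", 0, 400, "T1", 0, 400),
                  mk_aln("Q", 400, 1000, "T1", 400, 1000),
                  a[-1, ])
  sp3 <- find_spanning(split1, target_lengths = tl)
  expect_identical(nrow(sp3), 8L)
  expect_identical(sp3$covered_frac, sp$covered_frac)
})

test_that("extract_unspanned_intervals emits inter-block query gaps", {
  tl <- c(T1 = 1000, T2 = 1000, T3 = 500)
  a <- rbind(mk_aln("Q", 0, 1000, "T1", 0, 1000),
             mk_aln("Q", 1200, 2200, "T2", 0, 1000),
             mk_aln("Q", 2200, 2700, "T3", 0, 500))
  sp <- find_spanning(a, target_lengths = tl)
  iv <- extract_unspanned_intervals(sp)
  # 3 targets -> 2 candidate intervals, one abutting pair omitted
  expect_identical(nrow(iv), 1L)
  expect_identical(iv$start, 1000L)
  expect_identical(iv$end, 1200L)
  expect_identical(attr(iv, "n_empty"), 1L)
  # interval lengths never exceed the query span
  expect_lte(sum(iv$end - iv$start) +
               sum(sp$q_end - sp$q_start),
             max(sp$q_end) - min(sp$q_start))
})

test_that("paint_chromosomes chains joinable blocks and breaks ties", {
  a <- rbind(mk_aln("c1", 0, 100, "chr2", 100, 200),
             mk_aln("c1", 105, 195, "chr2", 210, 300),
             mk_aln("c1", 300, 330, "chr3", 50, 80))
  p <- paint_chromosomes(a)
  expect_identical(p$chromosome, "chr2")
  expect_identical(p$start, 100L)
  expect_identical(p$end, 300L)
  expect_equal(p$score, 190)
  expect_false(p$ambiguous)

  single <- mk_aln("c2", 0, 50, "chrX", 10, 60)
  p1 <- paint_chromosomes(single)
  expect_identical(p1$chromosome, "chrX")
  expect_equal(p1$score, 50)

  # equal-score chains: lexicographically smallest chromosome, flagged
  tie <- rbind(mk_aln("c3", 0, 100, "chr5", 0, 100),
               mk_aln("c3", 0, 100, "chr4", 900, 1000))
  pt <- paint_chromosomes(tie)
  expect_identical(pt$chromosome, "chr4")
  expect_true(pt$ambiguous)

  # gaps beyond max_join break the chain
  far <- rbind(mk_aln("c4", 0, 100, "chr1", 0, 100),
               mk_aln("c4", 110, 210, "chr1", 500000, 500100))
  pf <- paint_chromosomes(far, max_join = 1000)
  expect_equal(pf$score, 100)
  expect_identical(pf$n_blocks, 1L)
})
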