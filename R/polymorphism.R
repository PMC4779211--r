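#' Classify a biallelic bubble by its branch pair
#'
#' A bubble (fork in the de Bruijn graph) holds two branch alleles over the
#' same flanks. Classes: `oversize` when the longer branch exceeds
#' `size_cap`; `single_snp` when the branches have equal length and differ
#' at exactly one position; `single_indel` when the lengths differ by
#' `d > 0` and the branches share a prefix plus suffix at least as long as
#' the shorter branch (one contiguous inserted/deleted block of length
#' `d`); otherwise `mixed` (a combination of SNPs and indels with
#' interspersed invariant sequence). The prefix/suffix criterion is
#' deterministic and linear-time, and equivalent to "single contiguous
#' indel" under any alignment (oracle-tested in the suite).
#'
#' @param branch_a,branch_b Branch allele strings over `{A,C,G,T}`; one may
#'   be empty (a pure gap allele).
#' @param size_cap Maximum branch length (bp) before the bubble is set
#'   aside as `oversize`; applies to the longer branch.
#' @return One of `"single_snp"`, `"single_indel"`, `"mixed"`, `"oversize"`.
#' @examples
#' classify_bubble("A", "C")        # single_snp
#' classify_bubble("ACGT", "ACGGT") # single_indel
#' classify_bubble("ATA", "GTG")    # mixed
#' @export
classify_bubble <- function(branch_a, branch_b, size_cap = 12500L) {
  if (branch_a == branch_b) {
    stop("bubble with identical branches", call. = FALSE)
  }
  la <- nchar(branch_a); lb <- nchar(branch_b)
  if (max(la, lb) > size_cap) return("oversize")
  if (la == lb) {
    a <- charToRaw(branch_a); b <- charToRaw(branch_b)
    return(if (sum(a != b) == 1L) "single_snp" else "mixed")
  }
  shorter <- if (la < lb) branch_a else branch_b
  longer <- if (la < lb) branch_b else branch_a
  ls <- nchar(shorter)
  if (ls == 0L) return("single_indel")
  s <- charToRaw(shorter); l <- charToRaw(longer)
  lcp <- 0L
  while (lcp < ls && s[lcp + 1L] == l[lcp + 1L]) lcp <- lcp + 1L
  lcs <- 0L
  ll <- length(l)
  while (lcs < ls && s[ls - lcs] == l[ll - lcs]) lcs <- lcs + 1L
  if (lcp + lcs >= ls) "single_indel" else "mixed"
}

#' Classify every fork in a set of bubble lines
#'
#' @param lines List of [bubble_line()] objects.
#' @param size_cap Passed to [classify_bubble()].
#' @return `data.frame(line_id, fork_index, offset, branch_a, branch_b,
#'   class)`; `offset` is the 0-based fork position on the line flattened
#'   with the first branch of every upstream fork.
#' @export
classify_bubbles <- function(lines, size_cap = 12500L) {
  rows <- lapply(lines, function(bl) {
    n <- nrow(bl$forks)
    if (n == 0L) return(NULL)
    block_len <- nchar(bl$blocks)
    a_len <- nchar(bl$forks$branch_a)
    offset <- cumsum(c(0L, a_len[-n])) + cumsum(block_len[seq_len(n)])
    data.frame(line_id = bl$line_id, fork_index = seq_len(n),
               offset = offset,
               branch_a = bl$forks$branch_a, branch_b = bl$forks$branch_b,
               class = mapply(classify_bubble, bl$forks$branch_a,
                              bl$forks$branch_b,
                              MoreArgs = list(size_cap = size_cap)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(line_id = character(), fork_index = integer(),
                      offset = integer(), branch_a = character(),
                      branch_b = character(), class = character())
  }
  rownames(out) <- NULL
  out
}

#' Flatten a bubble line into a plain sequence
#'
#' Chooses one branch per fork (`first`, `second`, or seeded `random`) and
#' concatenates it with the invariant blocks — the operation an assembler
#' applies when it commits bubbles into the final assembly.
#'
#' @param line A [bubble_line()].
#' @param policy Branch choice policy.
#' @param seed Seed for the `random` policy (reproducible; caller RNG is
#'   untouched).
#' @return Named character vector of length 1 (a sequence record).
#' @export
flatten_bubbles <- function(line, policy = c("first", "second", "random"),
                            seed = 17L) {
  policy <- match.arg(policy)
  n <- nrow(line$forks)
  pick <- switch(policy,
    first = rep(TRUE, n),
    second = rep(FALSE, n),
    random = with_seed(seed, stats::runif(n) < 0.5))
  chosen <- ifelse(pick, line$forks$branch_a, line$forks$branch_b)
  out <- paste0(paste0(line$blocks[seq_len(n)], chosen, collapse = ""),
                line$blocks[n + 1L])
  stats::setNames(out, line$line_id)
}

#' Detect separately assembled haplotype contig pairs
#'
#' Finds pairs of contigs that align very well to one another over nearly
#' the whole length of both and are similarly sized — the signature of the
#' maternal and paternal copies of a locus kept as two contigs. Trivial
#' self-hits are discarded; for each remaining unordered pair the union
#' alignment coverage is computed on each contig and the pair is reported
#' iff both coverages reach `min_cov`, the length ratio (longer/shorter) is
#' at most `max_ratio`, and the alignment-length-weighted mean identity is
#' at least `min_identity`.
#'
#' @param self_alns Assembly-vs-itself alignment records.
#' @param min_cov Minimum union coverage fraction on both contigs.
#' @param min_identity Minimum mean percent identity.
#' @param max_ratio Maximum length ratio.
#' @param lengths Named vector of contig lengths (bp).
#' @return `data.frame(contig_a, contig_b, cov_a, cov_b, mean_identity,
#'   length_ratio)` with `contig_a < contig_b`, each pair once.
#' @export
detect_haplotype_pairs <- function(self_alns, min_cov = 0.9,
                                   min_identity = 95, max_ratio = 1.25,
                                   lengths) {
  a <- self_alns[self_alns$query_id != self_alns$target_id, , drop = FALSE]
  empty <- data.frame(contig_a = character(), contig_b = character(),
                      cov_a = numeric(), cov_b = numeric(),
                      mean_identity = numeric(), length_ratio = numeric())
  if (nrow(a) == 0L) return(empty)
  need <- unique(c(a$query_id, a$target_id))
  if (length(setdiff(need, names(lengths))) > 0L) {
    stop("missing contig length for: ",
         paste(utils::head(setdiff(need, names(lengths)), 3L), collapse = ", "),
         call. = FALSE)
  }
  ca <- pmin(a$query_id, a$target_id)
  cb <- pmax(a$query_id, a$target_id)
  rows <- lapply(split(seq_len(nrow(a)), paste(ca, cb, sep = "\r")),
    function(idx) {
      p <- sort(c(a$query_id[idx][1L], a$target_id[idx][1L]))
      cov_on <- function(ctg) {
        qi <- idx[a$query_id[idx] == ctg]
        ti <- idx[a$target_id[idx] == ctg]
        union_len(c(a$q_start[qi], a$t_start[ti]),
                  c(a$q_end[qi], a$t_end[ti])) / as.numeric(lengths[[ctg]])
      }
      data.frame(contig_a = p[1L], contig_b = p[2L],
                 cov_a = cov_on(p[1L]), cov_b = cov_on(p[2L]),
                 mean_identity = stats::weighted.mean(a$identity[idx],
                                                      a$aln_len[idx]),
                 length_ratio = max(lengths[[p[1L]]], lengths[[p[2L]]]) /
                   min(lengths[[p[1L]]], lengths[[p[2L]]]),
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, rows)
  out <- out[out$cov_a >= min_cov & out$cov_b >= min_cov &
               out$length_ratio <= max_ratio &
               out$mean_identity >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition assembly bp by per-contig variant density
#'
#' Splits an assembly into a monomorphic compartment (contigs with no
#' variants, assumed homozygous) and a polymorphic one, and reports the
#' zero-variant fraction of total bp, the SNP rate over the remaining bp,
#' and the implied bases-per-SNP spacing (`round(1000 / rate)`, halves away
#' from zero).
#'
#' @param variants Variant table from [read_variants()].
#' @param contig_lengths Named vector of contig lengths (bp); contigs absent
#'   from `variants` count as zero-variant.
#' @return List: `zero_fraction` (percent of bp), `variable_rate` (variants
#'   per kb; `NA` when no variable contigs), `spacing` (bp per variant;
#'   `NA` likewise), `per_contig` (`data.frame(contig_id, length, n_variants,
#'   density)`, density in variants/kb).
#' @export
partition_variant_density <- function(variants, contig_lengths) {
  unknown <- setdiff(unique(variants$contig_id), names(contig_lengths))
  if (length(unknown) > 0L) {
    stop("variant on unknown contig: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(variants$contig_id, levels = names(contig_lengths)))
  per_contig <- data.frame(contig_id = names(contig_lengths),
                           length = as.numeric(contig_lengths),
                           n_variants = as.integer(counts),
                           stringsAsFactors = FALSE)
  per_contig$density <- 1000 * per_contig$n_variants / per_contig$length
  total <- sum(per_contig$length)
  zero_bp <- sum(per_contig$length[per_contig$n_variants == 0L])
  variable_bp <- total - zero_bp
  variable_rate <- if (variable_bp > 0) {
    1000 * sum(per_contig$n_variants) / variable_bp
  } else NA_real_
  list(zero_fraction = 100 * zero_bp / total,
       variable_rate = variable_rate,
       spacing = if (!is.na(variable_rate) && variable_rate > 0) {
         as.integer(round_half_away(1000 / variable_rate))
       } else NA_integer_,
       per_contig = per_contig)
}

#' Mask low-complexity sequence by dinucleotide entropy
#'
#' A self-contained low-complexity masker: the sequence is scanned in
#' non-overlapping windows and a window is masked when the Shannon entropy
#' of its overlapping dinucleotides falls below `entropy_min` bits
#' (homopolymers score 0 bits, dinucleotide repeats 1 bit, random sequence
#' about 4 bits). Adjacent masked windows are merged. Externally produced
#' repeat annotations can be supplied instead via [read_intervals()].
#'
#' @param seq Named character vector of length 1, or a bare string.
#' @param window Window size (bp), `>= 4`.
#' @param entropy_min Entropy threshold (bits).
#' @return Interval `data.frame` of masked regions (label
#'   `"low_complexity"`); empty when the sequence is shorter than `window`.
#' @export
low_complexity_mask <- function(seq, window = 64L, entropy_min = 1.2) {
  stopifnot(window >= 4L)
  seq_id <- names(seq) %||% "seq"
  s <- unname(seq[[1L]])
  n <- nchar(s)
  if (n < window) return(intervals(character(), integer(), integer()))
  code <- match(strsplit(chartr("ACGT", "0123", s), "", fixed = TRUE)[[1L]],
                c("0", "1", "2", "3")) - 1L
  d <- 4L * code[-n] + code[-1L]             # dinucleotide codes, NA at N etc.
  W <- n %/% window
  pos <- seq_len(n - 1L)
  g <- (pos - 1L) %/% window + 1L
  keep <- pos %% window != 0L & g <= W & !is.na(d)  # drop bridging dinucs
  cnt <- matrix(tabulate(g[keep] + W * d[keep], nbins = 16L * W), nrow = W)
  tot <- rowSums(cnt)
  p <- cnt / pmax(tot, 1L)
  ent <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  masked <- ent < entropy_min & tot >= window %/% 2L
  if (!any(masked)) return(intervals(character(), integer(), integer()))
  merged <- reduce_intervals((which(masked) - 1L) * window,
                             which(masked) * window)
  intervals(seq_id, merged$start, merged$end, "low_complexity")
}

#' Low-complexity masking over a whole assembly
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams low_complexity_mask
#' @export
low_complexity_mask_all <- function(seqs, window = 64L, entropy_min = 1.2) {
  out <- do.call(rbind, lapply(names(seqs), function(id) {
    low_complexity_mask(stats::setNames(seqs[id], id), window, entropy_min)
  }))
  if (is.null(out)) out <- intervals(character(), integer(), integer())
  out
}

#' Enrichment of masked sequence inside target intervals
#'
#' Tests whether target intervals (e.g. sequence found between adjacent
#' reference contigs) carry more masked low-complexity sequence than the
#' genome at large. The ratio is target masked fraction over genome masked
#' fraction; significance comes from placing length-matched random
#' intervals uniformly across the sequences (seeded) and counting permuted
#' fractions at least as large as the observed one
#' (`p = (1 + hits) / (1 + n_perm)`).
#'
#' @param masked Masked intervals ([intervals()]).
#' @param targets Target intervals.
#' @param seq_lengths Named vector of sequence lengths; the genome total is
#'   their sum.
#' @param n_perm Number of permutations.
#' @param seed RNG seed (caller RNG untouched).
#' @return List: `target_frac`, `genome_frac`, `ratio` (`NA` when the
#'   genome masked fraction is zero), `p_value`, `n_perm`.
#' @export
interval_enrichment <- function(masked, targets, seq_lengths,
                                n_perm = 1000L, seed = 17L) {
  genome_total <- sum(as.numeric(seq_lengths))
  masked_bp <- 0
  for (sid in unique(masked$seq_id)) {
    m <- masked[masked$seq_id == sid, ]
    masked_bp <- masked_bp + union_len(m$start, m$end)
  }
  genome_frac <- masked_bp / genome_total
  frac_in <- function(tg) {
    tot <- 0; hit <- 0
    for (sid in unique(tg$seq_id)) {
      t <- tg[tg$seq_id == sid, ]
      m <- masked[masked$seq_id == sid, ]
      tot <- tot + union_len(t$start, t$end)
      hit <- hit + intersect_len(m$start, m$end, t$start, t$end)
    }
    if (tot == 0) return(NA_real_)
    hit / tot
  }
  target_frac <- frac_in(targets)
  widths <- targets$end - targets$start
  perm_frac <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      placed <- lapply(widths, function(w) {
        fits <- names(seq_lengths)[seq_lengths >= w]
        room <- seq_lengths[fits] - w + 1
        sid <- sample(fits, 1L, prob = room / sum(room))
        st <- sample.int(seq_lengths[[sid]] - w + 1L, 1L) - 1L
        data.frame(seq_id = sid, start = st, end = st + w,
                   stringsAsFactors = FALSE)
      })
      frac_in(do.call(rbind, placed))
    }, 0)
  })
  list(target_frac = target_frac,
       genome_frac = genome_frac,
       ratio = if (genome_frac > 0) target_frac / genome_frac else NA_real_,
       p_value = (1 + sum(perm_frac >= target_frac)) / (1 + n_perm),
       n_perm = n_perm)
}
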