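# Independent oracles used to check the package implementations, kept
# deliberately naive: enumeration and set arithmetic, no shared code paths.

# Nx by exhaustive candidate check: the largest length L such that
# sequences of length >= L hold at least x% of total bases.
oracle_nx <- function(lengths, x) {
  total <- sum(lengths)
  best <- NA
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= x / 100 * total) best <- L
  }
  best
}

# Bubble classification by exhaustive edit-script enumeration: a pair is a
# single contiguous indel iff some split point of the shorter branch aligns
# it as prefix + gap + suffix of the longer; a single SNP iff equal lengths
# with exactly one mismatching position.
oracle_bubble <- function(a, b, size_cap = 12500) {
  la <- nchar(a); lb <- nchar(b)
  if (max(la, lb) > size_cap) return("oversize")
  if (la == lb) {
    mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    return(if (mism == 1) "single_snp" else "mixed")
  }
  shorter <- if (la < lb) a else b
  longer <- if (la < lb) b else a
  ls <- nchar(shorter); ll <- nchar(longer)
  for (k in 0:ls) {
    pre_ok <- k == 0 || substr(longer, 1, k) == substr(shorter, 1, k)
    suf_ok <- k == ls ||
      substr(longer, ll - (ls - k) + 1, ll) == substr(shorter, k + 1, ls)
    if (pre_ok && suf_ok) return("single_indel")
  }
  "mixed"
}

# Gene recovery by set arithmetic under the declared acceptance order:
# novel coverage is computed with explicit position sets.
oracle_gene_recovery <- function(gene_len, hits, min_novel = 20) {
  ord <- order(-hits$score, -(hits$g_end - hits$g_start), hits$subject_id)
  covered <- integer(0)
  pieces <- 0
  for (i in ord) {
    span <- seq(hits$g_start[i] + 1, hits$g_end[i])
    if (length(setdiff(span, covered)) >= min_novel) {
      covered <- union(covered, span)
      pieces <- pieces + 1
    }
  }
  list(coverage = length(covered) / gene_len, pieces = pieces)
}

random_branch <- function(max_len = 12) {
  n <- sample(0:max_len, 1)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small end-to-end study shared across test files (built once per run).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(genome_length = 2e6, n_chromosomes = 2,
                               n_genes = 40, hap_dup = list(count = 4,
                                                            divergence = 0.02),
                               seed = 424242)
    }
    cache
  }
})
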