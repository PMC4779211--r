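#' Filter alignments by length and identity
#'
#' Drops very short or low-quality alignments before any comparative
#' analysis. The defaults quantify a judgment call and are recorded in every
#' report this package writes.
#'
#' @param alns Alignment records ([alignment_records()]).
#' @param min_len Minimum alignment block length (bp).
#' @param min_identity Minimum percent identity.
#' @return Filtered alignment records, order preserved.
#' @export
filter_alignments <- function(alns, min_len = 500L, min_identity = 90) {
  alns[alns$aln_len >= min_len & alns$identity >= min_identity, , drop = FALSE]
}

#' Reduce alignments to unambiguous 1:1 query-target pairings
#'
#' Per query, hits are grouped by target and targets ranked by summed
#' aligned bp. The best target is retained only when the second-best target
#' accrues strictly less than `dominance` times the best's aligned bp, and
#' the best target's hits cover at least `min_query_cov` of the query.
#' Queries failing either test are dropped entirely, and when two queries
#' claim the same best target, both are dropped — the result is a partial
#' bijection between queries and targets.
#'
#' @param alns Filtered alignment records.
#' @param dominance Maximum second-best/best aligned-bp ratio.
#' @param min_query_cov Minimum fraction of the query covered by the best
#'   target's hits.
#' @param query_lengths Optional named vector of query lengths; taken from
#'   the records' `q_len` column when omitted.
#' @param unique_targets Enforce the one-query-per-target rule. Keep the
#'   default when the reference is another contig set; set `FALSE` when the
#'   reference is chromosome-scale, where many queries legitimately claim
#'   the same target sequence.
#' @return Alignment records restricted to the surviving query/target pairs;
#'   attribute `pairs` holds the `data.frame(query_id, target_id)` mapping.
#' @export
reduce_one_to_one <- function(alns, dominance = 0.5, min_query_cov = 0.5,
                              query_lengths = NULL, unique_targets = TRUE) {
  if (nrow(alns) == 0L) return(alns)
  qlen_of <- function(q, rows) {
    if (!is.null(query_lengths)) {
      if (is.na(query_lengths[q] %||% NA)) {
        stop("no query length for '", q, "'", call. = FALSE)
      }
      return(as.numeric(query_lengths[[q]]))
    }
    ql <- alns$q_len[rows][!is.na(alns$q_len[rows])]
    if (length(ql) == 0L) {
      stop("no query length available for '", q,
           "'; supply query_lengths", call. = FALSE)
    }
    as.numeric(ql[1L])
  }
  per_query <- split(seq_len(nrow(alns)), alns$query_id)
  claims <- lapply(names(per_query), function(q) {
    rows <- per_query[[q]]
    bp <- vapply(split(rows, alns$target_id[rows]),
                 function(idx) sum(as.numeric(alns$aln_len[idx])), 0)
    bp <- sort(bp, decreasing = TRUE)
    best <- names(bp)[1L]
    second_bp <- if (length(bp) > 1L) bp[2L] else 0
    if (second_bp >= dominance * bp[1L]) return(NULL)
    best_rows <- rows[alns$target_id[rows] == best]
    cov <- union_len(alns$q_start[best_rows], alns$q_end[best_rows]) /
      qlen_of(q, rows)
    if (cov < min_query_cov) return(NULL)
    list(query = q, target = best, rows = best_rows)
  })
  claims <- claims[!vapply(claims, is.null, TRUE)]
  if (unique_targets && length(claims) > 0L) {
    targets <- vapply(claims, `[[`, "", "target")
    contested <- targets[duplicated(targets)]
    claims <- claims[!targets %in% contested]
  }
  out <- alns[unlist(lapply(claims, `[[`, "rows")), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs") <- data.frame(
    query_id = vapply(claims, `[[`, "", "query"),
    target_id = vapply(claims, `[[`, "", "target"),
    stringsAsFactors = FALSE)
  out
}

#' Separation on the reference between adjacent scaffold contigs
#'
#' Validates placeholder scaffold gaps: for each adjacent pair of component
#' contigs whose unambiguous 1:1 hits share target and strand and are
#' collinear in scaffold order (order reversed on the minus strand), the
#' separation is the half-open distance between their alignment footprints
#' on the target — so abutment gives 0 and overlap is negative. Compared
#' with the placeholder N-run length, this measures how well fixed-size
#' placeholders approximate real gap sizes. Pairs violating the
#' target/strand/collinearity requirements are skipped and counted
#' (attribute `n_skipped`).
#'
#' @param split Output of [split_scaffolds()] (contigs + gaps).
#' @param one_to_one Alignment records from [reduce_one_to_one()], at most
#'   one target per component contig.
#' @return `data.frame(scaffold_id, left_contig, right_contig, target_id,
#'   strand, separation, placeholder_len)`.
#' @export
adjacent_separation <- function(split, one_to_one) {
  gaps <- split$gaps
  if (anyDuplicated(unique(one_to_one[, c("query_id", "target_id")])$query_id)) {
    stop("one_to_one carries multiple targets for one contig", call. = FALSE)
  }
  # alignment footprint per contig: target, strand, [min t_start, max t_end)
  foot <- do.call(rbind, lapply(split(one_to_one, one_to_one$query_id),
    function(a) data.frame(query_id = a$query_id[1L],
                           target_id = a$target_id[1L],
                           strand = a$strand[1L],
                           t_start = min(a$t_start), t_end = max(a$t_end),
                           stringsAsFactors = FALSE)))
  n_skipped <- 0L
  rows <- vector("list", nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    li <- match(gaps$left_contig[i], foot$query_id)
    ri <- match(gaps$right_contig[i], foot$query_id)
    if (is.na(li) || is.na(ri) ||
        foot$target_id[li] != foot$target_id[ri] ||
        foot$strand[li] != foot$strand[ri]) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (foot$strand[li] == "+") {
      collinear <- foot$t_start[ri] > foot$t_start[li] &&
        foot$t_end[ri] > foot$t_end[li]
      sep <- foot$t_start[ri] - foot$t_end[li]
    } else {
      collinear <- foot$t_start[li] > foot$t_start[ri] &&
        foot$t_end[li] > foot$t_end[ri]
      sep <- foot$t_start[li] - foot$t_end[ri]
    }
    if (!collinear) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- data.frame(scaffold_id = gaps$scaffold_id[i],
                            left_contig = gaps$left_contig[i],
                            right_contig = gaps$right_contig[i],
                            target_id = foot$target_id[li],
                            strand = foot$strand[li],
                            separation = sep,
                            placeholder_len = gaps$length[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(scaffold_id = character(), left_contig = character(),
                      right_contig = character(), target_id = character(),
                      strand = character(), separation = integer(),
                      placeholder_len = integer())
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Find contigs of one assembly spanning multiple contigs of another
#'
#' A target contig is "spanned" by a query when the union of the query's
#' alignments to it covers at least `span_cov` of the target's length; a
#' query spanning two or more targets yields one span record per spanned
#' target, ordered along the query. Counting such queries in both alignment
#' directions compares the local contiguity of two assemblies.
#'
#' @param alns Filtered A-vs-B alignment records.
#' @param span_cov Minimum covered fraction of a target to call it spanned.
#' @param target_lengths Named vector of target lengths (bp).
#' @return `data.frame(spanning_contig, target_id, covered_frac, q_start,
#'   q_end, rank)`; `q_start/q_end` bound the target's aligned blocks on the
#'   query and `rank` orders targets along the query.
#' @export
find_spanning <- function(alns, span_cov = 0.9, target_lengths) {
  missing_t <- setdiff(unique(alns$target_id), names(target_lengths))
  if (length(missing_t) > 0L) {
    stop("missing target length for: ",
         paste(utils::head(missing_t, 3L), collapse = ", "), call. = FALSE)
  }
  if (nrow(alns) == 0L) {
    return(data.frame(spanning_contig = character(), target_id = character(),
                      covered_frac = numeric(), q_start = integer(),
                      q_end = integer(), rank = integer()))
  }
  key <- paste(alns$query_id, alns$target_id, sep = "\r")
  per_pair <- split(seq_len(nrow(alns)), key)
  pair_rows <- lapply(per_pair, function(idx) {
    tid <- alns$target_id[idx][1L]
    data.frame(spanning_contig = alns$query_id[idx][1L], target_id = tid,
               covered_frac = union_len(alns$t_start[idx], alns$t_end[idx]) /
                 as.numeric(target_lengths[[tid]]),
               q_start = min(alns$q_start[idx]), q_end = max(alns$q_end[idx]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  pairs <- pairs[pairs$covered_frac >= span_cov, , drop = FALSE]
  counts <- table(pairs$spanning_contig)
  pairs <- pairs[pairs$spanning_contig %in% names(counts)[counts >= 2L], ,
                 drop = FALSE]
  pairs <- pairs[order(pairs$spanning_contig, pairs$q_start, pairs$q_end), ,
                 drop = FALSE]
  pairs$rank <- stats::ave(seq_len(nrow(pairs)), pairs$spanning_contig,
                           FUN = seq_along)
  rownames(pairs) <- NULL
  pairs
}

#' Extract query intervals between consecutive spanned targets
#'
#' For a spanning contig, returns the query sequence intervals lying between
#' the aligned blocks of consecutive spanned targets — the sequence one
#' assembly contains that the other breaks at. Zero-length (abutting) and
#' clipped-to-empty (overlapping) intervals are omitted; the omitted count
#' is attached as attribute `n_empty`.
#'
#' @param span Span records from [find_spanning()] (one or more contigs).
#' @return Interval `data.frame` (`seq_id` = spanning contig, 0-based
#'   half-open), label `"unspanned"`.
#' @export
extract_unspanned_intervals <- function(span) {
  n_empty <- 0L
  rows <- lapply(split(span, span$spanning_contig), function(s) {
    s <- s[order(s$rank), , drop = FALSE]
    if (nrow(s) < 2L) stop("span record with fewer than 2 targets",
                           call. = FALSE)
    start <- s$q_end[-nrow(s)]
    end <- s$q_start[-1L]
    keep <- end > start
    n_empty <<- n_empty + sum(!keep)
    if (!any(keep)) return(NULL)
    intervals(s$spanning_contig[1L], start[keep], end[keep], "unspanned")
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- intervals(character(), integer(), integer())
  rownames(out) <- NULL
  attr(out, "n_empty") <- n_empty
  out
}

#' Assign contigs to chromosomes by chaining collinear alignments
#'
#' A rough chromosome painting: per contig, same-chromosome same-strand
#' alignments are chained when successive blocks advance strictly in both
#' query and target order (strand-adjusted; inversions break chains) with
#' gaps of at most `max_join` bp on either coordinate. The contig is
#' assigned to its maximum-score chain (score = summed aligned bp); score
#' ties are broken toward the lexicographically smallest chromosome and then
#' the leftmost chain start, with the `ambiguous` flag set.
#'
#' @param alns Filtered contig-vs-chromosome alignment records.
#' @param max_join Maximum joinable gap (bp) on both coordinates.
#' @return `data.frame(contig_id, chromosome, start, end, strand, score,
#'   n_blocks, ambiguous)`, chain coordinates on the chromosome.
#' @export
paint_chromosomes <- function(alns, max_join = 100000L) {
  if (nrow(alns) == 0L) {
    return(data.frame(contig_id = character(), chromosome = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), n_blocks = integer(),
                      ambiguous = logical()))
  }
  chain_group <- function(a) {
    # a: rows for one (contig, chromosome, strand), build maximal chains
    a <- a[order(a$q_start, a$q_end), , drop = FALSE]
    minus <- a$strand[1L] == "-"
    n <- nrow(a)
    new_chain <- rep(TRUE, n)
    if (n > 1L) {
      qgap <- a$q_start[-1L] - a$q_end[-n]
      if (minus) {
        tgap <- a$t_start[-n] - a$t_end[-1L]
      } else {
        tgap <- a$t_start[-1L] - a$t_end[-n]
      }
      ok <- qgap >= 0L & qgap <= max_join & tgap >= 0L & tgap <= max_join
      new_chain <- c(TRUE, !ok)
    }
    cid <- cumsum(new_chain)
    do.call(rbind, lapply(split(seq_len(n), cid), function(idx) {
      data.frame(contig_id = a$query_id[1L], chromosome = a$target_id[1L],
                 start = min(a$t_start[idx]), end = max(a$t_end[idx]),
                 strand = a$strand[1L],
                 score = sum(as.numeric(a$aln_len[idx])),
                 n_blocks = length(idx), stringsAsFactors = FALSE)
    }))
  }
  key <- paste(alns$query_id, alns$target_id, alns$strand, sep = "\r")
  chains <- do.call(rbind, lapply(split(alns, key), chain_group))
  out <- do.call(rbind, lapply(split(chains, chains$contig_id), function(ch) {
    ch <- ch[order(-ch$score, ch$chromosome, ch$start), , drop = FALSE]
    best <- ch[1L, , drop = FALSE]
    best$ambiguous <- nrow(ch) > 1L && ch$score[2L] == ch$score[1L]
    best
  }))
  rownames(out) <- NULL
  out
}
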