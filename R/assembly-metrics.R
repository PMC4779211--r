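#' Nx contiguity statistic
#'
#' Returns the largest sequence length `L` such that sequences of length
#' `>= L` together contain at least `x`% of the total assembly bases —
#' equivalently, sort descending, accumulate, and report the length at which
#' the running sum first reaches `x`% of the total. `nx_stat(lengths, 50)`
#' is the familiar N50, `nx_stat(lengths, 90)` the N90.
#'
#' @param lengths Numeric vector (multiset) of sequence lengths, all `>= 1`.
#' @param x Percent threshold in `(0, 100]`.
#' @return The Nx length in bp.
#' @examples
#' nx_stat(c(80, 70, 50, 40, 30, 20, 10), 50) # 70
#' nx_stat(c(80, 70, 50, 40, 30, 20, 10), 90) # 30
#' @export
nx_stat <- function(lengths, x) {
  if (length(lengths) == 0L) {
    stop("Nx statistic is undefined for an empty length set", call. = FALSE)
  }
  stopifnot(all(lengths >= 1), x > 0, x <= 100)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  s[which(cum >= x / 100 * cum[length(cum)])[1L]]
}

#' Split scaffolds into component contigs at placeholder N runs
#'
#' Short-read assemblers bridge small coverage gaps with runs of `N`
#' (placeholder gaps, 100 bp in the assembly this package was built to
#' dissect). Every internal N run of length `>= min_n_run` is treated as a
#' gap and removed; shorter N runs stay inside contigs; terminal N runs are
#' trimmed silently (they bridge nothing). Contigs are named
#' `<scaffold_id>.<k>` in left-to-right order.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param min_n_run Minimum N-run length (bp) treated as a gap.
#' @return List with `contigs` (named character vector) and `gaps`
#'   (`data.frame(scaffold_id, start, end, length, left_contig,
#'   right_contig)`, scaffold coordinates, 0-based half-open).
#' @export
split_scaffolds <- function(scaffolds, min_n_run = 10L) {
  check_sequences(scaffolds, "split_scaffolds input")
  contig_ids <- character(); contig_seqs <- character()
  gap_rows <- vector("list", length(scaffolds))
  for (i in seq_along(scaffolds)) {
    sid <- names(scaffolds)[i]
    seq <- scaffolds[[i]]
    runs <- gregexpr("N+", seq)[[1L]]
    sep_start <- integer(); sep_end <- integer()
    if (runs[1L] != -1L) {
      len <- attr(runs, "match.length")
      big <- len >= min_n_run
      sep_start <- as.integer(runs[big]) - 1L      # 0-based
      sep_end <- sep_start + len[big]
    }
    # segments between separator runs (0-based half-open)
    seg_start <- c(0L, sep_end)
    seg_end <- c(sep_start, nchar(seq))
    keep <- seg_end > seg_start
    if (!any(keep)) {
      warning("scaffold '", sid, "' is all N; no contigs emitted",
              call. = FALSE)
      next
    }
    ks <- seg_start[keep]; ke <- seg_end[keep]
    ids <- sprintf("%s.%d", sid, seq_along(ks))
    contig_ids <- c(contig_ids, ids)
    contig_seqs <- c(contig_seqs, substring(seq, ks + 1L, ke))
    # a separator is a recorded gap iff flanked by kept segments on both sides
    if (length(sep_start) > 0L && length(ks) > 1L) {
      internal <- sep_start %in% ke[-length(ke)]
      if (any(internal)) {
        gs <- sep_start[internal]; ge <- sep_end[internal]
        left_idx <- match(gs, ke)
        gap_rows[[i]] <- data.frame(
          scaffold_id = sid, start = gs, end = ge, length = ge - gs,
          left_contig = ids[left_idx], right_contig = ids[left_idx + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  gaps <- do.call(rbind, gap_rows[!vapply(gap_rows, is.null, TRUE)])
  if (is.null(gaps)) {
    gaps <- data.frame(scaffold_id = character(), start = integer(),
                       end = integer(), length = integer(),
                       left_contig = character(), right_contig = character())
  }
  list(contigs = stats::setNames(contig_seqs, contig_ids), gaps = gaps)
}

#' Basic assembly report (scaffold and contig blocks)
#'
#' Computes contiguity statistics twice: over the scaffolds as given, and
#' over the contigs obtained by splitting all scaffolds at placeholder N runs
#' ([split_scaffolds()]). Following the community convention for this
#' comparison, scaffolds shorter than `scaffold_min` and contigs shorter than
#' `contig_min` are excluded from the respective statistics. Contigs are
#' always derived by splitting, never supplied separately, so both blocks
#' describe one input.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param scaffold_min,contig_min Exclusion thresholds (bp).
#' @param min_n_run Passed to [split_scaffolds()].
#' @return `data.frame` with rows `scaffold` and `contig` and columns
#'   `level, n_sequences, n50, n90, mean_length, max_length, total_length`.
#' @export
assembly_report <- function(scaffolds, scaffold_min = 1000L,
                            contig_min = 200L, min_n_run = 10L) {
  stopifnot(length(scaffolds) >= 1L)
  contigs <- split_scaffolds(scaffolds, min_n_run = min_n_run)$contigs
  block <- function(lengths, min_len, level) {
    lengths <- lengths[lengths >= min_len]
    if (length(lengths) == 0L) {
      warning("all ", level, "s excluded by the ", min_len,
              " bp filter; zero-filled block", call. = FALSE)
      return(data.frame(level = level, n_sequences = 0L, n50 = 0L, n90 = 0L,
                        mean_length = 0, max_length = 0L, total_length = 0))
    }
    data.frame(level = level, n_sequences = length(lengths),
               n50 = nx_stat(lengths, 50), n90 = nx_stat(lengths, 90),
               mean_length = mean(lengths), max_length = max(lengths),
               total_length = sum(as.numeric(lengths)))
  }
  rbind(block(nchar(scaffolds), scaffold_min, "scaffold"),
        block(nchar(contigs), contig_min, "contig"))
}

#' Trim an assembly at a length cutoff
#'
#' Removes every record strictly shorter than `cutoff` (a record of exactly
#' `cutoff` bp is kept), preserving input order. Total bp is conserved:
#' kept + removed = input.
#'
#' @param records Named character vector of sequences.
#' @param cutoff Minimum retained length (bp).
#' @return List with `kept` (named character vector) and `removed_summary`
#'   (`list(n, bp)`).
#' @export
trim_assembly <- function(records, cutoff = 2000L) {
  stopifnot(cutoff >= 0)
  lens <- nchar(records)
  keep <- lens >= cutoff
  list(kept = records[keep],
       removed_summary = list(n = sum(!keep),
                              bp = sum(as.numeric(lens[!keep]))))
}

#' Sweep trimming cutoffs and score each by gene recovery
#'
#' For each cutoff, restricts the gene hit table to subjects retained after
#' trimming and re-scores gene recovery. To keep every reported statistic
#' monotone in the cutoff, means are taken over the full gene universe of
#' `gene_hits` (a gene lost to trimming contributes coverage 0 and 0 pieces).
#'
#' @param records Named character vector of assembly sequences.
#' @param gene_hits Gene hit table (see [score_gene_recovery()] for the
#'   column contract).
#' @param cutoffs Length cutoffs (bp) to evaluate.
#' @param min_novel Passed to [score_gene_recovery()].
#' @return `data.frame(cutoff, n_sequences, total_bp, genes_recovered,
#'   mean_recovery_pct, mean_pieces)`.
#' @export
cutoff_sweep <- function(records, gene_hits,
                         cutoffs = c(1000L, 2000L, 3000L, 4000L, 5000L),
                         min_novel = 20L) {
  if (length(cutoffs) == 0L) stop("empty cutoff list", call. = FALSE)
  missing_subj <- setdiff(unique(gene_hits$subject_id), names(records))
  if (length(missing_subj) > 0L) {
    stop("gene_hits reference unknown subjects: ",
         paste(utils::head(missing_subj, 3L), collapse = ", "), call. = FALSE)
  }
  genes <- unique(gene_hits$gene_id)
  lens <- nchar(records)
  out <- lapply(sort(cutoffs), function(cut) {
    kept <- names(records)[lens >= cut]
    hits <- gene_hits[gene_hits$subject_id %in% kept, , drop = FALSE]
    tab <- gene_recovery_table(hits, min_novel = min_novel)
    cov <- stats::setNames(rep(0, length(genes)), genes)
    pieces <- cov
    cov[tab$gene_id] <- tab$coverage
    pieces[tab$gene_id] <- tab$pieces
    data.frame(cutoff = cut, n_sequences = length(kept),
               total_bp = sum(as.numeric(lens[lens >= cut])),
               genes_recovered = sum(cov > 0),
               mean_recovery_pct = 100 * mean(cov),
               mean_pieces = mean(pieces))
  })
  do.call(rbind, out)
}
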