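#' Build a table of alignment records
#'
#' The internal alignment container is a plain `data.frame`, one row per
#' local alignment, with all coordinates 0-based half-open and the target
#' interval always ascending (strand records orientation). This is the
#' normal form every parser emits and every analysis consumes.
#'
#' @param query_id,target_id Sequence identifiers.
#' @param q_start,q_end,t_start,t_end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param matches Matching bases in the alignment block.
#' @param aln_len Alignment block length (bp).
#' @param identity Percent identity in `[0, 100]`; computed as
#'   `100 * matches / aln_len` when omitted.
#' @param q_len,t_len Full sequence lengths where known (`NA` otherwise).
#' @param tags Free-text extra fields preserved verbatim (PAF tags).
#' @return `data.frame` of validated alignment records.
#' @export
alignment_records <- function(query_id, q_start, q_end, target_id,
                              t_start, t_end, strand = "+",
                              matches = NULL, aln_len = NULL, identity = NULL,
                              q_len = NA_integer_, t_len = NA_integer_,
                              tags = "") {
  validate_alignments(build_alignment_df(
    query_id, q_start, q_end, target_id, t_start, t_end, strand,
    matches, aln_len, identity, q_len, t_len, tags))
}

build_alignment_df <- function(query_id, q_start, q_end, target_id,
                               t_start, t_end, strand, matches = NULL,
                               aln_len = NULL, identity = NULL,
                               q_len = NA_integer_, t_len = NA_integer_,
                               tags = "") {
  if (is.null(aln_len)) aln_len <- pmax(q_end - q_start, t_end - t_start)
  if (is.null(matches)) {
    matches <- if (is.null(identity)) aln_len else round(identity / 100 * aln_len)
  }
  if (is.null(identity)) identity <- ifelse(aln_len > 0, 100 * matches / aln_len, 0)
  n <- length(query_id)
  data.frame(query_id = as.character(query_id),
             q_len = as.integer(q_len),
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             strand = as.character(strand),
             target_id = as.character(target_id),
             t_len = as.integer(t_len),
             t_start = as.integer(t_start), t_end = as.integer(t_end),
             matches = as.integer(matches), aln_len = as.integer(aln_len),
             identity = as.numeric(identity),
             tags = rep_len(as.character(tags), n),
             stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  alignment_records(character(), integer(), integer(), character(),
                    integer(), integer(), character(), integer(), integer(),
                    numeric(), integer(), integer(), character())
}

validate_alignments <- function(df, reject_degenerate = FALSE) {
  bad <- df$q_start >= df$q_end | df$t_start >= df$t_end
  if (any(bad)) {
    if (reject_degenerate) {
      warning(sum(bad), " alignment record(s) with empty interval rejected",
              call. = FALSE)
      df <- df[!bad, , drop = FALSE]
    } else {
      stop("alignment with start >= end (row ", which(bad)[1L], ")",
           call. = FALSE)
    }
  }
  if (any(df$matches > df$aln_len)) {
    stop("alignment with matches > aln_len", call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$identity < 0 | df$identity > 100)) {
    stop("identity outside [0, 100]", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read whole-genome alignment tables
#'
#' Supports two on-disk dialects and normalizes both to the internal
#' convention (0-based half-open, ascending target interval, strand column):
#' \describe{
#'   \item{`paf`}{minimap2-style PAF: 12+ tab-separated columns, 0-based
#'     half-open; extra SAM-style tags are preserved verbatim in `tags`.}
#'   \item{`coords`}{nucmer `show-coords -T` tab dialect: columns
#'     `S1 E1 S2 E2 LEN1 LEN2 %IDY QUERY TARGET`, 1-based inclusive; a
#'     descending target interval (`S2 > E2`) encodes the minus strand.}
#' }
#' Rows whose interval is empty after normalization are rejected with a
#' warning.
#'
#' @param path Path to the alignment table.
#' @param dialect `"paf"` or `"coords"`.
#' @return `data.frame` of alignment records (see [alignment_records()]).
#' @export
read_alignments <- function(path, dialect = c("paf", "coords")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (dialect == "paf") parse_paf_lines(lines) else parse_coords_lines(lines)
}

parse_paf_lines <- function(lines) {
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 12L)) {
    stop("PAF row with fewer than 12 columns (line ", which(ncol < 12L)[1L],
         ")", call. = FALSE)
  }
  getc <- function(i) vapply(fields, `[`, "", i)
  tags <- vapply(fields, function(f) paste(f[-seq_len(12L)], collapse = "\t"), "")
  matches <- as.integer(getc(10L))
  aln_len <- as.integer(getc(11L))
  df <- build_alignment_df(
    query_id = getc(1L), q_len = as.integer(getc(2L)),
    q_start = as.integer(getc(3L)), q_end = as.integer(getc(4L)),
    strand = getc(5L),
    target_id = getc(6L), t_len = as.integer(getc(7L)),
    t_start = as.integer(getc(8L)), t_end = as.integer(getc(9L)),
    matches = matches, aln_len = aln_len,
    identity = ifelse(aln_len > 0, 100 * matches / aln_len, 0),
    tags = tags)
  validate_alignments(df, reject_degenerate = TRUE)
}

parse_coords_lines <- function(lines) {
  # skip any show-coords preamble (paths, "NUCMER", column banner)
  is_data <- grepl("^-?[0-9]+\t", lines)
  lines <- lines[is_data]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 9L)) {
    stop("coords row with fewer than 9 columns", call. = FALSE)
  }
  getc <- function(i) vapply(fields, `[`, "", i)
  s1 <- as.integer(getc(1L)); e1 <- as.integer(getc(2L))
  s2 <- as.integer(getc(3L)); e2 <- as.integer(getc(4L))
  len1 <- as.integer(getc(5L))
  idy <- as.numeric(getc(7L))
  minus <- s2 > e2
  t_start <- ifelse(minus, e2, s2) - 1L
  t_end <- ifelse(minus, s2, e2)
  df <- build_alignment_df(
    query_id = getc(8L), q_start = s1 - 1L, q_end = e1,
    strand = ifelse(minus, "-", "+"),
    target_id = getc(9L), t_start = t_start, t_end = t_end,
    matches = round(idy / 100 * len1), aln_len = len1, identity = idy)
  validate_alignments(df, reject_degenerate = TRUE)
}

#' Write alignment records
#'
#' `write_paf()` emits canonical 12-column PAF (plus preserved tags);
#' `write_coords()` emits the `show-coords -T` tab dialect, re-serializing
#' minus-strand records with the descending target interval of that format.
#'
#' @param alns Alignment record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alns, path) {
  rows <- sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t255",
                  alns$query_id,
                  ifelse(is.na(alns$q_len), alns$q_end, alns$q_len),
                  alns$q_start, alns$q_end, alns$strand,
                  alns$target_id,
                  ifelse(is.na(alns$t_len), alns$t_end, alns$t_len),
                  alns$t_start, alns$t_end, alns$matches, alns$aln_len)
  has_tags <- !is.na(alns$tags) & nzchar(alns$tags)
  rows[has_tags] <- paste(rows[has_tags], alns$tags[has_tags], sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_paf
#' @export
write_coords <- function(alns, path) {
  minus <- alns$strand == "-"
  s2 <- ifelse(minus, alns$t_end, alns$t_start + 1L)
  e2 <- ifelse(minus, alns$t_start + 1L, alns$t_end)
  rows <- sprintf("%d\t%d\t%d\t%d\t%d\t%d\t%.2f\t%s\t%s",
                  alns$q_start + 1L, alns$q_end, s2, e2,
                  alns$q_end - alns$q_start, abs(e2 - s2) + 1L,
                  alns$identity, alns$query_id, alns$target_id)
  writeLines(rows, path)
  invisible(path)
}
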