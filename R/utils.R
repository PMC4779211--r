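# Internal helpers shared across modules. All coordinates inside the package
# are 0-based half-open; 1-based inclusive appears only at file boundaries.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Length of the union of 0-based half-open intervals (single sequence).
union_len <- function(start, end) {
  if (length(start) == 0L) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(r))
}

# Reduce 0-based half-open intervals to a merged data.frame(start, end).
reduce_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

# Total overlap (bp) between two interval sets on one sequence.
intersect_len <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) return(0L)
  a <- IRanges::reduce(IRanges::IRanges(s1 + 1L, e1))
  b <- IRanges::reduce(IRanges::IRanges(s2 + 1L, e2))
  sum(IRanges::width(IRanges::intersect(a, b)))
}

# round() halves away from zero (base R rounds to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

IUPAC_CHARS <- c("A", "C", "G", "T", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

check_sequences <- function(seqs, where = "input") {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must carry non-empty ids (", where, ")", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", where, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence in ", where, call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad)) {
    stop("non-IUPAC character in sequence '", ids[bad][1L], "'", call. = FALSE)
  }
  invisible(seqs)
}

# Normalise raw sequence text: uppercase, RNA U -> T.
normalize_sequence <- function(x) chartr("uU", "TT", toupper(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
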