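#' Read nucleotide sequences from FASTA
#'
#' Reads a plain FASTA file into a named character vector, the package's
#' in-memory sequence container. Sequence text is uppercased and RNA `U` is
#' mapped to `T`, so soft-masking case never leaks into downstream analyses.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @param dialect `"plain"` for ordinary FASTA, `"bubble"` for the
#'   fork-annotated dialect (see [read_bubble_fasta()]).
#' @return For `dialect = "plain"`, a named character vector of uppercase
#'   IUPAC sequences; for `"bubble"`, a list of `bubble_line` objects.
#' @seealso [write_fasta()], [read_bubble_fasta()]
#' @export
read_fasta <- function(path, dialect = c("plain", "bubble")) {
  dialect <- match.arg(dialect)
  if (dialect == "bubble") return(read_bubble_fasta(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  ss <- Biostrings::readBStringSet(path)
  seqs <- normalize_sequence(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (grepl("[{}|]", paste(seqs, collapse = ""))) {
    stop("fork markup found in plain FASTA; use dialect = \"bubble\"",
         call. = FALSE)
  }
  check_sequences(seqs, where = path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  check_sequences(seqs, where = "write_fasta input")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a bubble line
#'
#' A bubble line is a de Bruijn assembly line in which heterozygous loci are
#' kept as unresolved forks: invariant sequence blocks alternate with
#' biallelic forks, each fork holding the two branch alleles (one branch may
#' be empty, encoding an indel). The first and last blocks may be empty, but
#' two forks are never adjacent without an intervening non-empty block.
#'
#' @param line_id Identifier.
#' @param blocks Character vector of invariant blocks, length `nrow(forks) + 1`.
#' @param forks `data.frame(branch_a, branch_b)` of branch alleles, possibly
#'   zero-row.
#' @return An object of class `bubble_line`.
#' @export
bubble_line <- function(line_id, blocks, forks = data.frame(branch_a = character(),
                                                            branch_b = character())) {
  stopifnot(is.character(blocks), nrow(forks) + 1L == length(blocks))
  if (nrow(forks) > 0L) {
    if (any(forks$branch_a == forks$branch_b)) {
      stop("fork with identical branches in line '", line_id, "'", call. = FALSE)
    }
    inner <- blocks[seq_len(length(blocks) - 2L) + 1L]
    if (length(blocks) > 2L && any(!nzchar(inner))) {
      stop("adjacent forks without intervening invariant block in line '",
           line_id, "'", call. = FALSE)
    }
  }
  structure(list(line_id = line_id, blocks = blocks,
                 forks = forks[, c("branch_a", "branch_b"), drop = FALSE]),
            class = "bubble_line")
}

#' @export
print.bubble_line <- function(x, ...) {
  cat(sprintf("<bubble_line %s: %d fork(s), %d invariant bp>\n",
              x$line_id, nrow(x$forks), sum(nchar(x$blocks))))
  invisible(x)
}

# Parse one bubble-dialect sequence body "AA{C|G}TT" into blocks + forks.
# Returns NULL for a multiallelic record (caller counts and skips it).
parse_bubble_body <- function(body, line_id, lineno) {
  n_open <- lengths(regmatches(body, gregexpr("{", body, fixed = TRUE)))
  n_close <- lengths(regmatches(body, gregexpr("}", body, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced fork markup in record '", line_id, "' near line ", lineno,
         call. = FALSE)
  }
  # strsplit keeps a leading "" for a body starting with markup but drops a
  # trailing one; restore it so pieces alternate block, fork, ..., block.
  pieces <- strsplit(body, "[{}]")[[1L]]
  if (length(pieces) == 0L) pieces <- ""
  if (endsWith(body, "}")) pieces <- c(pieces, "")
  if (length(pieces) %% 2L == 0L) {
    stop("unbalanced fork markup in record '", line_id, "' near line ", lineno,
         call. = FALSE)
  }
  blocks <- pieces[seq(1L, length(pieces), by = 2L)]
  forktxt <- if (length(pieces) > 1L) pieces[seq(2L, length(pieces), by = 2L)] else character()
  if (any(grepl("[{}]", blocks))) {
    stop("nested fork markup in record '", line_id, "' near line ", lineno,
         call. = FALSE)
  }
  branches <- strsplit(forktxt, "|", fixed = TRUE)
  # "A|" splits to just "A"; restore the empty second branch
  branches <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    n_bar <- nchar(forktxt[i]) - nchar(gsub("|", "", forktxt[i], fixed = TRUE))
    length(b) <- n_bar + 1L
    b[is.na(b)] <- ""
    b
  })
  nb <- lengths(branches)
  if (any(nb < 2L)) {
    stop("fork without '|' separator in record '", line_id, "' near line ",
         lineno, call. = FALSE)
  }
  if (any(nb > 2L)) return(NULL) # multiallelic: rejected by caller
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")),
               c(blocks, unlist(branches)))
  if (any(bad)) {
    stop("non-IUPAC character in record '", line_id, "'", call. = FALSE)
  }
  bubble_line(line_id, blocks,
              data.frame(branch_a = vapply(branches, `[`, "", 1L),
                         branch_b = vapply(branches, `[`, "", 2L)))
}

#' Read a fork-annotated ("bubble") FASTA file
#'
#' The bubble dialect is ordinary FASTA whose sequence bodies may contain
#' inline fork markup `{ALT1|ALT2}`; one alternative may be empty
#' (`{ACG|}` encodes a deletion allele). Records carrying forks with more
#' than two branches are skipped with a warning; the count of skipped
#' records is attached as attribute `n_rejected`.
#'
#' @param path Path to the bubble-dialect FASTA file.
#' @return List of [bubble_line()] objects, in file order.
#' @export
read_bubble_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    out <- list()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids)) {
    stop("duplicate record id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  n_rejected <- 0L
  out <- vector("list", length(hdr))
  keep <- logical(length(hdr))
  for (i in seq_along(hdr)) {
    body <- normalize_sequence(
      paste(lines[seq(hdr[i] + 1L, ends[i])[seq_len(max(0L, ends[i] - hdr[i]))]],
            collapse = ""))
    bl <- parse_bubble_body(body, ids[i], hdr[i])
    if (is.null(bl)) {
      n_rejected <- n_rejected + 1L
    } else {
      out[[i]] <- bl
      keep[i] <- TRUE
    }
  }
  if (n_rejected > 0L) {
    warning(n_rejected, " multiallelic record(s) rejected", call. = FALSE)
  }
  out <- out[keep]
  attr(out, "n_rejected") <- n_rejected
  out
}

# Serialise a bubble_line body back to markup text.
bubble_body <- function(line) {
  n <- length(line$blocks)
  if (n == 1L) return(line$blocks)
  fork_txt <- sprintf("{%s|%s}", line$forks$branch_a, line$forks$branch_b)
  paste0(paste0(line$blocks[-n], fork_txt, collapse = ""), line$blocks[n])
}

#' Write bubble lines to a fork-annotated FASTA file
#'
#' @param lines List of [bubble_line()] objects.
#' @param path Output path.
#' @param width Line wrap width in characters (markup may wrap across lines;
#'   the parser rejoins them).
#' @export
write_bubble_fasta <- function(lines, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (bl in lines) {
    body <- bubble_body(bl)
    starts <- seq(1L, max(1L, nchar(body)), by = width)
    writeLines(c(paste0(">", bl$line_id),
                 substring(body, starts, pmin(starts + width - 1L, nchar(body)))),
               con)
  }
  invisible(path)
}
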