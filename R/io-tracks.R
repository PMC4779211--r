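#' Variant and interval track IO
#'
#' `read_variants()` reads the minimal VCF column subset
#' (`CHROM POS ID REF ALT`; header lines starting with `#` are skipped and
#' multiallelic `ALT` entries are split into one record per alternative
#' allele). `read_intervals()` reads BED3+ (0-based half-open; column 4, when
#' present, becomes the `label`). Genotypes and INFO parsing are deliberately
#' out of scope.
#'
#' @param path Input path.
#' @return `read_variants()`: `data.frame(contig_id, pos, ref, alt)` with
#'   1-based `pos`, in file order. `read_intervals()`:
#'   `data.frame(seq_id, start, end, label)`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(contig_id = character(), pos = integer(),
                      ref = character(), alt = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L)) {
    stop("VCF row with fewer than 5 columns", call. = FALSE)
  }
  pos <- as.integer(vapply(fields, `[`, "", 2L))
  if (any(is.na(pos) | pos < 1L)) stop("VCF POS < 1", call. = FALSE)
  alts <- strsplit(vapply(fields, `[`, "", 5L), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  df <- data.frame(
    contig_id = rep(vapply(fields, `[`, "", 1L), n_alt),
    pos = rep(pos, n_alt),
    ref = rep(toupper(vapply(fields, `[`, "", 4L)), n_alt),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE)
  if (any(!nzchar(df$ref) | !nzchar(df$alt) | df$ref == df$alt)) {
    stop("invalid variant alleles (empty, or REF == ALT)", call. = FALSE)
  }
  df
}

#' Write variants as a minimal VCF
#'
#' @param variants `data.frame(contig_id, pos, ref, alt)`.
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               sprintf("%s\t%d\t.\t%s\t%s", variants$contig_id,
                       as.integer(variants$pos), variants$ref, variants$alt)),
             path)
  invisible(path)
}

#' @rdname read_variants
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(intervals(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("BED row with fewer than 3 columns", call. = FALSE)
  }
  label <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else "", "")
  intervals(seq_id = vapply(fields, `[`, "", 1L),
            start = as.integer(vapply(fields, `[`, "", 2L)),
            end = as.integer(vapply(fields, `[`, "", 3L)),
            label = label)
}

#' Construct an interval table (0-based half-open)
#'
#' @param seq_id Sequence identifiers.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param label Free-text labels.
#' @export
intervals <- function(seq_id, start, end, label = "") {
  df <- data.frame(seq_id = as.character(seq_id), start = as.integer(start),
                   end = as.integer(end),
                   label = rep_len(as.character(label), length(seq_id)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("interval with start >= end", call. = FALSE)
  if (any(df$start < 0L)) stop("negative interval start", call. = FALSE)
  df
}

#' Write intervals as BED
#'
#' @param ivls Interval `data.frame` from [intervals()].
#' @param path Output path.
#' @export
write_bed <- function(ivls, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", ivls$seq_id, ivls$start, ivls$end,
                     ifelse(nzchar(ivls$label), ivls$label, ".")),
             path)
  invisible(path)
}
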