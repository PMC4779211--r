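# Truth-annotated simulator. The generator emulates the study design this
# package evaluates: a genome fragmented into contigs, small coverage gaps
# rendered as fixed 100-bp placeholder N runs inside "scaffolds",
# partitioned heterozygosity (a monomorphic compartment plus a polymorphic
# one at a stated SNPs/kb rate), planted gene models, planted low-complexity
# tracts, separately assembled haplotype contig pairs, and exact truth
# alignment tables replacing external whole-genome aligner runs. Every
# operation is deterministic given its seed, and never touches caller RNG.

BASES <- c("A", "C", "G", "T")
BASE_UTF8 <- c(65L, 67L, 71L, 84L)

random_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(BASE_UTF8[sample.int(4L, n, replace = TRUE, prob = p)])
}

# IUPAC-aware reverse complement on plain strings (S4 container overhead
# is measurable at simulator scale, so this stays base R).
revcomp <- function(s) {
  comp <- chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", s)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), "",
         USE.NAMES = FALSE)
}

#' Simulate a truth genome
#'
#' Emits i.i.d. random chromosomes at a given GC content, with optional
#' planted low-complexity tracts (perfect dinucleotide repeats) at recorded
#' coordinates. The genome length defaults to a desk-scale stand-in for a
#' modestly sized insect genome.
#'
#' @param length Total genome length (bp).
#' @param n_chromosomes Number of chromosomes (equal sizes, remainder on the
#'   last).
#' @param gc GC fraction.
#' @param lc_tracts `list(count, length)`: number and length (bp) of planted
#'   low-complexity tracts.
#' @param seed RNG seed.
#' @return List: `genome` (named character vector `chr1..chrN`) and `truth`
#'   (list with `chrom_lengths`, `lc_tracts` interval data.frame, `gc`,
#'   `seed`).
#' @export
simulate_genome <- function(length, n_chromosomes = 2L, gc = 0.45,
                            lc_tracts = list(count = 0L, length = 0L),
                            seed = 1L) {
  stopifnot(length >= n_chromosomes * 1000)
  if (lc_tracts$count * lc_tracts$length > length / n_chromosomes) {
    stop("planted low-complexity tracts exceed chromosome length",
         call. = FALSE)
  }
  with_seed(seed, {
    base_len <- length %/% n_chromosomes
    lens <- rep(base_len, n_chromosomes)
    lens[n_chromosomes] <- lens[n_chromosomes] + length - sum(lens)
    genome <- stats::setNames(
      vapply(lens, random_dna, "", gc = gc),
      sprintf("chr%d", seq_len(n_chromosomes)))
    tract_rows <- list()
    if (lc_tracts$count > 0L) {
      placed <- lapply(names(genome), function(x) cbind(integer(), integer()))
      names(placed) <- names(genome)
      for (k in seq_len(lc_tracts$count)) {
        L <- lc_tracts$length
        for (try in 1:100) {
          chrom <- sample(names(genome), 1L, prob = lens)
          st <- sample.int(nchar(genome[[chrom]]) - L + 1L, 1L) - 1L
          prev <- placed[[chrom]]
          if (nrow(prev) == 0L ||
              all(st + L <= prev[, 1L] | st >= prev[, 2L])) break
        }
        placed[[chrom]] <- rbind(placed[[chrom]], c(st, st + L))
        di <- paste(sample(BASES, 2L), collapse = "")
        tract <- strtrim(strrep(di, ceiling(L / 2)), L)
        substr(genome[[chrom]], st + 1L, st + L) <- tract
        tract_rows[[k]] <- data.frame(seq_id = chrom, start = st,
                                      end = st + L, stringsAsFactors = FALSE)
      }
    }
    tracts <- do.call(rbind, tract_rows)
    if (is.null(tracts)) {
      tracts <- data.frame(seq_id = character(), start = integer(),
                           end = integer())
    }
    list(genome = genome,
         truth = list(chrom_lengths = stats::setNames(lens, names(genome)),
                      lc_tracts = tracts, gc = gc, seed = seed))
  })
}

#' Fragment a truth genome into a placeholder-gapped assembly
#'
#' Cuts each chromosome at seeded points into contigs; each junction either
#' skips a stretch of genome of true size drawn from `gap_size_dist` and
#' joins the flanking contigs with exactly `placeholder` Ns (an
#' intra-scaffold gap), or starts a new scaffold (a clean break). Contig bp
#' plus true gap bp per chromosome equals the chromosome length. A fraction
#' of scaffolds is emitted reverse-complemented so minus-strand paths are
#' exercised; component contigs are named `<scaffold>.<k>` in scaffold
#' orientation, matching [split_scaffolds()].
#'
#' @param sim Output of [simulate_genome()] (or a list with `genome`).
#' @param mean_contig Mean contig length (bp); lengths are drawn uniformly
#'   in `[0.5, 1.5] * mean_contig`.
#' @param gap_size_dist `c(min, max)` of the uniform true gap size (bp).
#' @param placeholder Placeholder N-run length (bp) written for every
#'   intra-scaffold gap regardless of its true size.
#' @param p_gap Probability that a junction is an intra-scaffold gap rather
#'   than a scaffold break.
#' @param revcomp_frac Fraction of scaffolds emitted on the minus strand.
#' @param seed RNG seed.
#' @return List: `scaffolds` (named character vector), `truth` (list with
#'   `placements` — contig genome intervals and strand — `gaps` with true
#'   sizes, `placeholder`, and the upstream genome truth).
#' @export
fragment_into_assembly <- function(sim, mean_contig = 8000L,
                                   gap_size_dist = c(0L, 500L),
                                   placeholder = 100L, p_gap = 0.5,
                                   revcomp_frac = 0.25, seed = 1L) {
  genome <- sim$genome
  stopifnot(mean_contig < min(nchar(genome)))
  with_seed(seed, {
    min_piece <- as.integer(max(200L, round(mean_contig / 4)))
    scaffold_seqs <- list()
    placements <- list(); gap_rows <- list()
    scf_n <- 0L
    for (chrom in names(genome)) {
      clen <- nchar(genome[[chrom]])
      pos <- 0L
      cur <- list()   # genome intervals of current scaffold's contigs
      cur_gaps <- integer()
      close_scaffold <- function() {
        scf_n <<- scf_n + 1L
        sid <- sprintf("scf%d", scf_n)
        strand <- if (stats::runif(1) < revcomp_frac) "-" else "+"
        iv <- do.call(rbind, cur)
        k <- nrow(iv)
        ord <- if (strand == "+") seq_len(k) else rev(seq_len(k))
        ids <- character(k); ids[ord] <- sprintf("%s.%d", sid, seq_len(k))
        placements[[length(placements) + 1L]] <<- data.frame(
          contig_id = ids, scaffold_id = sid, chrom = chrom,
          start = iv[, 1L], end = iv[, 2L], strand = strand,
          stringsAsFactors = FALSE)
        if (k > 1L) {
          # gap j sits between genome-order contigs j and j+1
          lg <- if (strand == "+") ids[-k] else ids[-1L]
          rg <- if (strand == "+") ids[-1L] else ids[-k]
          go <- if (strand == "+") seq_len(k - 1L) else rev(seq_len(k - 1L))
          gap_rows[[length(gap_rows) + 1L]] <<- data.frame(
            scaffold_id = sid, left_contig = lg[go], right_contig = rg[go],
            true_size = cur_gaps[go], stringsAsFactors = FALSE)
        }
        pieces <- substring(genome[[chrom]], iv[, 1L] + 1L, iv[, 2L])
        body <- paste(pieces, collapse = strrep("N", placeholder))
        if (strand == "-") body <- revcomp(body)
        scaffold_seqs[[sid]] <<- body
        cur <<- list(); cur_gaps <<- integer()
      }
      while (pos < clen) {
        L <- as.integer(round(stats::runif(1, 0.5 * mean_contig,
                                           1.5 * mean_contig)))
        L <- min(L, clen - pos)
        cur[[length(cur) + 1L]] <- c(pos, pos + L)
        pos <- pos + L
        rem <- clen - pos
        if (rem <= min_piece) {
          if (rem > 0L) {
            cur[[length(cur)]][2L] <- clen
            pos <- clen
          }
          close_scaffold()
        } else if (stats::runif(1) < p_gap) {
          g <- sample.int(gap_size_dist[2L] - gap_size_dist[1L] + 1L, 1L) -
            1L + gap_size_dist[1L]
          g <- min(g, rem - min_piece)
          cur_gaps <- c(cur_gaps, g)
          pos <- pos + g
        } else {
          close_scaffold()
        }
      }
    }
    placements <- do.call(rbind, placements)
    gaps <- do.call(rbind, gap_rows)
    if (is.null(gaps)) {
      gaps <- data.frame(scaffold_id = character(), left_contig = character(),
                         right_contig = character(), true_size = integer())
    }
    rownames(placements) <- rownames(gaps) <- NULL
    truth <- sim$truth %||% list()
    truth$placements <- placements
    truth$gaps <- gaps
    truth$placeholder <- placeholder
    truth$chrom_lengths <- truth$chrom_lengths %||%
      stats::setNames(nchar(genome), names(genome))
    list(scaffolds = unlist(scaffold_seqs), truth = truth)
  })
}

#' Plant heterozygosity: compartments, SNPs and indels
#'
#' Assigns contigs to a zero-variant (monomorphic) compartment by cumulative
#' bp in seeded-shuffled order until `zero_fraction` of total bp is reached
#' (the realized fraction is recorded — contig granularity makes an exact
#' match impossible). Variable contigs receive Poisson-placed SNPs and
#' contiguous indels at the stated per-kb rates. Emits the fork-annotated
#' bubble representation of every contig together with a matching truth
#' variant table (indels left-anchored, VCF style).
#'
#' @param contigs Named character vector (the assembly sequences).
#' @param zero_fraction Target fraction of total bp carrying no variants.
#' @param snp_rate SNPs per kb on variable contigs.
#' @param indel_rate Indels per kb on variable contigs.
#' @param max_indel Maximum indel length (bp); lengths uniform on
#'   `1..max_indel`.
#' @param seed RNG seed.
#' @return List: `lines` (bubble lines, one per contig), `variants`
#'   (`data.frame(contig_id, pos, ref, alt, type)`), `compartments`
#'   (`data.frame(contig_id, length, compartment)`),
#'   `realized_zero_fraction`.
#' @export
inject_variants <- function(contigs, zero_fraction = 0.39, snp_rate = 3.66,
                            indel_rate = 0.2, max_indel = 10L, seed = 1L) {
  stopifnot(zero_fraction >= 0, zero_fraction <= 1,
            snp_rate >= 0, indel_rate >= 0)
  if ((snp_rate + indel_rate) / 1000 > 1) {
    stop("variant rates imply more than one variant per base", call. = FALSE)
  }
  with_seed(seed, {
    lens <- nchar(contigs)
    total <- sum(as.numeric(lens))
    ord <- sample(names(contigs))
    cum <- cumsum(as.numeric(lens[ord]))
    zero_ids <- ord[cum <= zero_fraction * total]
    compartments <- data.frame(
      contig_id = names(contigs), length = unname(lens),
      compartment = ifelse(names(contigs) %in% zero_ids, "zero", "variable"),
      stringsAsFactors = FALSE)
    lines <- vector("list", length(contigs))
    var_rows <- vector("list", length(contigs))
    for (i in seq_along(contigs)) {
      id <- names(contigs)[i]
      seq <- contigs[[i]]
      len <- lens[[i]]
      if (id %in% zero_ids || len < 10L) {
        lines[[i]] <- bubble_line(id, seq)
        next
      }
      n_snp <- stats::rpois(1L, len / 1000 * snp_rate)
      n_ind <- stats::rpois(1L, len / 1000 * indel_rate)
      ev <- draw_variant_events(seq, len, n_snp, n_ind, max_indel)
      lines[[i]] <- events_to_bubble_line(id, seq, ev)
      var_rows[[i]] <- events_to_vcf_rows(id, seq, ev)
    }
    variants <- do.call(rbind, var_rows[!vapply(var_rows, is.null, TRUE)])
    if (is.null(variants)) {
      variants <- data.frame(contig_id = character(), pos = integer(),
                             ref = character(), alt = character(),
                             type = character())
    }
    rownames(variants) <- NULL
    list(lines = lines, variants = variants, compartments = compartments,
         realized_zero_fraction =
           sum(as.numeric(lens[zero_ids])) / total)
  })
}

# Draw non-colliding variant events on one contig. Events never touch the
# first or last two bases (forks keep non-empty flanking blocks), are
# separated by at least one invariant base, and avoid placeholder N runs.
# The alternative allele (SNP substitute base, or inserted sequence) is
# drawn here so the bubble and VCF representations agree by construction.
# Returns data.frame(pos, len, type, alt) with 1-based pos: SNP at pos;
# deletion of len bases starting at pos; insertion of len bases after pos.
draw_variant_events <- function(seq, len, n_snp, n_ind, max_indel) {
  empty <- data.frame(pos = integer(), len = integer(), type = character(),
                      alt = character())
  lo <- 3L; hi <- len - 2L - max_indel
  if (hi <= lo || (n_snp + n_ind) == 0L) return(empty)
  n <- min(n_snp + n_ind, (hi - lo) %/% (max_indel + 2L))
  n_ind <- min(n_ind, n); n_snp <- n - n_ind
  # thin from a grid of slots wide enough that no two events can collide
  slot_w <- max_indel + 2L
  n_slots <- (hi - lo) %/% slot_w
  slots <- sort(sample.int(n_slots, n))
  offs <- sample.int(slot_w, n, replace = TRUE) - 1L
  pos <- lo + (slots - 1L) * slot_w + pmin(offs, slot_w - max_indel - 1L)
  type <- sample(c(rep("snp", n_snp),
                   rep(c("del", "ins"), length.out = n_ind)))
  elen <- ifelse(type == "snp", 1L,
                 sample.int(max_indel, n, replace = TRUE))
  ev <- data.frame(pos = pos, len = as.integer(elen), type = type,
                   alt = "", stringsAsFactors = FALSE)
  touched <- substring(seq, ev$pos - 2L, ev$pos + ev$len + 1L)
  ev <- ev[!grepl("N", touched, fixed = TRUE), , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  for (j in seq_len(nrow(ev))) {
    ev$alt[j] <- switch(ev$type[j],
      snp = sample(setdiff(BASES, substr(seq, ev$pos[j], ev$pos[j])), 1L),
      del = "",
      ins = random_dna(ev$len[j]))
  }
  ev
}

events_to_bubble_line <- function(id, seq, ev) {
  if (nrow(ev) == 0L) return(bubble_line(id, seq))
  ev <- ev[order(ev$pos), , drop = FALSE]
  n <- nrow(ev)
  branch_a <- character(n); branch_b <- character(n)
  span_s <- integer(n); span_e <- integer(n)  # 1-based inclusive ref span
  for (j in seq_len(n)) {
    p <- ev$pos[j]
    if (ev$type[j] == "snp") {
      branch_a[j] <- substr(seq, p, p)
      branch_b[j] <- ev$alt[j]
      span_s[j] <- p; span_e[j] <- p
    } else if (ev$type[j] == "del") {
      branch_a[j] <- substr(seq, p, p + ev$len[j] - 1L)
      branch_b[j] <- ""
      span_s[j] <- p; span_e[j] <- p + ev$len[j] - 1L
    } else {
      branch_a[j] <- ""
      branch_b[j] <- ev$alt[j]
      span_s[j] <- p + 1L; span_e[j] <- p  # zero-width ref span after pos
    }
  }
  blocks <- substring(seq, c(1L, span_e + 1L), c(span_s - 1L, nchar(seq)))
  bubble_line(id, blocks, data.frame(branch_a = branch_a, branch_b = branch_b,
                                     stringsAsFactors = FALSE))
}

events_to_vcf_rows <- function(id, seq, ev) {
  if (nrow(ev) == 0L) return(NULL)
  ev <- ev[order(ev$pos), , drop = FALSE]
  ref <- character(nrow(ev)); alt <- character(nrow(ev))
  for (j in seq_len(nrow(ev))) {
    p <- ev$pos[j]
    if (ev$type[j] == "snp") {
      ref[j] <- substr(seq, p, p)
      alt[j] <- ev$alt[j]
    } else if (ev$type[j] == "del") {
      ref[j] <- substr(seq, p - 1L, p + ev$len[j] - 1L)
      alt[j] <- substr(seq, p - 1L, p - 1L)
      ev$pos[j] <- p - 1L
    } else {
      ref[j] <- substr(seq, p, p)
      alt[j] <- paste0(ref[j], ev$alt[j])
    }
  }
  data.frame(contig_id = id, pos = ev$pos, ref = ref, alt = alt,
             type = ev$type, stringsAsFactors = FALSE)
}

#' Plant gene models and haplotype-duplicate contigs
#'
#' Copies gene-length stretches out of contig interiors (recorded as truth
#' coordinates plus a noise-free hit table in the gene-recovery format) and
#' appends haplotype duplicates: copies of selected contigs carrying seeded
#' substitutions at the stated divergence, together with the noise-free
#' self-alignment records linking each pair (trivial identity self-hits are
#' included, as a real self-alignment would contain them).
#'
#' @param assembly Named character vector of contig sequences.
#' @param n_genes Number of genes to plant (at most one per contig).
#' @param gene_len Gene length (bp).
#' @param hap_dup `list(count, divergence)`: number of duplicated contigs
#'   and per-base substitution divergence of the second haplotype.
#' @param seed RNG seed.
#' @return List: `assembly` (with duplicates appended), `genes` (named
#'   character vector), `gene_truth` (`data.frame(gene_id, subject_id,
#'   s_start, s_end)`), `hits` (gene hit table), `hap_pairs`
#'   (`data.frame(contig_a, contig_b, divergence)`), `self_alns` (alignment
#'   records).
#' @export
plant_features <- function(assembly, n_genes = 100L, gene_len = 1500L,
                           hap_dup = list(count = 0L, divergence = 0.02),
                           seed = 1L) {
  with_seed(seed, {
    lens <- nchar(assembly)
    eligible <- names(assembly)[lens >= gene_len + 200L]
    if (n_genes > length(eligible)) {
      stop("n_genes exceeds placeable capacity (", length(eligible),
           " eligible contigs)", call. = FALSE)
    }
    genes <- character(); gene_truth <- NULL; hits <- NULL
    if (n_genes > 0L) {
      hosts <- sample(eligible, n_genes)
      offs <- integer(n_genes)
      for (j in seq_len(n_genes)) {
        L <- lens[[hosts[j]]]
        for (try in 1:20) {
          o <- sample.int(L - gene_len - 100L, 1L) + 50L - 1L
          if (!grepl("N", substr(assembly[[hosts[j]]], o + 1L, o + gene_len),
                     fixed = TRUE)) break
        }
        offs[j] <- o
      }
      gene_ids <- sprintf("gene%04d", seq_len(n_genes))
      genes <- stats::setNames(
        substring(assembly[hosts], offs + 1L, offs + gene_len), gene_ids)
      gene_truth <- data.frame(gene_id = gene_ids, subject_id = hosts,
                               s_start = offs, s_end = offs + gene_len,
                               stringsAsFactors = FALSE)
      hits <- data.frame(gene_id = gene_ids, gene_len = gene_len,
                         g_start = 0L, g_end = gene_len,
                         subject_id = hosts, s_start = offs,
                         s_end = offs + gene_len,
                         identity = 100, score = gene_len,
                         stringsAsFactors = FALSE)
    } else {
      hits <- data.frame(gene_id = character(), gene_len = integer(),
                         g_start = integer(), g_end = integer(),
                         subject_id = character(), s_start = integer(),
                         s_end = integer(), identity = numeric(),
                         score = numeric())
    }
    hap_pairs <- data.frame(contig_a = character(), contig_b = character(),
                            divergence = numeric())
    dup_seqs <- character()
    self_rows <- list()
    if (hap_dup$count > 0L) {
      dup_src <- sample(names(assembly)[lens >= 2000L], hap_dup$count)
      for (src in dup_src) {
        s <- assembly[[src]]
        L <- nchar(s)
        n_sub <- stats::rbinom(1L, L, hap_dup$divergence)
        if (n_sub > 0L) {
          at <- sample.int(L, n_sub)
          old <- strsplit(s, "")[[1L]][at]
          new <- vapply(old, function(b) {
            if (b %in% BASES) sample(setdiff(BASES, b), 1L) else b
          }, "")
          sv <- strsplit(s, "")[[1L]]
          sv[at] <- new
          s <- paste(sv, collapse = "")
        }
        did <- paste0(src, "_hap2")
        dup_seqs[did] <- s
        hap_pairs <- rbind(hap_pairs, data.frame(
          contig_a = min(src, did), contig_b = max(src, did),
          divergence = hap_dup$divergence, stringsAsFactors = FALSE))
        self_rows[[length(self_rows) + 1L]] <- alignment_records(
          query_id = src, q_start = 0L, q_end = L, target_id = did,
          t_start = 0L, t_end = L, strand = "+",
          matches = L - n_sub, aln_len = L, q_len = L, t_len = L)
      }
    }
    out_assembly <- c(assembly, dup_seqs)
    trivial <- alignment_records(
      query_id = names(out_assembly), q_start = 0L,
      q_end = nchar(out_assembly), target_id = names(out_assembly),
      t_start = 0L, t_end = nchar(out_assembly), strand = "+",
      matches = nchar(out_assembly), aln_len = nchar(out_assembly),
      q_len = nchar(out_assembly), t_len = nchar(out_assembly))
    self_alns <- rbind(trivial, do.call(rbind, self_rows))
    list(assembly = out_assembly, genes = genes, gene_truth = gene_truth,
         hits = hits, hap_pairs = hap_pairs, self_alns = self_alns)
  })
}

#' Emit truth alignment tables from simulator placements
#'
#' Replaces an external whole-genome aligner run with exact alignments: one
#' record per contig placement, coordinates taken from truth. With
#' `noise > 0`, identities are degraded by the substitution rate and
#' records are randomly split into two abutting blocks.
#'
#' @param truth Truth list from [fragment_into_assembly()].
#' @param noise Substitution rate used to degrade identity (0 = exact).
#' @param seed RNG seed (used only when `noise > 0`).
#' @return Alignment record `data.frame` (writable with [write_paf()]).
#' @export
emit_truth_alignments <- function(truth, noise = 0, seed = 1L) {
  pl <- truth$placements
  q_len <- pl$end - pl$start
  t_len <- unname(truth$chrom_lengths[pl$chrom])
  base <- alignment_records(
    query_id = pl$contig_id, q_start = 0L, q_end = q_len,
    target_id = pl$chrom, t_start = pl$start, t_end = pl$end,
    strand = pl$strand, matches = q_len, aln_len = q_len,
    q_len = q_len, t_len = t_len)
  if (noise <= 0) return(base)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(base)), function(i) {
      r <- base[i, , drop = FALSE]
      L <- r$q_end - r$q_start
      out <- if (L > 2L && stats::runif(1) < 0.5) {
        c1 <- sample.int(L - 1L, 1L)
        a <- r; b <- r
        a$q_end <- c1; b$q_start <- c1
        if (r$strand == "+") {
          a$t_end <- r$t_start + c1; b$t_start <- r$t_start + c1
        } else {
          a$t_start <- r$t_end - c1; b$t_end <- r$t_end - c1
        }
        rbind(a, b)
      } else r
      out$aln_len <- out$q_end - out$q_start
      out$matches <- round((1 - noise) * out$aln_len)
      out$identity <- 100 * out$matches / out$aln_len
      out
    })
    validate_alignments(do.call(rbind, rows))
  })
}

#' Run the full simulator with the study's default conditions
#'
#' Convenience wrapper chaining [simulate_genome()],
#' [fragment_into_assembly()], [inject_variants()] and [plant_features()]
#' under one seed, with defaults matching the conditions this package's
#' analyses assume: a 5 Mb, 2-chromosome genome, 100-bp placeholder gaps
#' with true sizes uniform on `[0, 500]` bp, a 39% zero-variant compartment
#' with 3.66 SNPs/kb on the remainder, 100 planted genes and 5 haplotype
#' pairs.
#'
#' @param genome_length,n_chromosomes,gc,lc_tracts See [simulate_genome()].
#' @param mean_contig,gap_size_dist,placeholder,p_gap,revcomp_frac See
#'   [fragment_into_assembly()].
#' @param zero_fraction,snp_rate,indel_rate See [inject_variants()].
#' @param n_genes,gene_len,hap_dup See [plant_features()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return List with `genome`, `scaffolds`, `assembly` (scaffolds plus
#'   haplotype duplicates), `truth`, `het` (bubble lines, variants,
#'   compartments), `features` (genes, hits, haplotype pairs, self
#'   alignments), and `truth_alns`.
#' @export
simulate_study <- function(genome_length = 5e6, n_chromosomes = 2L,
                           gc = 0.45,
                           lc_tracts = list(count = 10L, length = 2000L),
                           mean_contig = 8000L,
                           gap_size_dist = c(0L, 500L), placeholder = 100L,
                           p_gap = 0.5, revcomp_frac = 0.25,
                           zero_fraction = 0.39, snp_rate = 3.66,
                           indel_rate = 0.2,
                           n_genes = 100L, gene_len = 1500L,
                           hap_dup = list(count = 5L, divergence = 0.02),
                           seed = 1L) {
  g <- simulate_genome(genome_length, n_chromosomes, gc, lc_tracts,
                       seed = seed)
  asm <- fragment_into_assembly(g, mean_contig, gap_size_dist, placeholder,
                                p_gap, revcomp_frac, seed = seed + 1L)
  het <- inject_variants(asm$scaffolds, zero_fraction, snp_rate, indel_rate,
                         seed = seed + 2L)
  feats <- plant_features(asm$scaffolds, n_genes, gene_len, hap_dup,
                          seed = seed + 3L)
  list(genome = g$genome, scaffolds = asm$scaffolds,
       assembly = feats$assembly, truth = asm$truth, het = het,
       features = feats,
       truth_alns = emit_truth_alignments(asm$truth))
}
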