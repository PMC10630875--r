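#' Build an exact-match index of 5' splice-site 20-mers
#'
#' Maps every FIVE fragment's 20-mer and its reverse complement to
#' (fragment, orientation). Fragments whose 20-mer contains an `N` are
#' excluded: they can never be matched exactly. A 20-mer claimed by more than
#' one fragment, or by both orientations (reverse-complement palindrome), is
#' marked ambiguous; hits on it are later rejected rather than assigned.
#'
#' @param five_fragments FIVE-side fragment table; all sequences must have
#'   the same width (20 nt by default).
#' @return A `five_index`: list with `kmers` (data.table: `kmer`,
#'   `fragment_id`, `orientation`, `ambiguous`), `pdict` (a
#'   [Biostrings::PDict] over the distinct 20-mers) and `kmer_seqs`.
#' @export
build_5p_index <- function(five_fragments) {
  w <- nchar(five_fragments$sequence)
  if (length(unique(w)) > 1L || (length(w) && any(w != w[1]))) {
    stop("all 5'SS fragments must have identical length", call. = FALSE)
  }
  usable <- !grepl("N", five_fragments$sequence, fixed = TRUE)
  fr <- five_fragments[usable]
  if (nrow(fr) == 0L) {
    idx <- list(kmers = data.table(kmer = character(), fragment_id = character(),
                                   orientation = character(), ambiguous = logical()),
                pdict = NULL, kmer_seqs = character(), width = if (length(w)) w[1] else 20L)
    class(idx) <- "five_index"
    return(idx)
  }
  tab <- rbind(
    data.table(kmer = fr$sequence, fragment_id = fr$fragment_id,
               orientation = "SENSE"),
    data.table(kmer = revcomp(fr$sequence), fragment_id = fr$fragment_id,
               orientation = "ANTISENSE"))
  tab <- unique(tab)
  # ambiguous: kmer claimed by >1 fragment or by both orientations
  amb <- tab[, .(ambiguous = uniqueN(fragment_id) > 1L || uniqueN(orientation) > 1L),
             by = kmer]
  tab <- merge(tab, amb, by = "kmer")
  kmer_seqs <- sort(unique(tab$kmer))
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(kmer_seqs))
  idx <- list(kmers = tab, pdict = pdict, kmer_seqs = kmer_seqs,
              width = nchar(fr$sequence[1]))
  class(idx) <- "five_index"
  idx
}

#' @export
print.five_index <- function(x, ...) {
  cat("five_index:", length(x$kmer_seqs), "distinct", x$width, "nt k-mers,",
      sum(x$kmers$ambiguous), "ambiguous entries\n")
  invisible(x)
}

#' Find all exact 5' splice-site matches in one read
#'
#' Equivalent to scanning every window of the read against every indexed
#' 20-mer (either orientation); implemented with [Biostrings::matchPDict].
#'
#' @param read A read record (list/row with `sequence`), or a plain sequence
#'   string.
#' @param index A `five_index` from [build_5p_index()].
#' @return data.table with one row per match: `fragment_id`, `orientation`,
#'   `match_start`, `match_end` (0-based half-open read offsets),
#'   `ambiguous`.
#' @export
match_5p <- function(read, index) {
  seq <- if (is.character(read)) read else read$sequence
  empty <- data.table(fragment_id = character(), orientation = character(),
                      match_start = integer(), match_end = integer(),
                      ambiguous = logical())
  if (is.null(index$pdict) || nchar(seq) < index$width) return(empty)
  mi <- Biostrings::matchPDict(index$pdict, Biostrings::DNAString(seq))
  starts <- Biostrings::startIndex(mi)
  hit <- which(lengths(starts) > 0L)
  if (length(hit) == 0L) return(empty)
  rows <- lapply(hit, function(p) {
    entries <- index$kmers[kmer == index$kmer_seqs[p]]
    st <- starts[[p]] # 1-based
    # one row per (entry, offset)
    entries[rep(seq_len(nrow(entries)), each = length(st)),
            .(fragment_id, orientation, ambiguous,
              match_start = rep(st - 1L, times = nrow(entries)))]
  })
  out <- rbindlist(rows)
  out[, match_end := match_start + index$width]
  setcolorder(out, c("fragment_id", "orientation", "match_start", "match_end",
                     "ambiguous"))
  setorder(out, match_start, fragment_id, orientation)
  out[]
}

#' Resolve the 5' matches of one read to a single splice site
#'
#' A read is accepted only when it carries exactly one exact hit and that
#' hit's 20-mer is unambiguous; otherwise it is rejected with a reason:
#' `no_match` (zero hits), `multi_site` (hits to more than one fragment),
#' `multi_position` (same fragment at several offsets), `ambiguous_kmer`
#' (the matched 20-mer is shared between fragments or orientations).
#'
#' @param matches Output of [match_5p()] for one read.
#' @return list with `accept` (logical) and either `match` (single-row
#'   data.table) or `reason`.
#' @export
resolve_unique_5p <- function(matches) {
  n <- nrow(matches)
  if (n == 0L) return(list(accept = FALSE, reason = "no_match"))
  if (n == 1L) {
    if (matches$ambiguous[1]) return(list(accept = FALSE, reason = "ambiguous_kmer"))
    return(list(accept = TRUE, match = matches))
  }
  if (uniqueN(matches$fragment_id) > 1L) {
    return(list(accept = FALSE, reason = "multi_site"))
  }
  list(accept = FALSE, reason = "multi_position")
}

#' Trim a read around its 5' splice-site match
#'
#' The retained segment is the read portion on the branchpoint (3'-intronic)
#' side of the match: for a SENSE match the prefix before it, for an
#' ANTISENSE match the suffix after it. On mate 1 the first `umi_len`
#' positions (the UMI) are additionally removed from the retained interval.
#' Reads with fewer than `min_segment` nt remaining are rejected.
#'
#' @param read Read record (needs `sequence` and `mate`).
#' @param match Accepted single-row match from [resolve_unique_5p()].
#' @param umi_len UMI length on mate 1 (default 12).
#' @param min_segment Minimum retained length (default 20).
#' @return list with `accept` and either `segment` (list: `sequence`,
#'   `source_interval` 0-based half-open in the original read) or `reason`
#'   (`trim_short`).
#' @export
trim_read <- function(read, match, umi_len = 12L, min_segment = 20L) {
  len <- nchar(read$sequence)
  if (match$match_start < 0L || match$match_end > len) {
    stop("internal error: match offsets outside read", call. = FALSE)
  }
  if (match$orientation == "SENSE") {
    from <- if (read$mate == 1L) umi_len else 0L
    to <- match$match_start
  } else {
    from <- match$match_end
    to <- len
    # mate-1 UMI occupies [0, umi_len); an ANTISENSE suffix can only overlap
    # it if the match itself sat inside the UMI
    if (read$mate == 1L) from <- max(from, umi_len)
  }
  if (to - from < min_segment) return(list(accept = FALSE, reason = "trim_short"))
  list(accept = TRUE,
       segment = list(sequence = substr(read$sequence, from + 1L, to),
                      source_interval = c(from, to)))
}

#' Apply the 3' alignment quality filters
#'
#' A candidate alignment fails iff `mismatches > max_mismatches`, the
#' mismatch rate `mismatches / segment_len` strictly exceeds
#' `max_mismatch_rate`, or its longest single gap run exceeds `max_indel`
#' nt. All boundaries are inclusive keeps (5 mismatches pass, 10.0% passes,
#' a 3 nt indel passes). When `unique = FALSE` the read is failed as mapping
#' to more than one 3' splice site.
#'
#' @param alignment A single alignment row (from [align_3p()]).
#' @param segment_len Length of the aligned segment.
#' @param max_mismatches,max_mismatch_rate,max_indel Thresholds (defaults 5,
#'   0.10, 3).
#' @param unique Whether the read maps to a single 3' splice site.
#' @return list with `pass` (logical) and `reason` (`NA` when passing, else
#'   one of `mismatch_count`, `mismatch_rate`, `indel`, `multi_3p`).
#' @export
filter_3p <- function(alignment, segment_len, max_mismatches = 5L,
                      max_mismatch_rate = 0.10, max_indel = 3L, unique = TRUE) {
  if (alignment$mismatches > max_mismatches) {
    return(list(pass = FALSE, reason = "mismatch_count"))
  }
  if (alignment$mismatches / segment_len > max_mismatch_rate) {
    return(list(pass = FALSE, reason = "mismatch_rate"))
  }
  if (alignment$max_indel_len > max_indel) {
    return(list(pass = FALSE, reason = "indel"))
  }
  if (!isTRUE(unique)) return(list(pass = FALSE, reason = "multi_3p"))
  list(pass = TRUE, reason = NA_character_)
}

#' Gene, strand, orientation and intron-order consistency
#'
#' A candidate passes only when (a) the FIVE and THREE regions share at least
#' one gene id, (b) they are on the same strand, (c) the 5' and 3' read-local
#' orientations agree, and (d) the FIVE region's 5' splice site lies at or
#' upstream of the THREE region's 3' splice site in transcription direction
#' ("proper order"; trivially true when both come from the same region).
#'
#' @param five_match Accepted 5' match row (needs `fragment_id`,
#'   `orientation`).
#' @param three_alignment Passing 3' alignment row (needs `fragment_id`,
#'   `region_id`, `orientation`).
#' @param region_table Region table of the fragment database.
#' @return list with `pass`, `reason` (`gene_mismatch`, `strand_mismatch`,
#'   `orientation_mismatch`, `order` or `NA`) and `same_region`.
#' @export
consistency_checks <- function(five_match, three_alignment, region_table) {
  five_region_id <- sub("^5p:", "", five_match$fragment_id)
  three_region_id <- three_alignment$region_id
  five <- region_table[region_id == five_region_id]
  three <- region_table[region_id == three_region_id]
  stopifnot(nrow(five) == 1L, nrow(three) == 1L)
  same_region <- five_region_id == three_region_id
  g5 <- strsplit(five$gene_ids, ",", fixed = TRUE)[[1]]
  g3 <- strsplit(three$gene_ids, ",", fixed = TRUE)[[1]]
  shared <- intersect(g5, g3)
  if (length(shared) == 0L) {
    return(list(pass = FALSE, reason = "gene_mismatch", same_region = same_region))
  }
  if (five$strand != three$strand) {
    return(list(pass = FALSE, reason = "strand_mismatch", same_region = same_region))
  }
  if (five_match$orientation != three_alignment$orientation) {
    return(list(pass = FALSE, reason = "orientation_mismatch", same_region = same_region))
  }
  # 5'SS coordinate: region start on "+", region end on "-";
  # 3'SS coordinate: region end on "+", region start on "-"
  ok <- if (five$strand == "+") five$start <= three$end else five$end >= three$start
  if (!ok) {
    return(list(pass = FALSE, reason = "order", same_region = same_region))
  }
  list(pass = TRUE, reason = NA_character_, same_region = same_region,
       shared_genes = paste(sort(shared), collapse = ","))
}

#' Mate / strand orientation rule
#'
#' Fragments are stored in transcription orientation, so a SENSE hit means
#' the read as sequenced matches the gene's annotated strand. In the CORALL
#' stranded protocol mate 1 copies the RNA template (must map SENSE) and
#' mate 2 is its complement (must map ANTISENSE).
#'
#' @param mate 1 or 2.
#' @param mapping_orientation `"SENSE"` or `"ANTISENSE"`.
#' @return `TRUE`/`FALSE`.
#' @export
mate_strand_check <- function(mate, mapping_orientation) {
  if (!mate %in% c(1L, 2L)) stop("mate must be 1 or 2", call. = FALSE)
  if (mate == 1L) mapping_orientation == "SENSE" else mapping_orientation == "ANTISENSE"
}

#' Map a passing 3' alignment to a genomic branchpoint
#'
#' The branchpoint is the genomic coordinate of the fragment position aligned
#' to the segment's transcription-orientation 3'-terminal base, i.e.
#' `ref_end - 1` in fragment coordinates, mapped through the fragment's
#' genomic interval with strand. The reported base is the fragment sequence
#' at that position (transcription orientation).
#'
#' @param three_alignment Passing alignment row.
#' @param three_fragment The matching THREE fragment row.
#' @return list with `chrom`, `position` (0-based genomic) and `base`.
#' @export
call_branchpoint <- function(three_alignment, three_fragment) {
  p <- three_alignment$ref_end - 1L # 0-based offset in the fragment
  pos <- if (three_fragment$strand == "+") {
    three_fragment$start + p
  } else {
    three_fragment$end - 1L - p
  }
  list(chrom = three_fragment$chrom, position = as.integer(pos),
       base = substr(three_fragment$sequence, p + 1L, p + 1L))
}

#' Detect lariat reads in a sample
#'
#' Runs the full per-read chain: exact 5' splice-site 20-mer match, unique-
#' site resolution, UMI/splice-site trimming, semi-global 3' alignment,
#' mismatch/indel filters, 3'-site uniqueness, gene/strand/order consistency,
#' the mate-strand rule, and branchpoint calling. Each input read yields at
#' most one call; the audit log records the first failing stage of every
#' read that produced no call.
#'
#' @param reads QC-filtered read table ([read_sample_fastq()] then
#'   [filter_ambiguous()]).
#' @param fragment_db A `fragment_db` from [build_intron_index()].
#' @param params Pipeline parameter list as from [default_config()]; only the
#'   detection-related entries are used.
#' @return list with `calls` (data.table: `sample_id`, `read_id`, `mate`,
#'   `gene_ids`, `five_region_id`, `three_region_id`, `same_region`, `chrom`,
#'   `bp_pos`, `bp_base`, `mismatches`, `max_indel`, `strand`, sorted by
#'   sample, chrom, position, read id), `audit` (data.table: `read_id`,
#'   `mate`, `fail_stage`) and `stage_counts` (named integer vector of reads
#'   surviving each stage).
#' @export
detect_sample <- function(reads, fragment_db, params = default_config()) {
  stopifnot(inherits(fragment_db, "fragment_db"))
  idx <- build_5p_index(fragment_db$five)
  scoring <- params$scoring %||% default_scoring()
  three <- fragment_db$three
  regions <- fragment_db$regions

  empty_calls <- data.table(
    sample_id = character(), read_id = character(), mate = integer(),
    gene_ids = character(), five_region_id = character(),
    three_region_id = character(), same_region = logical(),
    chrom = character(), bp_pos = integer(), bp_base = character(),
    mismatches = integer(), max_indel = integer(), strand = character())
  audit <- data.table(read_id = character(), mate = integer(),
                      fail_stage = character())
  counts <- c(input = nrow(reads), five_matched = 0L, trimmed = 0L,
              three_passed = 0L, consistency_passed = 0L,
              mate_strand_passed = 0L, calls = 0L)
  if (nrow(reads) == 0L) {
    return(list(calls = empty_calls, audit = audit, stage_counts = counts))
  }

  # vectorized prefilter: which reads contain any indexed 20-mer at all
  candidates <- integer(0)
  if (!is.null(idx$pdict)) {
    wide <- which(nchar(reads$sequence) >= idx$width)
    if (length(wide)) {
      hits <- Biostrings::vwhichPDict(idx$pdict,
                                      Biostrings::DNAStringSet(reads$sequence[wide]))
      candidates <- wide[lengths(hits) > 0L]
    }
  }
  no_hit <- setdiff(seq_len(nrow(reads)), candidates)
  audit_rows <- list(data.table(read_id = reads$read_id[no_hit],
                                mate = reads$mate[no_hit],
                                fail_stage = rep("no_match", length(no_hit))))
  call_rows <- list()

  for (i in candidates) {
    read <- reads[i]
    fail <- function(stage) {
      audit_rows[[length(audit_rows) + 1L]] <<- data.table(
        read_id = read$read_id, mate = read$mate, fail_stage = stage)
    }
    matches <- match_5p(read$sequence, idx)
    res <- resolve_unique_5p(matches)
    if (!res$accept) { fail(res$reason); next }
    counts["five_matched"] <- counts["five_matched"] + 1L
    trimmed <- trim_read(read, res$match, umi_len = params$umi_len,
                         min_segment = params$min_segment)
    if (!trimmed$accept) { fail(trimmed$reason); next }
    counts["trimmed"] <- counts["trimmed"] + 1L
    seg <- trimmed$segment$sequence
    al <- align_3p(seg, three, scoring)
    # vectorized equivalent of filter_3p() over all candidate alignments
    pass_flags <- al$mismatches <= params$max_mismatches &
      al$mismatches / nchar(seg) <= params$max_mismatch_rate &
      al$max_indel_len <= params$max_indel
    passing <- al[pass_flags]
    if (nrow(passing) == 0L) {
      # report the filter reason of the best-scoring alignment
      best <- al[best == TRUE]
      fail(filter_3p(best, nchar(seg), params$max_mismatches,
                     params$max_mismatch_rate, params$max_indel)$reason)
      next
    }
    if (uniqueN(passing$fragment_id) > 1L) { fail("multi_3p"); next }
    counts["three_passed"] <- counts["three_passed"] + 1L
    ord <- order(-passing$score, passing$fragment_id, passing$ref_start,
                 match(passing$orientation, c("SENSE", "ANTISENSE")))
    chosen <- passing[ord[1]]
    cons <- consistency_checks(res$match, chosen, regions)
    if (!cons$pass) { fail(cons$reason); next }
    counts["consistency_passed"] <- counts["consistency_passed"] + 1L
    if (!mate_strand_check(read$mate, chosen$orientation)) {
      fail("mate_strand"); next
    }
    counts["mate_strand_passed"] <- counts["mate_strand_passed"] + 1L
    frag <- three[fragment_id == chosen$fragment_id]
    bp <- call_branchpoint(chosen, frag)
    call_rows[[length(call_rows) + 1L]] <- data.table(
      sample_id = read$sample_id, read_id = read$read_id, mate = read$mate,
      gene_ids = cons$shared_genes,
      five_region_id = sub("^5p:", "", res$match$fragment_id),
      three_region_id = chosen$region_id,
      same_region = cons$same_region,
      chrom = bp$chrom, bp_pos = bp$position, bp_base = bp$base,
      mismatches = chosen$mismatches, max_indel = chosen$max_indel_len,
      strand = frag$strand)
  }
  calls <- if (length(call_rows)) rbindlist(call_rows) else empty_calls
  setorder(calls, sample_id, chrom, bp_pos, read_id)
  counts["calls"] <- nrow(calls)
  list(calls = calls, audit = rbindlist(audit_rows), stage_counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write lariat calls, branchpoints and audit log
#'
#' Writes `lariat_calls.tsv`, `branchpoints.bed` (BED6, name = read id,
#' score = mismatches) and `audit.tsv` to `out_dir`.
#'
#' @param detection Result of [detect_sample()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_detection <- function(detection, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(detection$calls, file.path(out_dir, "lariat_calls.tsv"), sep = "\t")
  bed <- detection$calls[, .(chrom, start = bp_pos, end = bp_pos + 1L,
                             name = read_id, score = mismatches, strand)]
  fwrite(bed, file.path(out_dir, "branchpoints.bed"), sep = "\t",
         col.names = FALSE)
  fwrite(detection$audit, file.path(out_dir, "audit.tsv"), sep = "\t")
  invisible(out_dir)
}
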