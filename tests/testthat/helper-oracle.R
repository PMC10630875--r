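# Independent oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own code paths: the aligner oracle
# enumerates alignments recursively, the region oracle works per base, the
# 5' match oracle scans every read window by string comparison.

# Exhaustive-enumeration semi-global alignment oracle (tiny instances only).
# Enumerates every alignment of the full query against a substring of the
# reference (match 0 / mismatch -1 / gap run of length g costing 3 + g by
# default), pruning branches whose running score already falls below the best
# found (all future contributions are <= 0). Returns the optimal score and
# the set of (mismatches, max_indel) pairs realized by optimal alignments.
oracle_align <- function(q, r, match = 0, mismatch = -1,
                         gap_open = -3, gap_ext = -1) {
  stopifnot(match <= 0) # pruning assumes no positive contributions
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  rv <- strsplit(r, "", fixed = TRUE)[[1]]
  m <- length(qv); n <- length(rv)
  open1 <- abs(gap_open) + abs(gap_ext)
  ext <- abs(gap_ext)
  best <- -Inf
  tuples <- new.env(parent = emptyenv())
  push <- function(score, mm, maxrun) {
    if (score > best) {
      best <<- score
      rm(list = ls(tuples), envir = tuples)
    }
    if (score == best) assign(paste(mm, maxrun), TRUE, envir = tuples)
  }
  rec <- function(qi, rj, score, mm, curtype, currun, maxrun) {
    if (score < best) return(invisible())
    if (qi == m) {
      push(score, mm, max(maxrun, currun))
      return(invisible())
    }
    if (rj < n) { # diagonal
      hit <- qv[qi + 1L] == rv[rj + 1L]
      rec(qi + 1L, rj + 1L, score + if (hit) match else mismatch,
          mm + !hit, "M", 0L, max(maxrun, currun))
    }
    # query base against a gap
    if (curtype == "I") {
      rec(qi + 1L, rj, score - ext, mm, "I", currun + 1L, maxrun)
    } else {
      rec(qi + 1L, rj, score - open1, mm, "I", 1L, max(maxrun, currun))
    }
    # reference base against a gap (internal only: not before the first or
    # after the last query base -- those are the free semi-global ends)
    if (qi > 0L && rj < n) {
      if (curtype == "D") {
        rec(qi, rj + 1L, score - ext, mm, "D", currun + 1L, maxrun)
      } else {
        rec(qi, rj + 1L, score - open1, mm, "D", 1L, max(maxrun, currun))
      }
    }
    invisible()
  }
  for (s in 0:n) rec(0L, s, 0, 0L, "S", 0L, 0L)
  tup <- do.call(rbind, lapply(strsplit(ls(tuples), " "), as.integer))
  list(score = best,
       tuples = tup) # matrix: col1 mismatches, col2 max indel run
}

# Brute-force per-base oracle for exclusively intronic regions: a base
# belongs to a gene's exclusive intron iff it lies in the gene body and is
# covered by no exon of any gene on the subtracted strand(s).
oracle_exclusive_regions <- function(genes, subtract_strand = "same") {
  g <- genes$genes; ex <- genes$exons
  out <- list()
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    exi <- if (subtract_strand == "same") {
      ex[ex$chrom == gi$chrom & ex$strand == gi$strand, ]
    } else ex[ex$chrom == gi$chrom, ]
    bases <- seq(gi$start, gi$end - 1L)
    covered <- rep(FALSE, length(bases))
    for (k in seq_len(nrow(exi))) {
      covered <- covered | (bases >= exi$start[k] & bases < exi$end[k])
    }
    keep <- bases[!covered]
    if (!length(keep)) next
    runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = gi$chrom, strand = gi$strand,
      start = vapply(runs, min, 0L), end = vapply(runs, max, 0L) + 1L,
      gene_id = gi$gene_id)
  }
  if (!length(out)) return(NULL)
  regs <- data.table::rbindlist(out)
  regs[, .(gene_ids = paste(sort(unique(gene_id)), collapse = ",")),
       by = .(chrom, start, end, strand)]
}

# All-window 5' match oracle: literal string comparison of every read window
# against every fragment sequence and its reverse complement.
oracle_match_5p <- function(seq, five_fragments) {
  w <- nchar(five_fragments$sequence[1])
  hits <- list()
  for (off in 0:(nchar(seq) - w)) {
    win <- substr(seq, off + 1L, off + w)
    if (grepl("N", win, fixed = TRUE)) next
    for (i in seq_len(nrow(five_fragments))) {
      fs <- five_fragments$sequence[i]
      if (grepl("N", fs, fixed = TRUE)) next
      if (win == fs) {
        hits[[length(hits) + 1L]] <- data.table::data.table(
          fragment_id = five_fragments$fragment_id[i], orientation = "SENSE",
          match_start = off)
      }
      if (win == as.character(Biostrings::reverseComplement(Biostrings::DNAString(fs)))) {
        hits[[length(hits) + 1L]] <- data.table::data.table(
          fragment_id = five_fragments$fragment_id[i],
          orientation = "ANTISENSE", match_start = off)
      }
    }
  }
  if (!length(hits)) {
    return(data.table::data.table(fragment_id = character(),
                                  orientation = character(),
                                  match_start = integer()))
  }
  out <- data.table::rbindlist(hits)
  data.table::setorder(out, match_start, fragment_id, orientation)
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
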