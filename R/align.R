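#' Default alignment scoring
#'
#' Match 0, mismatch -1, gap open -3, gap extend -1: a gap run of length g
#' costs 3 + g. The acceptance region of the downstream filters (mismatch
#' count/rate, maximum indel run) is what decides a read, not the raw score,
#' so the scoring only needs to rank candidate placements sensibly.
#'
#' @return Named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 0, mismatch = -1, gap_open = -3, gap_extend = -1)
}

#' Semi-global alignment of a query against a reference
#'
#' Aligns the full query against any substring of the reference (ends-free in
#' the reference only) under affine gap scoring, and reports the optimal
#' score together with the statistics of one optimal alignment chosen by a
#' deterministic traceback (diagonal preferred over reference-gap over
#' query-gap; among equal-scoring end columns the leftmost). Characters are
#' compared literally, so `N` matches only `N`.
#'
#' @param query,ref Uppercase nucleotide strings.
#' @param scoring Scoring list as from [default_scoring()].
#' @return list with `score`, `ref_start`/`ref_end` (0-based half-open
#'   interval of the reference substring consumed), `mismatches`,
#'   `max_indel_len` (longest single gap run), `total_indel_len`,
#'   `n_gap_runs`, and `ops` (per-query-step operation string over
#'   `M`/`I`/`D`).
#' @export
align_semiglobal <- function(query, ref, scoring = default_scoring()) {
  stopifnot(nchar(query) >= 1L, nchar(ref) >= 1L)
  .align_semiglobal_cpp(query, ref,
                        as.numeric(scoring$match), as.numeric(scoring$mismatch),
                        abs(as.numeric(scoring$gap_open)),
                        abs(as.numeric(scoring$gap_extend)))
}

#' Align a trimmed segment to the 3' splice-site fragments
#'
#' For every THREE fragment, computes the optimal semi-global alignment of
#' the segment in SENSE orientation (segment as sequenced equals the
#' fragment's transcription-orientation sequence) and in ANTISENSE
#' orientation (the reverse complement of the segment is aligned, so that
#' reference coordinates always run in transcription orientation). The
#' best-scoring row is marked, with deterministic tie-breaking: higher score,
#' then lexicographic `fragment_id`, then smaller `ref_start`, then SENSE
#' before ANTISENSE.
#'
#' @param segment Retained 3'-intronic sequence (read orientation), length
#'   at least 20.
#' @param three_fragments THREE-side fragment table.
#' @param scoring Scoring list.
#' @return data.table with one row per (fragment, orientation):
#'   `fragment_id`, `region_id`, `orientation`, `score`, `ref_start`,
#'   `ref_end`, `mismatches`, `max_indel_len`, `total_indel_len`, `best`
#'   (logical, exactly one TRUE when fragments exist).
#' @export
align_3p <- function(segment, three_fragments, scoring = default_scoring()) {
  if (nchar(segment) < 20L) {
    stop("segment shorter than 20 nt", call. = FALSE)
  }
  n <- nrow(three_fragments)
  seg_rc <- revcomp(segment)
  m <- 2L * n
  sc <- numeric(m); rs <- integer(m); re <- integer(m); mm <- integer(m)
  mx <- integer(m); tot <- integer(m)
  for (i in seq_len(n)) {
    frag <- three_fragments$sequence[i]
    for (k in 1:2) {
      q <- if (k == 1L) segment else seg_rc
      al <- align_semiglobal(q, frag, scoring)
      j <- 2L * (i - 1L) + k
      sc[j] <- al$score; rs[j] <- al$ref_start; re[j] <- al$ref_end
      mm[j] <- al$mismatches; mx[j] <- al$max_indel_len
      tot[j] <- al$total_indel_len
    }
  }
  out <- data.table(
    fragment_id = rep(three_fragments$fragment_id, each = 2L),
    region_id = rep(three_fragments$region_id, each = 2L),
    orientation = rep(c("SENSE", "ANTISENSE"), times = n),
    score = sc, ref_start = rs, ref_end = re, mismatches = mm,
    max_indel_len = mx, total_indel_len = tot)
  if (nrow(out)) {
    ord <- order(-out$score, out$fragment_id, out$ref_start,
                 match(out$orientation, c("SENSE", "ANTISENSE")))
    out[, best := FALSE]
    out$best[ord[1]] <- TRUE
  } else {
    out <- cbind(out, best = logical(0))
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
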