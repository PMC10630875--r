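#' Read a paired-end FASTQ sample into a read table
#'
#' Reads R1/R2 FASTQ files (plain or gzipped) into the package's read-record
#' table. Read ids are the pair id: trailing `/1`, `/2` suffixes and any
#' whitespace comment are stripped. Mate-of-origin comes from the file a read
#' was found in (R1 = mate 1, R2 = mate 2); in the CORALL library design
#' read 1 is sense to the transcript and carries the 12 nt UMI prefix.
#'
#' @param fastq_r1,fastq_r2 FASTQ paths; `fastq_r2` may be `NULL` for
#'   single-file input.
#' @param sample_id Sample label attached to every record.
#' @return data.table with columns `read_id`, `mate`, `sequence`, `sample_id`
#'   (sequences uppercase ACGTN).
#' @export
read_sample_fastq <- function(fastq_r1, fastq_r2 = NULL, sample_id = "sample") {
  r1 <- read_one_fastq(fastq_r1, 1L, sample_id)
  if (is.null(fastq_r2)) return(r1)
  r2 <- read_one_fastq(fastq_r2, 2L, sample_id)
  if (nrow(r1) != nrow(r2)) {
    stop("R1/R2 record counts differ (", nrow(r1), " vs ", nrow(r2), ")",
         call. = FALSE)
  }
  rbind(r1, r2)
}

read_one_fastq <- function(path, mate, sample_id) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(ss))
  ids <- sub("/[12]$", "", ids)
  data.table(read_id = ids, mate = mate,
             sequence = toupper(as.character(ss)), sample_id = sample_id)
}

#' Extract unmapped reads from a BAM file
#'
#' Yields reads whose unmapped flag is set, restoring the original sequencing
#' orientation (records stored reverse-complemented by the aligner are
#' reverse-complemented back). Requires the Rsamtools package.
#'
#' @param bam_path Path to a BAM file.
#' @param sample_id Sample label.
#' @return Read table as in [read_sample_fastq()].
#' @export
select_unmapped <- function(bam_path, sample_id = "sample") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("select_unmapped() requires the Rsamtools package", call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE),
    what = c("qname", "flag", "seq"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  flags <- res$flag
  if (length(flags) == 0L) {
    return(data.table(read_id = character(), mate = integer(),
                      sequence = character(), sample_id = character()))
  }
  paired <- bitwAnd(flags, 0x1L) > 0L
  if (any(!paired)) stop("record without mate flags (unpaired) in ", bam_path,
                         call. = FALSE)
  mate <- ifelse(bitwAnd(flags, 0x40L) > 0L, 1L,
                 ifelse(bitwAnd(flags, 0x80L) > 0L, 2L, NA_integer_))
  if (anyNA(mate)) stop("record with neither first- nor second-mate flag in ",
                        bam_path, call. = FALSE)
  seqs <- res$seq
  rev <- bitwAnd(flags, 0x10L) > 0L
  if (any(rev)) seqs[rev] <- Biostrings::reverseComplement(seqs[rev])
  data.table(read_id = res$qname, mate = as.integer(mate),
             sequence = toupper(as.character(seqs)), sample_id = sample_id)
}

#' Filter reads with too many ambiguous bases
#'
#' Discards a read iff its fraction of `N` bases strictly exceeds
#' `max_n_frac` (default 0.05, i.e. "> 5% ambiguous"). Mates are filtered
#' independently: a surviving single mate still enters detection.
#'
#' @param reads Read table.
#' @param max_n_frac Maximum tolerated N fraction (strict inequality).
#' @return list with `kept` (read table) and `discarded` (read table plus a
#'   `reason` column).
#' @export
filter_ambiguous <- function(reads, max_n_frac = 0.05) {
  if (nrow(reads) == 0L) {
    return(list(kept = reads, discarded = cbind(reads, reason = character(0))))
  }
  n_count <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(reads$sequence), "N")[, 1]
  frac <- n_count / nchar(reads$sequence)
  drop <- frac > max_n_frac
  discarded <- reads[drop]
  if (nrow(discarded)) discarded[, reason := "ambiguous_bases"] else
    discarded <- cbind(discarded, reason = character(0))
  list(kept = reads[!drop], discarded = discarded)
}
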