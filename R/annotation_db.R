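#' Parse a GTF annotation into gene models
#'
#' Reads a GENCODE-style GTF (1-based inclusive coordinates) and returns one
#' gene model per `gene_id`, with exons merged across all transcripts. All
#' coordinates are converted to the package-internal 0-based half-open
#' convention. The gene body is taken from the `gene` feature when present,
#' otherwise from the min/max over the gene's exons.
#'
#' @param gtf_path Path to a GTF file. Lines starting with `#` are ignored.
#' @param contig_filter Optional character vector of contig names; features on
#'   other contigs are dropped.
#' @return An object of class `gene_set`: a list with `genes` (data.table:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`) and `exons` (data.table:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`), both 0-based half-open,
#'   exons merged per gene.
#' @export
parse_annotation <- function(gtf_path, contig_filter = NULL) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path, call. = FALSE)
  lines <- readLines(gtf_path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gs <- list(genes = empty_gene_table(), exons = empty_exon_table())
    class(gs) <- "gene_set"
    return(gs)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line ", line_no[which(nf != 9L)[1]],
         ": expected 9 tab-separated fields, got ", nf[which(nf != 9L)[1]],
         call. = FALSE)
  }
  dt <- data.table(
    chrom = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start1 = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    end1 = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L),
    line = line_no
  )
  bad <- which(is.na(dt$start1) | is.na(dt$end1) | !dt$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("malformed GTF line ", dt$line[bad[1]],
         ": non-numeric coordinates or invalid strand", call. = FALSE)
  }
  if (!is.null(contig_filter)) dt <- dt[chrom %in% contig_filter]
  dt <- dt[feature %in% c("gene", "exon")]
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", dt$attrs)
  no_gid <- !grepl('gene_id "', dt$attrs, fixed = TRUE)
  if (any(no_gid & dt$feature == "exon")) {
    stop("malformed GTF line ", dt$line[which(no_gid & dt$feature == "exon")[1]],
         ": exon feature without gene_id attribute", call. = FALSE)
  }
  dt[, gene_id := gid]
  # 1-based inclusive -> 0-based half-open
  dt[, `:=`(start = start1 - 1L, end = end1)]

  exons <- dt[feature == "exon",
              .(start = merge_starts(start, end), end = merge_ends(start, end)),
              by = .(gene_id, chrom, strand)]
  gene_rows <- dt[feature == "gene", .(gene_id, chrom, strand, start, end)]

  gene_ids <- unique(c(gene_rows$gene_id, exons$gene_id))
  span <- exons[, .(start = min(start), end = max(end)),
                by = .(gene_id, chrom, strand)]
  genes <- rbind(gene_rows, span[!gene_id %in% gene_rows$gene_id])
  setkey(genes, gene_id)
  genes <- unique(genes, by = "gene_id")

  # exons must lie inside their gene body
  chk <- merge(exons, genes, by = c("gene_id", "chrom", "strand"),
               suffixes = c("", ".g"))
  out <- chk[start < get("start.g") | end > get("end.g")]
  if (nrow(out)) {
    stop("exon [", out$start[1], ",", out$end[1], ") of gene ", out$gene_id[1],
         " lies outside its gene body", call. = FALSE)
  }
  gs <- list(genes = genes[order(gene_id)],
             exons = exons[order(gene_id, start)])
  class(gs) <- "gene_set"
  gs
}

empty_gene_table <- function() {
  data.table(gene_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer())
}

empty_exon_table <- function() empty_gene_table()

merge_starts <- function(s, e) IRanges::start(IRanges::reduce(IRanges::IRanges(s + 1L, e))) - 1L
merge_ends <- function(s, e) IRanges::end(IRanges::reduce(IRanges::IRanges(s + 1L, e)))

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes,", nrow(x$exons), "merged exons\n")
  invisible(x)
}

#' Compute exclusively intronic regions
#'
#' For each gene, subtracts from the gene body the union of all exons of all
#' genes on the same chromosome (and, by default, the same strand), keeping
#' the maximal leftover intervals. Intervals identical in
#' (chrom, start, end, strand) produced by several genes are collapsed into a
#' single region carrying all contributing gene ids. This removes duplicated
#' or overlapping non-unique intronic sequence arising from overlapping genes
#' and alternative transcripts.
#'
#' @param genes A `gene_set` from [parse_annotation()].
#' @param subtract_strand `"same"` (default) subtracts only exons of genes on
#'   the gene's own strand; `"both"` subtracts exons from either strand.
#' @return data.table with columns `region_id` (`chrom:start-end:strand`),
#'   `chrom`, `start`, `end`, `strand`, `length`, `gene_ids` (comma-joined,
#'   sorted), 0-based half-open, sorted by chrom/start/strand.
#' @export
exclusive_intronic_regions <- function(genes, subtract_strand = c("same", "both")) {
  subtract_strand <- match.arg(subtract_strand)
  stopifnot(inherits(genes, "gene_set"))
  g <- genes$genes
  ex <- genes$exons
  if (nrow(g) == 0L) return(empty_region_table())
  pieces <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i]
    exi <- if (subtract_strand == "same") {
      ex[chrom == gi$chrom & strand == gi$strand]
    } else {
      ex[chrom == gi$chrom]
    }
    body <- IRanges::IRanges(gi$start + 1L, gi$end)
    exr <- IRanges::reduce(IRanges::IRanges(exi$start + 1L, exi$end))
    left <- IRanges::setdiff(body, exr)
    if (length(left) == 0L) next
    pieces[[i]] <- data.table(
      chrom = gi$chrom, strand = gi$strand,
      start = IRanges::start(left) - 1L, end = IRanges::end(left),
      gene_id = gi$gene_id)
  }
  regs <- rbindlist(pieces)
  if (is.null(regs) || nrow(regs) == 0L) return(empty_region_table())
  collapsed <- regs[, .(gene_ids = paste(sort(unique(gene_id)), collapse = ",")),
                    by = .(chrom, start, end, strand)]
  collapsed[, `:=`(
    region_id = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
    length = end - start)]
  setcolorder(collapsed, c("region_id", "chrom", "start", "end", "strand",
                           "length", "gene_ids"))
  setorder(collapsed, chrom, start, end, strand)
  collapsed[]
}

empty_region_table <- function() {
  data.table(region_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), length = integer(),
             gene_ids = character())
}

#' Drop intronic regions shorter than a minimum length
#'
#' Regions shorter than `min_len` (default 300 nt) are removed so that the
#' 20 nt 5' splice-site and 250 nt 3' splice-site fragments of a region can
#' never overlap. The boundary is inclusive: a region of exactly `min_len` is
#' kept.
#'
#' @param regions data.table from [exclusive_intronic_regions()].
#' @param min_len Minimum region length in nt.
#' @param allow_short Set `TRUE` to permit `min_len < 270` (the 20 + 250
#'   fragments would then overlap); otherwise this is a configuration error.
#' @return The filtered region table, input order preserved.
#' @export
filter_min_length <- function(regions, min_len = 300L, allow_short = FALSE) {
  if (min_len < 270L && !isTRUE(allow_short)) {
    stop("min_len < 270 makes the 20 nt and 250 nt fragments overlap; ",
         "pass allow_short = TRUE to override", call. = FALSE)
  }
  regions[regions$length >= min_len, ]
}

#' Extract splice-site fragment sequences
#'
#' For every intronic region, extracts the first `five_len` nt immediately
#' downstream of the 5' splice site and the `three_len` nt immediately
#' upstream of the 3' splice site, in transcription orientation (minus-strand
#' fragments are reverse-complemented genome slices).
#'
#' Plus strand: FIVE = `[start, start+20)`, THREE = `[end-250, end)`.
#' Minus strand: FIVE = revcomp of `[end-20, end)`, THREE = revcomp of
#' `[start, start+250)`. The recorded `start`/`end` columns are always the
#' genomic (forward-strand) interval of the slice.
#'
#' @param regions Region table, every region at least `five_len + three_len`
#'   nt long.
#' @param genome A [Biostrings::DNAStringSet] keyed by contig name (as from
#'   [Biostrings::readDNAStringSet()]), or a path to a FASTA file.
#' @param five_len,three_len Fragment lengths in nt (defaults 20 and 250).
#' @return A list with data.tables `five` and `three`, each with columns
#'   `fragment_id`, `region_id`, `side` (`"FIVE"`/`"THREE"`), `sequence`,
#'   `chrom`, `start`, `end`, `strand`, `gene_ids`.
#' @export
extract_fragments <- function(regions, genome, five_len = 20L, three_len = 250L) {
  genome <- load_genome(genome)
  if (nrow(regions)) {
    if (any(regions$length < five_len + three_len)) {
      stop("all regions must be at least ", five_len + three_len, " nt",
           call. = FALSE)
    }
    missing_contig <- setdiff(unique(regions$chrom), names(genome))
    if (length(missing_contig)) {
      stop("contig absent from genome: ", missing_contig[1], call. = FALSE)
    }
    clen <- setNames(Biostrings::width(genome), names(genome))
    over <- regions[end > clen[chrom] | start < 0L]
    if (nrow(over)) {
      stop("region ", over$region_id[1], " extends past the end of contig ",
           over$chrom[1], call. = FALSE)
    }
  }
  one_side <- function(side) {
    if (nrow(regions) == 0L) {
      return(data.table(fragment_id = character(), region_id = character(),
                        side = character(), sequence = character(),
                        chrom = character(), start = integer(), end = integer(),
                        strand = character(), gene_ids = character()))
    }
    if (side == "FIVE") {
      s <- ifelse(regions$strand == "+", regions$start, regions$end - five_len)
      e <- s + five_len
    } else {
      s <- ifelse(regions$strand == "+", regions$end - three_len, regions$start)
      e <- s + three_len
    }
    seqs <- extract_genome_slices(genome, regions$chrom, s, e, regions$strand)
    data.table(
      fragment_id = paste0(ifelse(side == "FIVE", "5p:", "3p:"), regions$region_id),
      region_id = regions$region_id, side = side, sequence = seqs,
      chrom = regions$chrom, start = as.integer(s), end = as.integer(e),
      strand = regions$strand, gene_ids = regions$gene_ids)
  }
  list(five = one_side("FIVE"), three = one_side("THREE"))
}

#' @keywords internal
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(is(genome, "DNAStringSet"))
  af <- Biostrings::alphabetFrequency(genome)
  other <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(other > 0)) {
    stop("genome contains non-ACGTN characters on contig ",
         names(genome)[which(other > 0)[1]], call. = FALSE)
  }
  genome
}

# extract [start, end) 0-based slices, reverse-complementing on "-"
extract_genome_slices <- function(genome, chrom, start, end, strand) {
  out <- character(length(chrom))
  for (ct in unique(chrom)) {
    idx <- which(chrom == ct)
    v <- Biostrings::Views(genome[[ct]], start = start[idx] + 1L, end = end[idx])
    ss <- as(v, "DNAStringSet")
    neg <- strand[idx] == "-"
    if (any(neg)) ss[neg] <- Biostrings::reverseComplement(ss[neg])
    out[idx] <- as.character(ss)
  }
  toupper(out)
}

#' Write splice-site fragments to FASTA
#'
#' Header format: `fragment_id|region_id|gene_ids|strand|chrom:start-end`
#' (gene ids comma-joined). Round-trips losslessly through
#' [read_fragment_fasta()].
#'
#' @param fragments A fragment data.table (one side of [extract_fragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_fasta <- function(fragments, path) {
  headers <- sprintf("%s|%s|%s|%s|%s:%d-%d",
                     fragments$fragment_id, fragments$region_id,
                     fragments$gene_ids, fragments$strand,
                     fragments$chrom, fragments$start, fragments$end)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(fragments)) {
    writeLines(paste0(">", headers, "\n", fragments$sequence, collapse = "\n"), con)
  }
  invisible(path)
}

#' Read a fragment FASTA written by [write_fragment_fasta()]
#'
#' @param path FASTA path.
#' @return Fragment data.table with the same columns as
#'   [extract_fragments()] output.
#' @export
read_fragment_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    return(data.table(fragment_id = character(), region_id = character(),
                      side = character(), sequence = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_ids = character()))
  }
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  if (any(lengths(parts) != 5L)) stop("malformed fragment FASTA header", call. = FALSE)
  coord <- vapply(parts, `[[`, "", 5L)
  m <- regmatches(coord, regexec("^(.+):([0-9]+)-([0-9]+)$", coord))
  data.table(
    fragment_id = vapply(parts, `[[`, "", 1L),
    region_id = vapply(parts, `[[`, "", 2L),
    side = ifelse(startsWith(vapply(parts, `[[`, "", 1L), "5p:"), "FIVE", "THREE"),
    sequence = as.character(ss),
    chrom = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)),
    end = as.integer(vapply(m, `[[`, "", 4L)),
    strand = vapply(parts, `[[`, "", 4L),
    gene_ids = vapply(parts, `[[`, "", 3L))
}

#' Write intronic regions as BED6
#'
#' Columns: chrom, start, end, region_id, length, strand (0-based half-open).
#'
#' @param regions Region table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_introns_bed <- function(regions, path) {
  bed <- regions[, .(chrom, start, end, region_id, length, strand)]
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build the full intron / splice-site fragment database
#'
#' Convenience composition of [parse_annotation()],
#' [exclusive_intronic_regions()], [filter_min_length()] and
#' [extract_fragments()]; optionally writes `introns.bed`, `fivess.fa` and
#' `threess.fa` to `out_dir`.
#'
#' @param gtf_path,genome GTF and genome FASTA (path or `DNAStringSet`).
#' @param min_intron_len Minimum exclusive-region length (default 300).
#' @param subtract_strand `"same"` or `"both"` (see
#'   [exclusive_intronic_regions()]).
#' @param out_dir Optional output directory.
#' @param five_len,three_len Fragment lengths.
#' @return A `fragment_db`: list with `regions`, `five`, `three` data.tables
#'   and the parameters used.
#' @export
build_intron_index <- function(gtf_path, genome, min_intron_len = 300L,
                               subtract_strand = "same", out_dir = NULL,
                               five_len = 20L, three_len = 250L) {
  genes <- parse_annotation(gtf_path)
  regions <- exclusive_intronic_regions(genes, subtract_strand = subtract_strand)
  regions <- filter_min_length(regions, min_len = min_intron_len)
  frags <- extract_fragments(regions, genome, five_len = five_len,
                             three_len = three_len)
  db <- list(regions = regions, five = frags$five, three = frags$three,
             params = list(min_intron_len = min_intron_len,
                           subtract_strand = subtract_strand,
                           five_len = five_len, three_len = three_len))
  class(db) <- "fragment_db"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_introns_bed(regions, file.path(out_dir, "introns.bed"))
    write_fragment_fasta(db$five, file.path(out_dir, "fivess.fa"))
    write_fragment_fasta(db$three, file.path(out_dir, "threess.fa"))
  }
  db
}

#' @export
print.fragment_db <- function(x, ...) {
  cat("fragment_db:", nrow(x$regions), "exclusive intronic regions (>=",
      x$params$min_intron_len, "nt),", nrow(x$five), "5'SS /", nrow(x$three),
      "3'SS fragments\n")
  invisible(x)
}
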