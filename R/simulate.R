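#' Simulation configuration
#'
#' The generator emulates the library structure the detector assumes: a
#' random multi-gene annotation with introns on both sides of the 300 nt
#' exclusivity threshold, CORALL-style stranded 2 x 150 bp paired-end reads
#' where read 1 is sense and carries a 12 nt UMI prefix, exon-only background
#' mRNA pairs, and planted lariat-junction reads whose 3'-intronic segment
#' ends at a known branchpoint and is followed by the intron's 5' end.
#'
#' Defaults: genes carry 3-6 exons of 100-300 nt; a quarter of introns are
#' short (120-260 nt, below the 300 nt exclusivity threshold) and the rest
#' 320-1000 nt; branchpoints sit 18-45 nt upstream of the 3' splice site
#' (the biologically typical window) and are adenine with probability 0.9;
#' the junction read keeps 20-110 nt of 3'-intronic sequence before the
#' branchpoint; inserts are fixed at 300 nt; sequencing is error-free unless
#' `substitution_rate` / `n_rate` are raised.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_chroms,chrom_len Number and length of chromosomes.
#' @param n_genes Number of genes (alternating strands, round-robin over
#'   chromosomes).
#' @param n_exons_range Exons per gene (introns = exons - 1).
#' @param exon_len_range,intron_len_short,intron_len_long,p_short_intron
#'   Exon/intron length distributions (uniform integer ranges; a short
#'   intron is drawn with probability `p_short_intron`).
#' @param intergenic_gap Range of gaps between genes.
#' @param read_len,umi_len,insert_size Read structure.
#' @param n_background_pairs,n_lariat_reads Read counts.
#' @param bp_offset_range Branchpoint distance upstream of the 3' splice
#'   site (nt).
#' @param split_range Number of 3'-intronic nt (ending at the branchpoint)
#'   in the junction read.
#' @param substitution_rate,n_rate Per-base error rates.
#' @param fraction_mate2_lariats Fraction of junction reads emitted on
#'   mate 2 (antisense path).
#' @param p_bp_adenine Probability the planted branchpoint base is forced to
#'   adenine; detectability never depends on it.
#' @param intron_retention_rate Fraction of background pairs drawn from
#'   unspliced pre-mRNA instead of the spliced transcript (stressor,
#'   default off).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 100000L,
                       n_genes = 20L, n_exons_range = c(3L, 6L),
                       exon_len_range = c(100L, 300L),
                       intron_len_short = c(120L, 260L),
                       intron_len_long = c(320L, 1000L),
                       p_short_intron = 0.25,
                       intergenic_gap = c(500L, 1500L),
                       read_len = 150L, umi_len = 12L, insert_size = 300L,
                       n_background_pairs = 500L, n_lariat_reads = 200L,
                       bp_offset_range = c(18L, 45L),
                       split_range = c(20L, 110L),
                       substitution_rate = 0, n_rate = 0,
                       fraction_mate2_lariats = 0.5,
                       p_bp_adenine = 0.9,
                       intron_retention_rate = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_background_pairs >= 0, cfg$n_lariat_reads >= 0,
            cfg$n_genes >= 0, cfg$substitution_rate >= 0,
            cfg$substitution_rate <= 1, cfg$n_rate >= 0, cfg$n_rate <= 1)
  if (cfg$bp_offset_range[1] < 1 || cfg$bp_offset_range[2] > 250) {
    stop("bp_offset_range must lie within (0, 250]", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random genome and annotation
#'
#' Draws a uniform-base genome, then lays genes round-robin over the
#' chromosomes with alternating strands and random intergenic gaps. Each
#' gene alternates exons and introns per the configured length
#' distributions. Reproducible per seed (the function seeds the RNG).
#'
#' @param config A [sim_config()].
#' @return list with `genome` (named character vector, one string per
#'   chromosome), `genes`, `exons`, `introns` data.tables (0-based
#'   half-open, `introns` additionally carries `region_id` and `length`)
#'   and `gtf_lines` (character vector, 1-based GTF).
#' @export
gen_genome_and_annotation <- function(config) {
  set.seed(config$seed)
  genome <- setNames(vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
          collapse = "")
  }, ""), paste0("chr", seq_len(config$n_chroms)))

  cursor <- setNames(rep(0L, config$n_chroms), names(genome))
  genes <- list(); exons <- list(); introns <- list(); gtf <- character()
  for (gi in seq_len(config$n_genes)) {
    chrom <- names(genome)[((gi - 1L) %% config$n_chroms) + 1L]
    strand <- if (gi %% 2L == 1L) "+" else "-"
    gap <- sample_range(config$intergenic_gap, 1L)
    n_ex <- sample_range(config$n_exons_range, 1L)
    ex_len <- sample_range(config$exon_len_range, n_ex)
    in_len <- if (n_ex > 1L) {
      short <- runif(n_ex - 1L) < config$p_short_intron
      ifelse(short,
             sample_range(config$intron_len_short, n_ex - 1L),
             sample_range(config$intron_len_long, n_ex - 1L))
    } else integer(0)
    span <- sum(ex_len) + sum(in_len)
    start <- cursor[chrom] + gap
    if (start + span > config$chrom_len) {
      stop("gene layout exceeds chromosome length; increase chrom_len or ",
           "reduce n_genes", call. = FALSE)
    }
    cursor[chrom] <- start + span
    gene_id <- sprintf("SIMG%04d", gi)
    # exon/intron coordinates left to right
    pos <- start
    ex_iv <- matrix(0L, n_ex, 2L); in_iv <- matrix(0L, max(n_ex - 1L, 0L), 2L)
    for (k in seq_len(n_ex)) {
      ex_iv[k, ] <- c(pos, pos + ex_len[k]); pos <- pos + ex_len[k]
      if (k < n_ex) { in_iv[k, ] <- c(pos, pos + in_len[k]); pos <- pos + in_len[k] }
    }
    genes[[gi]] <- data.table(gene_id = gene_id, chrom = chrom, strand = strand,
                              start = start, end = start + span)
    exons[[gi]] <- data.table(gene_id = gene_id, chrom = chrom, strand = strand,
                              start = ex_iv[, 1], end = ex_iv[, 2])
    if (n_ex > 1L) {
      # intron rank in transcription order
      rk <- if (strand == "+") seq_len(n_ex - 1L) else rev(seq_len(n_ex - 1L))
      introns[[gi]] <- data.table(gene_id = gene_id, chrom = chrom,
                                  strand = strand, start = in_iv[, 1],
                                  end = in_iv[, 2], intron_rank = rk)
    }
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s.1";', gene_id, gene_id)
    gtf <- c(gtf,
             sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                     chrom, start + 1L, start + span, strand, gene_id),
             sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                     chrom, start + 1L, start + span, strand, attr_str),
             sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                     chrom, ex_iv[, 1] + 1L, ex_iv[, 2], strand, attr_str))
  }
  introns <- rbindlist(introns)
  if (nrow(introns)) {
    introns[, `:=`(region_id = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
                   length = end - start)]
  } else {
    introns <- data.table(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), intron_rank = integer(),
                          region_id = character(), length = integer())
  }
  list(genome = genome,
       genes = if (length(genes)) rbindlist(genes) else empty_gene_table(),
       exons = if (length(exons)) rbindlist(exons) else empty_exon_table(),
       introns = introns, gtf_lines = gtf)
}

# uniform integer draw from [a, b]; safe when a == b (unlike sample(a:b))
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

# transcription-orientation slice of a plain-character genome, [start,end) 0-based
sim_slice <- function(genome, chrom, start, end, strand) {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

random_umi <- function(n, umi_len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * umi_len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate one planted lariat read pair
#'
#' The junction read, in transcription orientation, is the `split` intronic
#' nucleotides ending at the branchpoint followed by the intron's first
#' nucleotides (filling the read). On mate 1 it is emitted as UMI + sense
#' sequence; on mate 2 it is reverse-complemented. The partner mate is drawn
#' from the intronic sequence ending at the branchpoint (the other arm of
#' the circular lariat template).
#'
#' @param region One intron row (list or single-row data.table with `chrom`,
#'   `start`, `end`, `strand`, `region_id`, `gene_id`).
#' @param genome Named character vector of chromosome sequences.
#' @param bp_offset Branchpoint distance upstream of the 3' splice site
#'   (>= 1).
#' @param split Number of 3'-intronic nt (ending at the branchpoint) in the
#'   junction read.
#' @param mate Which mate carries the junction (1 or 2).
#' @param config A [sim_config()] (read structure fields are used).
#' @param read_id Identifier for the pair.
#' @return list with `r1`, `r2` (sequences) and `truth` (one-row data.table
#'   with the exact genomic branchpoint and a detectability verdict).
#' @export
gen_lariat_read <- function(region, genome, bp_offset, split, mate, config,
                            read_id = "LAR000001") {
  L <- region$end - region$start
  if (bp_offset < 1L || split < 1L || bp_offset + split > L) {
    stop("split/bp_offset inconsistent with region length ", L, call. = FALSE)
  }
  intron <- sim_slice(genome, region$chrom, region$start, region$end,
                      region$strand)
  bp_ipos <- L - bp_offset # 1-based intron position of the branchpoint
  bp_pos <- if (region$strand == "+") region$start + bp_ipos - 1L
            else region$end - bp_ipos
  bp_base <- substr(intron, bp_ipos, bp_ipos)
  seg3 <- substr(intron, bp_ipos - split + 1L, bp_ipos)
  five_len <- config$read_len - split - if (mate == 1L) config$umi_len else 0L
  five_len <- max(0L, min(five_len, L))
  five_part <- substr(intron, 1L, five_len)
  core <- paste0(seg3, five_part)
  # partner mate: intronic sequence ending at the branchpoint
  if (mate == 1L) {
    r1 <- paste0(random_umi(1L, config$umi_len), core)
    p_from <- max(1L, bp_ipos - config$read_len + 1L)
    r2 <- revcomp(substr(intron, p_from, bp_ipos))
  } else {
    r2 <- revcomp(core)
    p_core <- config$read_len - config$umi_len
    p_from <- max(1L, bp_ipos - p_core + 1L)
    r1 <- paste0(random_umi(1L, config$umi_len), substr(intron, p_from, bp_ipos))
  }
  reason <- if (L < 300L) "intron_short"
    else if (split < 20L) "segment_short"
    else if (five_len < 20L) "five_short"
    else if (split + bp_offset > 250L) "bp_beyond_fragment"
    else NA_character_
  truth <- data.table(
    read_id = read_id, kind = "lariat", gene_id = region$gene_id,
    region_id = region$region_id, bp_chrom = region$chrom,
    bp_pos = as.integer(bp_pos), bp_base = bp_base,
    mate_carrying_junction = as.integer(mate),
    detectable = is.na(reason),
    reason = ifelse(is.na(reason), "", reason))
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Generate background mRNA read pairs
#'
#' Pairs are drawn from the spliced (exon-only) transcripts of the synthetic
#' genes: mate 1 = UMI + sense sequence, mate 2 = antisense, fixed insert
#' size. With `intron_retention_rate > 0` a fraction of pairs comes from
#' unspliced pre-mRNA instead (gene body including introns).
#'
#' @param config A [sim_config()].
#' @param annotation Output of [gen_genome_and_annotation()].
#' @return list with `r1`, `r2` (character vectors) and `truth` (data.table).
#' @export
gen_background_pairs <- function(config, annotation) {
  n <- config$n_background_pairs
  empty <- list(r1 = character(0), r2 = character(0),
                truth = data.table(read_id = character(), kind = character(),
                                   gene_id = character(), region_id = character(),
                                   bp_chrom = character(), bp_pos = integer(),
                                   bp_base = character(),
                                   mate_carrying_junction = integer(),
                                   detectable = logical(), reason = character()))
  if (n == 0L || nrow(annotation$genes) == 0L) return(empty)
  g <- annotation$genes
  # spliced transcript per gene, transcription orientation
  txs <- vapply(seq_len(nrow(g)), function(i) {
    ex <- annotation$exons[gene_id == g$gene_id[i]][order(start)]
    s <- paste(substring(annotation$genome[[g$chrom[i]]], ex$start + 1L, ex$end),
               collapse = "")
    if (g$strand[i] == "-") revcomp(s) else s
  }, "")
  pre <- vapply(seq_len(nrow(g)), function(i) {
    sim_slice(annotation$genome, g$chrom[i], g$start[i], g$end[i], g$strand[i])
  }, "")
  retained <- runif(n) < config$intron_retention_rate
  gidx <- sample.int(nrow(g), n, replace = TRUE)
  tx <- ifelse(retained, pre[gidx], txs[gidx])
  tx_len <- nchar(tx)
  insert <- pmin(config$insert_size, tx_len)
  from <- floor(runif(n) * (tx_len - insert + 1L)) + 1L # 1-based
  r1_core <- pmin(config$read_len - config$umi_len, insert)
  r1 <- paste0(random_umi(n, config$umi_len),
               substr(tx, from, from + r1_core - 1L))
  r2_len <- pmin(config$read_len, insert)
  r2 <- revcomp_vec(substr(tx, from + insert - r2_len, from + insert - 1L))
  truth <- data.table(
    read_id = sprintf("BG%06d", seq_len(n)),
    kind = ifelse(retained, "background_retained", "background"),
    gene_id = g$gene_id[gidx], region_id = NA_character_,
    bp_chrom = NA_character_, bp_pos = NA_integer_, bp_base = NA_character_,
    mate_carrying_junction = NA_integer_, detectable = FALSE,
    reason = "background")
  list(r1 = r1, r2 = r2, truth = truth)
}

revcomp_vec <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Inject sequencing errors
#'
#' I.i.d. substitutions (to a uniformly drawn different base) at
#' `substitution_rate` and N replacements at `n_rate`, per base, using the
#' ambient RNG stream. Truth records are untouched.
#'
#' @param seqs Character vector of read sequences.
#' @param substitution_rate,n_rate Per-base rates in `[0, 1]`.
#' @return Mutated character vector.
#' @export
inject_errors <- function(seqs, substitution_rate = 0, n_rate = 0) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            n_rate >= 0, n_rate <= 1)
  if ((substitution_rate == 0 && n_rate == 0) || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    len <- length(v)
    if (substitution_rate > 0) {
      at <- which(runif(len) < substitution_rate)
      for (p in at) v[p] <- sample(setdiff(bases, v[p]), 1L)
    }
    if (n_rate > 0) {
      at <- which(runif(len) < n_rate)
      v[at] <- "N"
    }
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate a complete dataset
#'
#' Generates genome, annotation, background pairs and planted lariat pairs,
#' optionally forces planted branchpoint bases to adenine, injects errors,
#' and (when `out_dir` is given) writes `sim_genome.fa`, `sim.gtf`,
#' `sim_R1.fastq.gz`, `sim_R2.fastq.gz` and `truth.tsv`. Planted introns are
#' sampled uniformly from the annotation's introns (short ones included, so
#' the truth table also carries non-detectable records).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return list with `genome` (DNAStringSet), `annotation`, `reads`
#'   (data.table: `read_id`, `mate`, `sequence`), `truth` (data.table) and,
#'   when written, the output `paths`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  ann <- gen_genome_and_annotation(config) # seeds the RNG
  introns <- ann$introns

  # plan lariats, then force branchpoint bases before any read is drawn
  n_lar <- if (nrow(introns) > 0L) config$n_lariat_reads else 0L
  plan <- NULL
  if (n_lar > 0L) {
    ridx <- sample.int(nrow(introns), n_lar, replace = TRUE)
    bp_offset <- sample_range(config$bp_offset_range, n_lar)
    split <- sample_range(config$split_range, n_lar)
    L <- introns$length[ridx]
    split <- pmax(1L, pmin(split, L - bp_offset))
    mate <- ifelse(runif(n_lar) < config$fraction_mate2_lariats, 2L, 1L)
    force_a <- runif(n_lar) < config$p_bp_adenine
    plan <- data.table(ridx = ridx, bp_offset = bp_offset, split = split,
                       mate = mate, force_a = force_a)
    for (i in seq_len(n_lar)) {
      if (!plan$force_a[i]) next
      reg <- introns[plan$ridx[i]]
      bp_ipos <- (reg$end - reg$start) - plan$bp_offset[i]
      # 1-based genome-string position of the branchpoint
      gpos <- if (reg$strand == "+") reg$start + bp_ipos
              else reg$end - bp_ipos + 1L
      base <- if (reg$strand == "+") "A" else "T"
      substr(ann$genome[[reg$chrom]], gpos, gpos) <- base
    }
  }

  bg <- gen_background_pairs(config, ann)
  lar_r1 <- character(n_lar); lar_r2 <- character(n_lar)
  lar_truth <- vector("list", n_lar)
  for (i in seq_len(n_lar)) {
    reg <- introns[plan$ridx[i]]
    lr <- gen_lariat_read(reg, ann$genome, plan$bp_offset[i], plan$split[i],
                          plan$mate[i], config,
                          read_id = sprintf("LAR%06d", i))
    lar_r1[i] <- lr$r1; lar_r2[i] <- lr$r2; lar_truth[[i]] <- lr$truth
  }
  truth <- rbind(bg$truth,
                 if (n_lar) rbindlist(lar_truth) else NULL)
  ids <- c(bg$truth$read_id, if (n_lar) sprintf("LAR%06d", seq_len(n_lar)))
  r1 <- inject_errors(c(bg$r1, lar_r1), config$substitution_rate, config$n_rate)
  r2 <- inject_errors(c(bg$r2, lar_r2), config$substitution_rate, config$n_rate)

  reads <- rbind(
    data.table(read_id = ids, mate = 1L, sequence = r1),
    data.table(read_id = ids, mate = 2L, sequence = r2))
  genome_dss <- Biostrings::DNAStringSet(ann$genome)

  out <- list(genome = genome_dss, annotation = ann, reads = reads,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(out_dir, "sim_genome.fa"),
      gtf = file.path(out_dir, "sim.gtf"),
      r1 = file.path(out_dir, "sim_R1.fastq.gz"),
      r2 = file.path(out_dir, "sim_R2.fastq.gz"),
      truth = file.path(out_dir, "truth.tsv"))
    Biostrings::writeXStringSet(genome_dss, paths$genome)
    writeLines(ann$gtf_lines, paths$gtf)
    write_fastq(ids, r1, paths$r1)
    write_fastq(ids, r2, paths$r2)
    fwrite(truth, paths$truth, sep = "\t")
    out$paths <- paths
  }
  out
}

write_fastq <- function(ids, seqs, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  }
  invisible(path)
}
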