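# Small in-code fixtures shared across test files. Everything is generated
# at test time; nothing is read from disk except what a test writes itself.

# deterministic random genome as a DNAStringSet
toy_genome <- function(lens = c(chr1 = 3000L), seed = 1L) {
  set.seed(seed)
  Biostrings::DNAStringSet(vapply(lens, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, ""))
}

# one GTF feature line, 1-based inclusive coordinates
gtf_line <- function(chrom, feature, start1, end1, strand, gene_id,
                     tx = paste0(gene_id, ".1")) {
  sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, feature, start1, end1, strand, gene_id, tx)
}

write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

# the recurring toy gene: G1 on chr1:+, body (1000,1400) 0-based, exons
# (1000,1100) and (1300,1400), single 200 nt intron (1100,1300)
toy_g1_gtf <- function(extra = character()) {
  write_gtf(c(
    gtf_line("chr1", "gene", 1001, 1400, "+", "G1"),
    gtf_line("chr1", "exon", 1001, 1100, "+", "G1"),
    gtf_line("chr1", "exon", 1301, 1400, "+", "G1"),
    extra))
}

write_test_fastq <- function(ids, seqs, path = tempfile(fileext = ".fastq")) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}

# fragment_db over a single long + strand intron of the toy genome; the
# region is the full intron of a two-exon gene
toy_db <- function(intron_len = 400L, strand = "+", seed = 5L) {
  glen <- 2000L + intron_len
  genome <- toy_genome(c(chr1 = glen), seed = seed)
  # exon1 (500,700), intron (700, 700+intron_len), exon2 (+200)
  i0 <- 700L; i1 <- 700L + intron_len
  gtf <- write_gtf(c(
    gtf_line("chr1", "gene", 501, i1 + 200L, strand, "G1"),
    gtf_line("chr1", "exon", 501, 700, strand, "G1"),
    gtf_line("chr1", "exon", i1 + 1L, i1 + 200L, strand, "G1")))
  build_intron_index(gtf, genome)
}
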