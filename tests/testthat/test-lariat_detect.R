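frag_tab <- function(seqs, ids = sprintf("5p:r%d", seq_along(seqs))) {
  data.table::data.table(
    fragment_id = ids, region_id = sub("^5p:", "", ids), side = "FIVE",
    sequence = seqs, chrom = "chr1", start = 0L, end = nchar(seqs),
    strand = "+", gene_ids = "G1")
}

test_that("5' index resolves sense/antisense and flags ambiguity", {
  set.seed(21)
  f1 <- random_dna(20)
  idx <- build_5p_index(frag_tab(f1))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(f1)))
  m <- match_5p(paste0(random_dna(30), f1, random_dna(10)), idx)
  expect_equal(m[, .(fragment_id, orientation, match_start, match_end)],
               data.table::data.table(fragment_id = "5p:r1",
                                      orientation = "SENSE",
                                      match_start = 30L, match_end = 50L))
  m2 <- match_5p(paste0(random_dna(10), rc, random_dna(30)), idx)
  expect_equal(m2$orientation, "ANTISENSE")
  expect_equal(m2$match_start, 10L)

  # two fragments sharing a 20-mer: the k-mer is ambiguous
  idx2 <- build_5p_index(frag_tab(c(f1, f1), ids = c("5p:rA", "5p:rB")))
  expect_true(all(idx2$kmers$ambiguous))
  # fragments containing N are absent from the index
  withN <- paste0(substr(f1, 1, 19), "N")
  idx3 <- build_5p_index(frag_tab(withN))
  expect_equal(nrow(idx3$kmers), 0L)
  expect_equal(nrow(match_5p(paste0("AAAA", withN, "TTTT"), idx3)), 0L)
  # width validation
  expect_error(build_5p_index(frag_tab(c(f1, random_dna(19)))), "identical length")
})

test_that("match_5p equals the brute-force all-window oracle", {
  set.seed(22)
  for (rep in 1:20) {
    frags <- frag_tab(vapply(1:3, function(i) random_dna(20), ""))
    idx <- build_5p_index(frags)
    seq <- random_dna(120)
    # plant 0-2 occurrences, either orientation
    for (k in seq_len(sample(0:2, 1))) {
      f <- sample(frags$sequence, 1)
      if (runif(1) < 0.5) {
        f <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(f)))
      }
      at <- sample(1:(nchar(seq) - 20 + 1), 1)
      substr(seq, at, at + 19) <- f
    }
    got <- match_5p(seq, idx)[, .(fragment_id, orientation, match_start)]
    want <- oracle_match_5p(seq, frags)
    expect_equal(got, want)
  }
})

test_that("resolve_unique_5p classifies rejection reasons", {
  m <- function(frag, start, amb = FALSE) data.table::data.table(
    fragment_id = frag, orientation = "SENSE", match_start = start,
    match_end = start + 20L, ambiguous = amb)
  expect_equal(resolve_unique_5p(m("f", 1L)[0])$reason, "no_match")
  expect_true(resolve_unique_5p(m("f", 1L))$accept)
  expect_equal(resolve_unique_5p(rbind(m("f1", 1L), m("f2", 40L)))$reason,
               "multi_site")
  expect_equal(resolve_unique_5p(rbind(m("f", 1L), m("f", 40L)))$reason,
               "multi_position")
  expect_equal(resolve_unique_5p(m("f", 1L, amb = TRUE))$reason,
               "ambiguous_kmer")
})

test_that("trim_read keeps the branchpoint side and enforces minimum length", {
  set.seed(23)
  read <- list(read_id = "x", mate = 1L, sequence = random_dna(150))
  m <- function(s, ori) list(match_start = s, match_end = s + 20L,
                             orientation = ori)
  # mate 1, SENSE at 52-72: segment = read[12:52), 40 nt
  t1 <- trim_read(read, m(52L, "SENSE"))
  expect_true(t1$accept)
  expect_equal(t1$segment$source_interval, c(12L, 52L))
  expect_equal(t1$segment$sequence, substr(read$sequence, 13, 52))
  # mate 1, SENSE at 28-48: 16 nt < 20 -> reject
  expect_equal(trim_read(read, m(28L, "SENSE"))$reason, "trim_short")
  # mate 2, ANTISENSE at 60-80: suffix [80,150), 70 nt, no UMI removal
  read2 <- list(read_id = "y", mate = 2L, sequence = read$sequence)
  t3 <- trim_read(read2, m(60L, "ANTISENSE"))
  expect_equal(t3$segment$source_interval, c(80L, 150L))
  expect_equal(nchar(t3$segment$sequence), 70L)
  # boundary: exactly 20 nt retained is kept
  expect_true(trim_read(read, m(32L, "SENSE"))$accept)
  expect_equal(trim_read(read, m(31L, "SENSE"))$reason, "trim_short")
  # offsets outside the read are an internal error
  expect_error(trim_read(read, m(140L, "SENSE")), "internal error")
})

test_that("align_3p finds exact placements and ranks deterministically", {
  set.seed(24)
  frag <- random_dna(250)
  three <- data.table::data.table(
    fragment_id = "3p:r1", region_id = "r1", side = "THREE", sequence = frag,
    chrom = "chr1", start = 1000L, end = 1250L, strand = "+", gene_ids = "G1")
  seg <- substr(frag, 201, 240)
  al <- align_3p(seg, three)
  b <- al[best == TRUE]
  expect_equal(b[, c(ref_start, ref_end, mismatches, max_indel_len)],
               c(200L, 240L, 0L, 0L))
  expect_equal(b$orientation, "SENSE")
  # one substituted base -> one mismatch, same interval
  seg2 <- seg
  substr(seg2, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(seg2, 10, 10))[1]
  b2 <- align_3p(seg2, three)[best == TRUE]
  expect_equal(b2[, c(ref_start, ref_end, mismatches)], c(200L, 240L, 1L))
  # antisense: the reverse complement of the segment aligns as ANTISENSE
  rcseg <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  b3 <- align_3p(rcseg, three)[best == TRUE]
  expect_equal(b3$orientation, "ANTISENSE")
  expect_equal(b3[, c(ref_start, ref_end)], c(200L, 240L))
  expect_error(align_3p(substr(seg, 1, 19), three), "shorter than 20")
})

test_that("semi-global aligner matches the enumeration oracle (small cases)", {
  set.seed(25)
  for (i in 1:60) {
    q <- random_dna(sample(5:12, 1))
    r <- random_dna(sample(12:30, 1))
    im <- align_semiglobal(q, r)
    or <- oracle_align(q, r)
    expect_identical(im$score, or$score)
    expect_true(any(or$tuples[, 1] == im$mismatches &
                    or$tuples[, 2] == im$max_indel_len))
    # reported stats re-score to the reported score
    expect_equal(im$score, -im$mismatches - 3 * im$n_gap_runs - im$total_indel_len)
  }
})

test_that("filter_3p applies the inclusive-keep thresholds", {
  al <- function(mm, indel = 0L) list(mismatches = mm, max_indel_len = indel)
  expect_equal(filter_3p(al(6L), 100L)$reason, "mismatch_count")
  expect_true(filter_3p(al(5L), 60L)$pass)               # 8.3%
  expect_equal(filter_3p(al(5L), 40L)$reason, "mismatch_rate") # 12.5%
  expect_true(filter_3p(al(2L), 20L)$pass)               # 10.0% exactly
  expect_equal(filter_3p(al(0L, 4L), 60L)$reason, "indel")
  expect_true(filter_3p(al(0L, 3L), 60L)$pass)
  expect_equal(filter_3p(al(0L), 60L, unique = FALSE)$reason, "multi_3p")
})

test_that("consistency checks enforce gene, strand, orientation and order", {
  regions <- data.table::data.table(
    region_id = c("chr1:100-500:+", "chr1:800-1200:+", "chr1:100-500:-",
                  "chr2:10-400:+"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 800L, 100L, 10L), end = c(500L, 1200L, 500L, 400L),
    strand = c("+", "+", "-", "+"), length = c(400L, 400L, 400L, 390L),
    gene_ids = c("G1", "G1", "G2", "G3"))
  fm <- function(rid, ori = "SENSE") list(fragment_id = paste0("5p:", rid),
                                          orientation = ori)
  ta <- function(rid, ori = "SENSE") list(fragment_id = paste0("3p:", rid),
                                          region_id = rid, orientation = ori)
  same <- consistency_checks(fm("chr1:100-500:+"), ta("chr1:100-500:+"), regions)
  expect_true(same$pass); expect_true(same$same_region)
  # different genes
  expect_equal(consistency_checks(fm("chr1:100-500:+"), ta("chr2:10-400:+"),
                                  regions)$reason, "gene_mismatch")
  # orientation disagreement
  expect_equal(consistency_checks(fm("chr1:100-500:+", "ANTISENSE"),
                                  ta("chr1:100-500:+", "SENSE"),
                                  regions)$reason, "orientation_mismatch")
  # transcription order on +: FIVE downstream of THREE fails
  expect_equal(consistency_checks(fm("chr1:800-1200:+"), ta("chr1:100-500:+"),
                                  regions)$reason, "order")
  ok <- consistency_checks(fm("chr1:100-500:+"), ta("chr1:800-1200:+"), regions)
  expect_true(ok$pass); expect_false(ok$same_region)
})

test_that("mate/strand rule passes the four protocol scenarios", {
  expect_true(mate_strand_check(1L, "SENSE"))
  expect_false(mate_strand_check(1L, "ANTISENSE"))
  expect_false(mate_strand_check(2L, "SENSE"))
  expect_true(mate_strand_check(2L, "ANTISENSE"))
  expect_error(mate_strand_check(3L, "SENSE"), "mate")
})

test_that("branchpoint coordinates map through fragment intervals", {
  frag <- function(strand, start, end) list(
    chrom = "chr1", start = start, end = end, strand = strand,
    sequence = strrep("A", end - start))
  al <- function(ref_end) list(ref_end = ref_end)
  expect_equal(call_branchpoint(al(250L), frag("+", 1150L, 1400L))$position, 1399L)
  expect_equal(call_branchpoint(al(250L), frag("-", 1100L, 1350L))$position, 1100L)
  expect_equal(call_branchpoint(al(240L), frag("+", 1150L, 1400L))$position, 1389L)
})

test_that("detect_sample calls planted reads and rejects background", {
  db <- toy_db(intron_len = 400L)
  genome <- toy_genome(c(chr1 = 2400L), seed = 5)
  reg <- db$regions[1]
  gchar <- setNames(as.character(genome), names(genome))
  cfgs <- sim_config(seed = 31)
  lr1 <- gen_lariat_read(cbind(reg, gene_id = "G1"), gchar, bp_offset = 30L,
                         split = 40L, mate = 1L, cfgs, read_id = "L1")
  lr2 <- gen_lariat_read(cbind(reg, gene_id = "G1"), gchar, bp_offset = 25L,
                         split = 35L, mate = 2L, cfgs, read_id = "L2")
  set.seed(32)
  reads <- data.table::data.table(
    read_id = c("L1", "L2", "BGX"),
    mate = c(1L, 2L, 1L),
    sequence = c(lr1$r1, lr2$r2, random_dna(150)),
    sample_id = "S1")
  det <- detect_sample(reads, db)
  expect_equal(nrow(det$calls), 2L)
  expect_equal(det$calls[read_id == "L1", c(chrom, bp_pos)],
               c(lr1$truth$bp_chrom, as.character(lr1$truth$bp_pos)))
  expect_equal(det$calls[read_id == "L2", bp_pos], lr2$truth$bp_pos)
  expect_equal(det$audit[read_id == "BGX", fail_stage], "no_match")

  # every emitted call satisfies the hard filters
  expect_true(all(det$calls$mismatches <= 5L))
  expect_true(all(det$calls$max_indel <= 3L))
  expect_true(all(det$calls$same_region))

  # a junction read on the wrong mate fails the mate/strand rule
  wrong <- data.table::data.table(read_id = "L1w", mate = 2L,
                                  sequence = lr1$r1, sample_id = "S1")
  detw <- detect_sample(rbind(wrong,
                              data.table::data.table(read_id = "L1w2", mate = 2L,
                                                     sequence = substr(lr1$r1, 13, 150),
                                                     sample_id = "S1")), db)
  expect_equal(nrow(detw$calls), 0L)
  expect_true("mate_strand" %in% detw$audit$fail_stage)

  # determinism: shuffled input order yields an identical call table
  det2 <- detect_sample(reads[c(3, 1, 2)], db)
  expect_identical(det$calls, det2$calls)
})
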