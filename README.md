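# lariatrace

Split-read detection of intron lariats in paired-end stranded RNA-seq.

## The problem

During pre-mRNA splicing the excised intron is released as a **lariat**: a
loop closed by a 2'-5' phosphodiester bond between the **branchpoint**
(chiefly an adenine 18-45 nt upstream of the 3' splice site) and the
intron's first nucleotide. Lariats are normally linearized by the
debranching enzyme DBR1 and degraded. When debranching is impaired — for
example when DBR1 is destabilized — lariats accumulate, and RNA-seq reads
that traverse the branchpoint become measurably more frequent. Such reads
carry 3'-intronic sequence immediately *followed by* the intron's 5' end, an
order impossible in linear RNA, so spliced aligners leave them unmapped.
`lariatrace` recovers them from the unmapped read fraction and reports
per-sample lariat burden, a direct readout of debranching capacity.

## The method

1. **Intron database.** From a GTF, compute *exclusively intronic regions*:
   each gene body minus the union of all exons of all genes on the same
   strand and chromosome (identical leftover intervals from several genes
   are collapsed). Regions shorter than 300 nt are dropped so the two
   splice-site fragments can never overlap. For each region extract, in
   transcription orientation, the first **20 nt** downstream of the 5'
   splice site and the **250 nt** upstream of the 3' splice site.
2. **5' match.** Scan each unmapped read (after discarding reads with >5%
   ambiguous bases) for exact, unique hits of any 5'SS 20-mer in either
   orientation — equivalent to keeping only perfect, single-site hits of an
   end-to-end alignment of the 20-mers against the reads.
3. **Trim.** Keep the read portion on the branchpoint side of the hit,
   remove the 12 nt UMI from mate-1 reads, and require >= 20 nt remaining.
4. **3' alignment.** Align the retained segment semi-globally (full
   segment vs. any substring of the 250 nt fragment; match 0, mismatch -1,
   gap open -3, gap extend -1). Reject segments with > 5 mismatches, a
   mismatch rate > 10%, a single indel run > 3 nt, or hits to more than one
   3' splice site.
5. **Consistency and mate rule.** The 5' and 3' regions must share a gene
   and strand, agree in orientation, and sit in transcription order. In the
   CORALL stranded protocol read 1 copies the RNA template, so mate-1 hits
   must be sense and mate-2 hits antisense to the gene.
6. **Branchpoint and quantification.** The branchpoint is the genomic
   position aligned to the segment's 3'-terminal base. Per sample,
   `lariats per million (LPM) = n_lariat_reads / (total_reads / 1e6)`;
   groups are compared by the ratio of mean LPM with Welch's unpaired
   t-test. (As an order of magnitude: 263 lariat reads in a 176.5M-read
   library is 1.49 LPM; 1.49 vs 0.12 LPM is a 11.8-fold enrichment.)

A seeded simulator generates the whole stated world — genome, annotation,
background mRNA pairs, planted lariat-junction reads with a truth table —
so every stage is testable without downloads.

## Worked example

```r
library(lariatrace)

cfg <- sim_config(seed = 42, n_genes = 10,
                  n_background_pairs = 200, n_lariat_reads = 50)
sim <- simulate_dataset(cfg, out_dir = "sim")
sheet <- data.frame(sample_id = "SIM", group = "MUT",
                    fastq_r1 = sim$paths$r1, fastq_r2 = sim$paths$r2,
                    total_reads = 2 * (200 + 50))
res <- run_pipeline(sim$paths$gtf, sim$paths$genome, sheet, "out")

res$db
#> fragment_db: 26 exclusive intronic regions (>= 300 nt), 26 5'SS / 26 3'SS fragments
res$summary
#>    sample_id  group n_lariat_reads total_reads lariats_per_million
#> 1:       SIM    MUT             36         500               72000
head(res$detections$SIM$calls[, .(read_id, mate, gene_ids, chrom,
                                  bp_pos, bp_base, mismatches, strand)], 5)
#>      read_id  mate gene_ids  chrom bp_pos bp_base mismatches strand
#> 1: LAR000041     1 SIMG0001   chr1   1705       A          0      +
#> 2: LAR000012     2 SIMG0003   chr1   5333       A          0      +
#> 3: LAR000035     1 SIMG0003   chr1   5333       A          0      +
#> 4: LAR000039     2 SIMG0003   chr1   6026       A          0      +
#> 5: LAR000043     2 SIMG0003   chr1   6981       T          0      +
```

Of the 50 planted lariat reads, 36 meet the detectability conditions (long
enough intron, >= 20 nt on each side of the junction, branchpoint within
250 nt of the 3' splice site) and all 36 are recovered at their exact
planted branchpoint coordinates; the remaining 14 were deliberately planted
in undetectable configurations (e.g. sub-300 nt introns) and produce no
calls. The LPM of 72,000 is only meaningful relative to the toy denominator
of 500 reads — real libraries have 10^7-10^8 reads and LPM values of
order 0.1-10. `bp_base` is reported but never filtered on: branchpoints are
*chiefly* adenine (here forced to A with probability 0.9), not always.

Each sample directory contains `lariat_calls.tsv`, `branchpoints.bed`,
`audit.tsv` (first failing stage per read) and `qc_discarded.tsv`; the run
directory adds `index/` (`introns.bed`, `fivess.fa`, `threess.fa`),
`summary.tsv`, optionally `comparison.tsv`, the resolved `config.json` and
a `manifest.json` with input checksums and per-stage read counts.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/lariatrace.R", package = "lariatrace"))')
Rscript $CLI build-index --gtf ann.gtf --genome genome.fa --out-dir idx
Rscript $CLI detect --index-dir idx --r1 R1.fq.gz --r2 R2.fq.gz \
        --sample-id S1 --out-dir out/S1
Rscript $CLI quantify --calls out/S1/lariat_calls.tsv \
        --samplesheet samples.tsv --group-a MUT --group-b CTR --out-dir out
Rscript $CLI simulate --config sim.json --out-dir sim
Rscript $CLI run --gtf ann.gtf --genome genome.fa \
        --samplesheet samples.tsv --out-dir out
```

Exit codes: 0 ok, 2 configuration error, 3 input error. A JSON/YAML
`--config` file overrides the built-in defaults; every run writes the
resolved configuration next to its outputs.

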