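---
title: "Detecting intron lariats from branchpoint-spanning reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intron lariats from branchpoint-spanning reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The signal being measured

Splicing excises each intron as a lariat: the intron's 5' end is joined to
the branchpoint — an internal nucleotide, chiefly an adenine, typically
18-45 nt upstream of the 3' splice site — by a 2'-5' phosphodiester bond.
The debranching enzyme DBR1 linearizes lariats for degradation; when DBR1
is scarce, lariats persist. A reverse transcriptase traversing the loop
produces cDNA in which 3'-intronic sequence is immediately followed by the
intron's first nucleotides. No linear transcript has that arrangement, so
these reads fail genome alignment and accumulate in the unmapped fraction —
which is exactly where this package looks. The per-sample rate of such
reads, normalized per million sequenced reads (LPM), is a quantitative
proxy for debranching capacity.

## The detection model and its assumptions

A read is called a lariat read iff all of the following hold:

1. it contains an **exact, unique** occurrence of the first 20 nt of
   exactly one exclusively intronic region (either orientation);
2. after removing the matched 20-mer, the UMI (mate 1 only) and everything
   on the 5'-splice-site side, at least 20 nt remain;
3. the retained segment aligns semi-globally to the last 250 nt of some
   single intronic region with at most 5 mismatches, at most a 10% mismatch
   rate, and no gap run longer than 3 nt;
4. the 5' and 3' regions share a gene and strand, both hits have the same
   read-local orientation, and the 5' splice site is at or upstream of the
   3' splice site in transcription direction;
5. the orientation obeys the stranded protocol: mate 1 sense, mate 2
   antisense.

The branchpoint is then the genomic position aligned to the segment's
transcription-orientation 3'-terminal base, and its base is reported but
never filtered on.

Assumptions inherited from this design: the library is stranded with read 1
as the template copy and a 12 nt UMI prefix (CORALL-style); introns of
interest are at least 300 nt after exclusivity subtraction (shorter ones
are invisible by construction); branchpoints more than 250 nt from the 3'
splice site cannot be captured; and lariat abundance is low enough that
per-read calling (at most one call per read) is the right granularity.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_intron_len` | 300 | nt | keeps the 20 + 250 nt fragments from overlapping, with margin |
| `five_len` | 20 | nt | long enough that exact matches are specific, short enough to sit inside a read |
| `three_len` | 250 | nt | covers the biologically plausible branchpoint window upstream of the 3'SS |
| `umi_len` | 12 | nt | UMI length of the assumed library prep |
| `min_segment` | 20 | nt | shorter segments align non-specifically |
| `max_mismatches` | 5 | count | tolerance for sequencing error + RT misincorporation at the branchpoint |
| `max_mismatch_rate` | 0.10 | fraction | same, scaled for short segments |
| `max_indel` | 3 | nt | longest tolerated single gap run |
| `max_n_frac` | 0.05 | fraction | reads with > 5% ambiguous bases are discarded |
| `subtract_strand` | `"same"` | — | see design decisions |

All "greater than" thresholds are strict, so the boundary values pass:
5 mismatches pass and 6 fail; a rate of exactly 10.0% passes; a 3 nt indel
passes and a 4 nt one fails; 20 retained nt pass and 19 fail; a 300 nt
region is kept and a 299 nt one dropped. The acceptance suite pins each of
these boundaries.

## Numerical choices

**5' matching.** Conceptually this stage is an end-to-end alignment of all
20 nt fragments against the reads keeping only perfect, unique hits. Since
the surviving hits of such an alignment are exactly the ungapped perfect
20-mer matches, the implementation uses exact 20-mer lookup over all read
windows (Biostrings `PDict`), which is mathematically equivalent and
deterministic. Fragments whose 20-mer contains an `N` can never match
exactly and are excluded from the index; a 20-mer claimed by two fragments,
or equal to its own reverse complement, is *ambiguous* and any read hitting
it is rejected rather than arbitrarily assigned. A read with several hits
is rejected as `multi_site` (different fragments) or `multi_position`
(same fragment twice) — the conservative reading of "a single 5' splice
site".

**3' alignment.** The retained segment is aligned with an affine-gap
semi-global dynamic program (full query against any substring of the
fragment; match 0, mismatch −1, gap open −3, gap extend −1, i.e. a gap run
of length *g* costs 3 + *g*), implemented in C++ with a deterministic
traceback: diagonal preferred over reference gap over query gap, and the
leftmost end column among score ties. Antisense candidates are aligned as
the reverse complement of the segment, so fragment coordinates always run
in transcription orientation and the branchpoint is always at `ref_end - 1`.
Across fragments, ties break by score, then fragment id, then smaller
reference start, then sense before antisense. The filters — not the raw
score — define the acceptance region, so any optimal aligner reporting
mismatch and gap-run counts reproduces the decision; the score only ranks
placements. Co-optimal alignments can differ in their (mismatch, max-indel)
statistics; the reported pair is the one realized by the deterministic
traceback, and the test suite verifies both that the score equals an
independent exhaustive enumeration's optimum and that the reported pair is
realized by some optimal alignment.

**Degenerate inputs.** Empty FASTQ files yield empty call tables and
all-zero manifests; a zero-gene annotation yields an empty region table; a
`min_intron_len` below 270 nt (where the fragments would overlap) is a
configuration error unless explicitly overridden. Call tables are sorted by
sample, chromosome, branchpoint and read id, so outputs are byte-identical
regardless of read input order.

## Design decisions that were genuinely open

* **Strand-aware exon subtraction.** "Subtract any exon of any gene in a
  strand-aware manner" admits two readings. The default subtracts only
  same-strand exons: an antisense exon does not erase intronic sequence
  that remains uniquely attributable on its own strand, and the stranded
  protocol keeps the two strands separable downstream. `subtract_strand =
  "both"` gives the stricter reading.
* **Overlapping regions.** Maximal subtracted intervals are kept per gene;
  only *identical* intervals are collapsed (carrying all gene ids).
  Overlapping but non-identical intervals from different genes survive
  separately; the uniqueness filters reject reads that cannot be assigned
  to one of them.
* **Indel filter granularity.** "An indel longer than 3 bp" is enforced per
  gap run (`max_indel_len`); total indel length is recorded but not
  filtered, since the wording points at a single event.
* **Proper order across introns.** The order check passes candidates whose
  5' and 3' splice sites come from *different* introns of the same gene in
  transcription order (conceivable multi-intron lariat artifacts);
  `same_region` is recorded on every call so a same-intron-only policy is
  recoverable by filtering.
* **UMI handling.** The 12 nt UMI is trimmed from mate-1 segments; calls
  are *not* deduplicated by UMI by default, since lariat reads are rare and
  the upstream protocol does not state a deduplication step.
* **LPM denominator.** Total sequenced reads in the library (both mates)
  is the default denominator; using the unmapped-read input count is
  allowed but warned about, because it changes the meaning of LPM.
* **Branchpoint base.** Reported, never filtered: branchpoints are chiefly
  but not exclusively adenine, and filtering would bias the readout.

## What the simulator emulates — and what it does not

The generator draws a uniform-base genome, lays non-overlapping genes with
alternating strands (3-6 exons of 100-300 nt; introns 120-260 nt with
probability 0.25, else 320-1000 nt, so both sides of the 300 nt threshold
occur), and emits 2 × 150 nt pairs: background pairs from spliced
exon-only transcripts (mate 1 = UMI + sense, mate 2 = antisense, fixed
300 nt insert) and junction reads built as `split` intronic nt ending at
the branchpoint followed by the intron's first nucleotides, with
`split` ~ U[20, 110] and the branchpoint 18-45 nt upstream of the 3' splice
site, forced to adenine with probability 0.9. Each junction read's partner
mate is drawn from the lariat sequence ending at the branchpoint. Every
planted read carries a truth record with its exact genomic branchpoint and
a detectability verdict (intron ≥ 300 nt, ≥ 20 nt on each side of the
junction after trimming, branchpoint within 250 nt of the 3' splice site).

A green end-to-end test therefore establishes: perfect recovery of
detectable planted junctions at exact branchpoint coordinates, zero calls
on exon-only background, correctness of both mate/orientation paths, and
stability of all of this under permutation of input order and reuse of
seeds. It does **not** establish performance on real libraries:
the simulator has no quality scores, no PCR duplicates, no intron-retention
background by default (available as a stressor flag), no repeats or
homology between genes (uniform random sequence makes 20-mer collisions
vanishingly rare, whereas real genomes have repeat families), no variable
insert sizes, and no reverse-transcriptase mutation signature at the
branchpoint. Absolute LPM values from toy denominators are not comparable
to real libraries. With a 1% substitution rate, recall on a pinned seed is
about 0.8 (the regression test asserts a 0.70 floor): errors inside the
required exact 20-mer are the dominant loss mode, which is a real
limitation of the exact-match design, shared with the perfect-hit filter
it reproduces.

## Known limitations

* Branchpoints farther than 250 nt from the 3' splice site are invisible
  by construction, as are introns shorter than 300 nt after exclusivity.
* One sequencing error inside the 20 nt splice-site word loses the read;
  sensitivity therefore degrades roughly linearly with the per-base error
  rate times 20.
* The unique-site requirements discard reads from recently duplicated
  introns or repeat-rich splice sites; this trades recall for precision.
* Trans-splicing, back-splicing (circRNA) junctions and recursive splicing
  are out of scope and could in principle produce look-alike reads; the
  gene/strand/order consistency checks remove the common cases.
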