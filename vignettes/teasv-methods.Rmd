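---
title: "Split-read detection of TE insertions from noisy long reads: methods"
author: "teasv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read detection of TE insertions from noisy long reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A transposable element (TE) that jumps creates a new junction in the host
genome: on one side of the insertion point the sequence is the original
locus, on the other it is the element. A single long read that crosses such
a junction is split evidence of the insertion — part of the read aligns to a
genomic locus, the adjacent part aligns to the TE. With kilobase-scale reads
this *split-read* signal is unambiguous even at single-molecule error rates
around 13%, because several hundred bases of flank identify a locus uniquely
in a genome the size of *Arabidopsis thaliana*. teasv implements this idea
end to end: a deterministic local aligner tolerant of 10–15% error, two
detection modes, a quantitative replacement for the manual dot-plot
validation step, breakpoint clustering, and a simulator that generates
genomes with planted insertions and nanopore-like reads so that every stage
can be tested against known truth.

## Alignment model

All similarity search uses one scoring scheme: match +2, mismatch −3, gap of
length $k$ costs $5 + 2k$. These are the classic error-tolerant nucleotide
search parameters (reward 2, gap open 5, gap extend 2, with the mismatch −3
that accompanies reward 2 in that scoring family); the package exposes them
in `scoring_scheme()`. Significance is decided by a minimum HSP score
(default 50) and length (default 40 columns) instead of E-values: with a
fixed score floor the result set does not depend on database size and is
fully deterministic.

The aligner is seed-and-extend. Exact 11-mers of the query are looked up in
a k-mer index of the subject; hits are binned by diagonal band (512
diagonals wide) and query locality, and each seed cluster is extended by a
banded affine-gap Smith–Waterman (Gotoh) DP with 100 extra diagonals on
each side of the seed envelope. Within a band the best local alignment is
reported and the flanking query ranges are re-scanned recursively, so an
alignment fragmented by an error burst still yields all its co-linear
pieces. Two details matter for correctness and speed:

* **Exactness on small problems.** When the DP matrix is below
  `full_dp_limit` cells (default 4·10⁶) the band covers every diagonal, so
  the best reported HSP score *equals* the full Smith–Waterman optimum.
  The test suite verifies this against the independent
  `Biostrings::pairwiseAlignment()` implementation on hundreds of random
  pairs.
* **Seed-density filtering.** At 13% error an aligned base is the start of
  an error-free 11-mer with probability 0.87¹¹ ≈ 0.22, so genuine blocks
  produce a seed every ~5 bp. Random 11-mer coincidences, in contrast,
  spread thin: a cluster must contain at least one seed per 300 bp of its
  query span (and at least `min_seeds = 2`), which keeps the number of
  wasted band extensions essentially linear in read length. Without this
  filter the quadratic growth of chance seed pairs makes >20 kb reads
  intractable.

"Contiguously aligned" is operationalised by `chain_blocks()`: co-linear,
same-strand HSPs with query and subject gaps of at most 50 bp (small
overlaps tolerated) merge into a block whose `joined_query_span` is the
union of member query intervals. Indel-rich reads fragment alignments, and
a single-HSP reading of "contiguous" would systematically under-measure
genomic blocks.

## Detection

Both modes share `detection_thresholds()` (defaults in parentheses):

| rule | default | role |
|---|---|---|
| `min_block_len` | 400 bp | smallest genomic block that anchors a breakpoint |
| `max_block_frac` | 0.75 | block may cover at most this fraction of the read |
| `min_te_len` | 200 bp | smallest TE alignment of the read remainder |
| `locus_window` / `flank_pad` | 2 kb / 1 kb | genomic context rebuilt around the locus |
| `min_hsp_sum` | 300 bp (strict) | locus-side alignment sum at validation |
| `hsp_sum_frac_low/high` | 0.33 / 0.75 (inclusive) | locus-side fraction of read length |
| `cluster_tolerance` | 100 bp | breakpoints this close merge into one call |
| `min_genomic_frac` | 0.20 (inclusive) | upstream read-QC retention bound |

**Ab initio mode** (`ab_initio_scan()`) asks, per read: (1) does a genomic
block of ≥ 400 bp cover ≤ 75% of the read; (2) does the rest of the read
align over ≥ 200 bp to some library element *adjacent to that block* on
the read (within 100 bp); (3) does the read agree with its reconstructed
locus? Only reads passing all three yield breakpoint signatures. Every
in-bounds block is considered, not just the best-scoring one: with a
log-normal length distribution a single ~100-kb read regularly spans two
separate insertions, carrying one genuine junction per element, and each
TE alignment on the read supports exactly one signature (a full-span
geometry consumes its element alignment for both flanks, so one spanning
read never double-counts). **Targeted mode** (`targeted_scan()`) starts from the element
instead: it aligns one chosen TE against every read, classifies TE-hit
reads (`full_TE` ≥ 95% element sequence; `split`; `full_span`; `none`), and
locates the non-TE portion on the genome. The same thresholds gate both
modes, which is what makes their validated site sets comparable — a
property the test suite asserts.

**Reference TE copies.** At context construction every library element is
aligned back to the genome and chained matches ≥ `min_te_len` become
annotated reference copies. These annotations serve two purposes. Calls at
such a locus are flagged `is_reference_copy` (the native copy of an active
element is expected to be re-found and must not count as a neo-insertion).
And genomic chains lying mostly (>50%) inside a reference copy are not
allowed to define a read's genomic block: for a junction read whose TE
portion exceeds its flank, the highest-scoring "genomic" chain is otherwise
the TE itself re-found at its native locus, the remainder becomes the
flank, and the read is lost at the TE-library step. Masking these chains
makes block choice mean what it is supposed to mean — locus evidence — and
is the package's resolution of an ambiguity the original protocol (which
also had the native element in its reference) never spells out.

**Locus validation** (`verify_locus_construct()`) automates the manual
dot-plot inspection step: the genomic block, padded by 1 kb on each side,
is concatenated with the element and the read is re-aligned against this
construct. For a split read the locus-side HSP-length sum must exceed
300 bp and comprise 33–75% of the read length. The fraction window is
computed on the **locus side** of the construct, not the whole construct: a
genuine junction read aligns to flank + TE over nearly 100% of its length,
so a whole-construct fraction could never satisfy an upper bound of 75% —
the bound is meaningful only as a constraint on the genomic portion, which
is also how the original protocol's comparison against the extracted
genomic region behaves. `two_sided_junction` records whether locus- and
TE-side alignments approach within 50 bp on the read, and a signature is
only emitted when they do: sum and fraction alone cannot distinguish a
genuine junction from a read whose genomic block ends far from its TE
sequence (for instance when a long flank alignment fragments), which is
precisely the false-positive class that manual dot-plot inspection used to
remove. Requiring the junction to be visible is the automated form of that
inspection.

Full-span reads (entire element plus both flanks, recognised in either
mode when a second unmasked chain sits reference-adjacent across the TE
hit) are validated differently: locus-side sum > 300 bp plus alignment
adjacency at *both* junctions. Their genomic fraction is legitimately small
relative to a 5.3-kb element — a 7-kb read spanning a full element carries
only ~25% flank — so the 33% floor would reject exactly the most
informative read class.

**Clustering and evaluation.** Breakpoint signatures of the same family
within 100 bp on a chromosome merge into one call (single linkage, median
position, strand-consensus orientation; ties are "unknown"). The 100-bp
tolerance comfortably absorbs target-site-duplication offsets (a TSD of
5 bp places the two junction breakpoints 5 bp apart) and alignment-end
jitter at 13% error (observed breakpoint offsets are a few bp).
`evaluate_against_truth()` excludes reference-copy calls, then matches
calls to planted truth within 50 bp, nearest first, each truth record used
once.

## The simulator

`run_benchmark()` chains the whole pipeline under one seed. Its defaults
*are* the study conditions the package targets, and tests never tune them:

* genome: 1 Mb i.i.d. sequence at 36% GC (Arabidopsis-like), carrying one
  native copy of the element so that reference-copy flagging and the
  competition between native and new loci are exercised;
* element: synthetic 5.3-kb LTR retrotransposon with 400-bp terminal
  repeats — the geometry of an active COPIA-like element. The sequence is
  random; no real element sequence is redistributed;
* insertions: ten copy-paste neo-insertions, random orientation, 5-bp
  target-site duplications (the LTR-retrotransposon norm; DNA-transposon
  plans default to 3 bp), spaced ≥ 2 read-medians apart so junctions are
  separable;
* reads: log-normal lengths with median 4.6 kb and sdlog 1.5 — this spread
  puts ~72% of reads between 500 bp and 15 kb, matching the shape of the
  long-read length distribution the method was developed on; per-base
  errors at 13% total, split 50% substitutions, 25% insertions, 25%
  deletions (single-molecule errors are indel-rich; exact shares for the
  early chemistry were never published, so the split is exposed in
  `read_error_model()`); both strands equiprobable; uniform starts,
  truncated at chromosome ends.

The generator plants insertions mechanically (flank–TSD–TE–TSD–flank, the
element reverse-complemented for antisense plans; cut-paste plans also
excise a stated donor) and emits truth records in both coordinate systems:
the input-genome position where a caller will place the breakpoint, and the
mutated-genome interval used for read-origin bookkeeping. Read ids encode
their true template interval, which lets `qualifying_junction_reads()`
decide — from truth alone, without alignment — which reads the detector
*should* convert into signatures: TE overlap ≥ 200 bp plus a flank within
the block bounds (or the full-span variant with ≥ 200 bp flank on both
sides). At 0.8X coverage the recall of the pipeline equals the fraction of
insertions that received at least one such read; at 5X essentially every
insertion has several.

What the simulator does **not** model: homopolymer-conditioned errors,
quality-score correlation, chimeric reads, non-uniform genome composition
(real genomes carry repeat families that multiply the split-alignment FDR
the method's own discussion warns about), and methylation state. Passing
tests therefore demonstrate the correctness of the algorithmic chain under
the stated error model, not performance on arbitrary real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GFF3 output
  converts to 1-based inclusive; BED round-trips byte-identically.
* Boundary semantics follow the stated rules literally: "at least" bounds
  inclusive (20% QC, 400 bp block, 200 bp TE), the 33–75% window inclusive,
  the 300-bp HSP sum strict.
* Medians are lower-interpolation (the lower of the two central values for
  even n), so summaries are identical across platforms.
* Ties in chaining and clustering break by (score, leftmost coordinate);
  cluster output is sorted by (chromosome, position), making
  `cluster_calls()` idempotent and order-invariant.
* Ambiguity characters map to N, never seed an alignment, and score as
  mismatches inside the DP.
* Empty inputs: no HSPs yields empty results, an empty kept set yields a
  zero summary, an empty TE library is a configuration error,
  `mean_identity()` of an empty set is a domain error.
* Locus windows clipped at chromosome ends are noted in the concordance
  result (`clipped`).

## Problem sizes used in the checks

The shipped tests exercise the full design at desk scale: the planted
-insertion benchmark runs on a 1-Mb genome with ten insertions at 5X
coverage (three seeds, aggregated) and 0.8X (one seed); null runs use five
seeds at 0.8X with no insertions; aligner exactness uses 100+ random pairs
of 50–150 bp; smaller worlds (100–200 kb, two to three insertions) back the
unit tests. `scripts/acceptance.R` reruns the 5X and 0.8X benchmarks from
scratch at the same sizes under a caller-supplied seed.

## Known limitations

* Insertions into repetitive or TE-dense reference regions inherit the
  usual split-read ambiguities; the simulator's i.i.d. genome does not
  probe them.
* Zygosity is not called: support counts are reported, but het/hom status
  requires orthogonal evidence.
* Deletions of reference TE copies (absence variants) are out of scope, as
  are somatic-frequency estimation and multi-sample joint calling.
* The ddCt utility implements only the 2^−ΔΔCt arithmetic with a diploid
  calibrator taken as 2; amplification-efficiency correction is not
  modelled, and extrachromosomal element DNA can bias copy estimates
  upward.
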