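---
title: "Methods: dual annotation of alternative splicing at desk scale"
author: "dualsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual annotation of alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Why two pipelines

Exon-centric annotation of alternative splicing (AS) from short-read
RNA-seq comes in two flavours. A *mapping-first* caller aligns reads to the
reference genome, decomposes spliced alignments into blocks, and interprets
junction reads against a transcript annotation. An *assembly-first* caller
assembles reads into a De Bruijn graph (DBG) first and aligns the
assembled variant sequences to the genome afterwards, using the annotation
only as evidence. The two designs fail in complementary ways: the
mapping-first caller cannot see exons or junctions absent from the
annotation and silently discards multi-mapping reads (recent paralogs),
while the assembly-first caller misses lowly expressed isoforms (it needs
the whole alternative path covered by overlapping reads, not just one
junction read), prunes relatively weakly supported junctions inside highly
expressed genes as likely errors, and deliberately skips highly branching
graph regions created by repeat families such as exonised Alu elements.

`dualsplice` implements both callers at desk scale, a shared
negative-binomial test for differential exon usage, a comparator that
mechanises the discrepancy categories above, and a deterministic simulator
that plants each failure mode on purpose so every claim in this vignette is
backed by a test.

## The assembly-first caller

**Graph.** Nodes are canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement), so unstranded libraries assemble into
one double-stranded graph; edges connect k-mers overlapping by k-1 nt and
carry the count of their (k+1)-mer, symmetric under strand. Node counts
conserve the total number of k-mer occurrences in the reads and are kept
per sample. `k` must be odd (no reverse-complement-palindromic k-mers);
41 suits real 76-nt reads, 15 is the toy default used throughout the test
suite, where genes are hundreds of nt.

**Error/noise filtering.** At every branching vertex, edges supported by
less than `relative_cutoff` (default 0.02) of the reads branching out of
(or into) that vertex are removed, in both orientations, and logged. This
is the mechanism by which a local assembler drops sequencing errors and
relatively weak junctions in highly expressed genes; the logged removals
later let the comparator explain why an event was missed.

**Bubbles.** A variation in transcript content appears as a bubble: two
internally vertex-disjoint paths sharing their first and last k-mers.
Enumeration walks the unitig-compressed graph from every branching vertex;
a per-source budget (default 1e5 partial-path extensions) bounds the
search, and bubbles whose two paths traverse more than `max_branches`
(default 5) distinct branching vertices are skipped and counted rather
than enumerated — repeat-induced subgraphs are combinatorial and real
assemblers do not enumerate them either. An exact equivalence test against
brute-force enumeration of all endpoint-sharing vertex-disjoint path pairs
(an independent igraph implementation) runs on 100 seeded random graphs.

**Annotation.** Bubble paths are aligned to the genome by an exact
seed-and-extend spliced aligner (mismatch tolerance 0: the paths were
assembled from the same reads that came from this genome; a SAM import
path would serve parity runs with a real aligner). Anchors slide along the
path (15-mer seeds, shorter fallbacks for paths whose blocks are smaller
than a seed); extension backtracks over candidate intron gaps, preferring
GT-donor block ends and AG-preceded targets, and a final wobble pass
shifts each junction inside its alignment-ambiguity window, in either
direction, onto canonical GT-AG boundaries. Gaps of at least 30 nt are
introns. The block-count signature then classifies the bubble: 3-vs-2
blocks with shared outer boundaries is exon skipping; 1-vs-2 blocks is a
genomic deletion below 50 nt of gap and an intron retention above
(`ir_threshold`, user-configurable); 2-vs-1 is a genomic insertion;
2-vs-2 differing at a single inner boundary is an alternative
donor/acceptor, oriented by gene strand. When a flanking exon is shorter
than k the block count rises on both paths and classification relies on
the block-count *difference*, which is unchanged. Splice sites are looked
up in the annotated donor/acceptor sets; novel sites are reported with
their genomic dinucleotides. Paths aligning to several loci separate into
exact repeats (both paths at both loci — putative AS in a recent
duplication, reported with all loci) and inexact repeats. Bubbles that
differ only by substitutions linked to a nearby polymorphism are merged
and their counts summed.

## The mapping-first caller

Input is one SAM per sample. Records must be mapped, primary and paired
with mapping quality at least 10 (`samtools view -F 260 -f 1 -q 10`
semantics); the MAPQ cutoff is what removes multi-mapping reads, and hence
recent paralogs. CIGAR strings are decomposed into blocks (M/=/X advance
both axes, D stays within a block, N splits blocks, I consumes read only,
S counts as soft-clip); terminal blocks under 4 nt are trimmed as too
short to place reliably. A junction read is dropped when more than 10% of
it is soft-clipped, when an indel lies within 5 nt of a junction (the
junction position would be uncertain; the window is our choice, the
criterion is standard), or when its first or last block overlaps anything
other than exactly one projected exon. Junctions where both boundaries are
novel and shifted by the same amount (within 1 nt) on opposite sides are
discarded as mapping artifacts.

**Projected exons.** Transcript exons are grouped by transitive genomic
overlap; each group becomes one genomic exon whose start is the leftmost
start over the members that are not the first exon of their transcript
(falling back to the leftmost start when only first exons exist), and
whose end is the rightmost end over non-last members ending before the
next group (falling back symmetrically). When a strict majority of the
transcripts containing both exons flanking an intron annotate it as
retained, the two exons and the intron become one merged genomic exon.
The strict-majority reading is our operationalisation of "most frequent
annotation"; with one retaining and one splicing transcript the exons stay
separate.

**Events.** Every covered junction that skips at least one projected exon
is a candidate. If the junction is annotated, one event is emitted per
annotated combination of flanking exons and skipped exon set (so one
exclusion junction can legitimately yield both a single-skip and a
multi-exon-skip event). If it is not annotated, the event is annotated
with the longest covered inclusion isoform: the chain of covered inclusion
junctions through the interior exons with the most exons. Quantification
uses junction reads only: the exclusion count is the exclusion-junction
read count, the inclusion count the mean of the two inclusion junctions,
each summed over all annotated alternative donors/acceptors of that
junction. Blocks that run continuously across an exon-intron boundary are
counted as intron-retention evidence.

## The shared differential layer

Per event, counts follow a negative-binomial GLM,
log lambda_ijk = mu + alpha_i + beta_j + (alpha beta)_ij, with isoform
(variant 1 = inclusion) and condition main effects; the null of no
isoform-by-condition interaction is tested by a likelihood-ratio test with
one degree of freedom and p-values are BH-adjusted across events
(undefined p-values excluded from the number of tests). Effect size is
PSI = inclusion/(inclusion+exclusion) per replicate, masked when a
replicate's total count is below 10 (a ratio of a handful of reads is not
an effect size), averaged within condition; DeltaPSI is the difference and
propagates undefinedness. A call is significant when the adjusted p-value
is at most 0.05 and |DeltaPSI| at least 0.1. Non-integer inclusion counts
(means of two junctions) are rounded half-up before fitting.

**Dispersion.** The NB dispersion is estimated by a bias-corrected moment
estimator on the within-cell (isoform x condition) replication, pooled
across all events of a run and shared by the full and reduced fits of
every event — the approach of the common-dispersion estimators used
throughout the count-based differential-analysis literature. We examined
per-event estimators first: at two replicates per condition, per-event
maximum likelihood collapses toward underdispersion and inflates the
type-I error to ~0.22 at nominal 0.05, while estimating under the null
model absorbs any true interaction into the dispersion and leaves the test
without power. The pooled estimator is calibrated (empirical type-I error
0.057 at nominal 0.05 in the packaged null simulation) and retains power
(~0.8 at 50x coverage for |DeltaPSI| = 0.3). With no replication at all
the dispersion is unidentifiable and the fit falls back to Poisson, the
only honest option in a 2x2 single-replicate design. `fit_and_test()`
accepts an explicit dispersion for users who have an external estimate.

Calibration is checked at dispersion 0.1 (1000 null events, 2x2 design);
DeltaPSI recovery (planted 0.3 at 100x coverage, 200 events, mean absolute
error under 0.05) is assessed at dispersion 0.01, near the read-sampling
limit, because at dispersion 0.1 the replicate-level PSI sampling noise
alone exceeds that error budget regardless of the estimator.

## The comparator

Events are matched on skipped-exon coordinates only — the two pipelines
may choose different flanking exons for the same skipped exon, so flanks
are ignored (exact matching; a small tolerance option exists for
alternative-boundary events, which the assembly side reports as distinct
variants while the mapping side merges them). Poorly expressed isoforms
are filtered with both an absolute and a relative cutoff: minor isoform
under 5 reads, or under 10% of the reads supporting both isoforms. Events
found by one pipeline only are categorised: misses of the mapping-first
caller split into novel-exon, novel-flank and novel-combination by
annotation lookup, or paralog when the assembler flagged an exact repeat;
misses of the assembly split into repeat-overlap (skipped exon intersects
a repeat interval), low-minor-isoform (minor isoform under 5 reads before
filtering) and complex-low-branch (the assembler's log shows the
relative-support filter removed the exclusion junction). Low-minor is
checked before complex-low-branch: a 2-read isoform usually also trips the
relative-support filter, and the scarcity of reads, not the filter, is the
operative explanation.

## The simulator

The generator emulates the structure of a two-condition, two-replicate
polyA RNA-seq comparison: a single-contig genome of multi-exon genes with
canonical GT-AG introns; a complete transcript annotation except where a
scenario says otherwise; 76-nt proper read pairs (insert 180 nt) tiling
each expressed isoform uniformly, with per-replicate fragment numbers
drawn NB around the planted inclusion-rate weights times the junction
coverage; and a ground-truth SAM with spliced placements, MAPQ 50 for
unique placements and MAPQ 0 plus a secondary record for reads lying
wholly in duplicated sequence — so the mapping-first caller's filters are
exercised without running an aligner (a real aligner's SAM can be supplied
instead). Default conditions: 20 genes, 30 skipping events, junction
coverage 50, NB dispersion 0.05, condition-1 PSIs uniform on [0.2, 0.65],
half the events shifted by ±0.3, substitution errors off (the
relative-support filter, not error correction, is the mechanism under
test). Engineered scenarios plant one case each of: a novel exon absent
from the annotation; a verbatim gene duplication (every read
multi-mapping); a repeat-derived annotated exon whose ~300-nt unit recurs,
diverged by ~4%, inside six expressed single-exon background genes (the
divergence is what makes the graph around the exon highly branching); a
2-read minor isoform under 3x-coverage inclusion; a relatively weak
exclusion junction (~15% of its own event but under 2% of the reads
branching out of the shared vertex, thanks to a highly expressed companion
gene sharing the terminal 20 nt of the flanking exon); a 12-nt flanking
exon; an intron retention; and a 30-nt genomic deletion.

What the simulator does not model: sequencing-error profiles, library
chemistry, minus-strand genes (strand handling is exercised by constructed
fixtures instead), expression of introns or intergenic DNA, alternative
first/last exons, and between-sample library-size differences (counts are
local junction counts and no normalisation is applied — a caveat for real
data with very unequal depths). Passing tests therefore demonstrate the
mechanisms, not performance on real libraries.

## Numerical and design choices

* Coordinates are 1-based inclusive on all GTF-facing interfaces; BED
  output is 0-based half-open.
* Bubble path lengths are bounded: the longer path at most 1000 nt plus
  the flanks (exon-sized inserts), the shorter at least k+1 nt. Path
  spells include both shared end k-mers, and junction ambiguity (the two
  continuations sharing their first or last bases) shortens a
  pure-junction spell below 2k, so the lower bound is deliberately
  permissive.
* Equal-length bubble paths (possible for inexact repeats) are ordered
  lexicographically; classification does not depend on the choice. Each
  bubble is reported in the orientation with the lexicographically smaller
  key, making output byte-stable.
* Assembly event quantification counts junction reads (reads spanning a
  path-specific junction with at least 4 nt on each side), the same
  convention as the mapping-first caller; the raw per-path read support is
  kept on the bubble records.
* The enumeration budget (1e5 partial paths per source) turns pathological
  regions into logged skips instead of hangs; branch-bound pruning usually
  triggers first.
* Event identifiers, file ordering and JSON digit settings are fixed so a
  fixed seed reproduces byte-identical outputs.
* Degenerate inputs: empty FASTA/GTF error or warn explicitly; an isoform
  with all-zero counts yields an NA p-value flagged `degenerate`, never an
  exception; unmapped bubble paths are logged and skipped.
* Problem sizes in the packaged checks — 20 genes/30 events at 50x for the
  concordance run, 8 plain genes plus five scenarios for the discrepancy
  run, 1000 events for calibration, 100 random graphs for the enumeration
  oracle, 4-5 genes for determinism — were chosen as the smallest sizes at
  which every mechanism is exercised with comfortable statistical margins.

## Known limitations

The toy spliced aligner assumes error-free paths (configurable mismatch
tolerance is not implemented; import of externally produced SAM is).
Multi-gene overlaps list all genes rather than resolving one. The
assembly caller does not type SNP-only bubbles. Condition designs beyond
two conditions are out of scope, as is exonic-read quantification, which
pollutes pairwise comparisons of complex events. Which paralogous locus
expresses which isoform is undetermined by design.
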