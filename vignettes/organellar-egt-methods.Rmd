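---
title: "Methods: organellar assembly and endosymbiotic transfer detection"
author: "orgEGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organellar assembly and endosymbiotic transfer detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

Plant cells carry three genomes, and sequence moves among them: plastome
segments lodge in the mitogenome (MTPTs), and both organellar genomes leave
copies in the nucleus (NUPTs and NUMTs). orgEGT implements the complete
computational workflow for studying these transfers in a *Solanum*-like
system: assembling a circular mitogenome from short paired-end reads by
baiting and iterative extension, quantifying its exact duplicated regions,
mapping syntenic blocks and rearrangements between related mitogenomes, and
calling, deduplicating, and summarizing the transfers themselves. Every
step runs end-to-end on a synthetic genome trio whose ground truth is known
exactly, which is what makes the pipeline testable.

## The synthetic study system

`sim_config()` defaults describe a 1/10 linear scale-down of the real
system, so that the full pipeline runs in well under a minute on one core
while preserving the statistical structure the methods rely on:

* **Plastome** (15.5 kb): the quadripartite LSC--IRa--SSC--IRb layout with
  IRb the exact reverse complement of IRa (scaled from the ~155 kb, 25.5 kb
  IR plastome of tomato). Background sequence is i.i.d. at 45% GC, matching
  the organellar GC content of Solanaceae.
* **Mitogenome** (42.4 kb, circular): exact repeat families (a 2 kb direct
  pair, a 300 bp inverted pair, a 150 bp direct pair; union 4.9 kb, about
  12% of the genome, the duplication fraction observed in tomato
  mitogenomes) and three plastome implants of 256, 32 and 701 bp drawn from
  the LSC, SSC and IR respectively -- a 1/10 scaling of the 2,558 / 32 /
  7,008 bp compartment totals reported for tomato, with the 32 bp SSC
  segment kept at full size because it is the smallest-detectable case.
* **Nuclear chromosomes** (3 x 100 kb): scattered small implants and
  tightly clustered large implants from both organelles, degraded by
  substitutions (divergence 0--0.05) plus indels at one tenth the
  substitution rate (geometric lengths, capped at 10 bp). Clustered groups
  sit inside one window at most five times their total length, with
  spacers up to 500 bp. Implant density is a few-fold higher than the
  ~0.2--0.4% observed in real tomato chromosomes so that desk-scale
  chromosomes carry enough events to measure recall.
* **Reads**: 200x paired-end coverage, 100 bp reads, inserts Normal(400,
  60), uniform starts honoring circularity, constant Q40 qualities, error
  rate 0 by default (the study's quality trimming is modeled as a
  pass-through). Mixture weights let plastome reads over-represent shared
  MTPT regions, reproducing the characteristic high-depth peaks used for
  coverage QC. Read length and insert geometry are configuration, not
  claims about the original sequencing runs, which did not publish them.

**Breakpoint disambiguation.** After implanting a segment, the generator
redraws any host base within 12 bp of the junction that equals the
source-genome continuation base. Without this, a chance-matching flank
(probability 1/4 per base) is indistinguishable *in principle* from a
slightly longer transfer, and exact-recovery checks of implant coordinates
would be ill-posed. Twelve bases suffice because the aligner's X-drop
terminator (20 score units at mismatch -2) can never carry an extension
through ten consecutive mismatches.

Every implant and repeat is logged in a `GroundTruth` event table; the
table is exhaustive (a conservation test verifies that every base that
differs from the pre-implant background lies inside a logged event), and
`validate_against_truth()` scores calls against it by reciprocal 50%
overlap.

What passing on this generator does *not* show: robustness to sequencing
error profiles, heteroplasmy, transposable-element decay of nuclear
copies, or the seed-table scaling needed for gigabase nuclear genomes.
The generator's background is uniform random sequence, which is
repeat-free at these scales; real intergenic DNA is not.

## Assembly by baiting and iteration

"Mapping with zero mismatches" is operationalized as exact matching
throughout:

1. **Baiting** (`bait_reads()`): a read pair is recruited when either mate
   shares one exact 31-mer (either strand) with a bait; ahead of contig
   building, `map_reads_exact()` applies the stricter zero-mismatch
   full-read criterion, which excludes reads from diverged nuclear copies
   (their fixed substitutions break exact matching) while retaining every
   error-free organellar read.
2. **Contigs** (`build_contigs()`): maximal unbranched paths of the k = 63
   de Bruijn graph over both strands -- zero mismatches by construction,
   with per-base read support recorded.
3. **Iterative extension** (`extend_iterate()`): each iteration recruits
   reads sharing a 31-mer with the current contigs, rebuilds the graph over
   contigs plus recruits, merges unbranched paths, and attempts repeat
   resolution; total assembled length never decreases, and iteration stops
   at convergence.
4. **Circularization** (`circularize()`): an exact terminal overlap of at
   least 50 bp is trimmed and the genome emitted at its canonical rotation
   (the lexicographically minimal rotation of the smaller of sequence and
   reverse complement), so independent assemblies of the same molecule are
   byte-comparable.

**Repeat resolution.** Repeats longer than k collapse into single unitigs.
Copy numbers are estimated from coverage relative to the length-weighted
median, and a depth-first search enumerates closed traversals of the
condensed graph using each unitig (in either orientation) its copy number
of times. A single direct-repeat pair admits exactly one such traversal,
so a 4 kb repeat in a 40 kb circle is recovered without guessing even when
no read or insert spans it. Because coverage-derived copy numbers are
heuristic -- plastome-derived reads inflate MTPT depth without adding
mitochondrial copies -- candidate copy-number vectors are tried in order of
distance from the coverage estimate, pruned by node-degree balance, and
the first vector admitting a traversal wins. When several distinct
traversals remain (interleaved repeat families; the flip isomer of an
inverted repeat), paired-end concordance decides: each candidate sequence
is scored by the number of read pairs placeable with inward-facing mates
at fragment length at most `max_insert`, and only a strict winner is
accepted. Residual ties are surfaced as ambiguity rather than resolved
arbitrarily -- the honest answer for a genome that recombines through its
repeats. An early greedy design extended contig ends by per-base majority
consensus; at a repeat exit with balanced read support that coin-flips the
wrong way half the time, which is why graph traversal plus pair
concordance replaced it.

**Coverage QC** (`coverage_profile()`): reads are re-anchored by exact
31-mers; intervals under 200x are flagged low, intervals at or above five
times the median flagged as plastome-like high-depth (MTPT candidates).

## Local alignment and E-values

`find_hsps()` is a seed-and-extend local aligner: exact 11-base words on
both strands, banded affine-gap extension (band half-width 50, X-drop 20)
with full traceback for identity and gap accounting. Scoring is
blastn-like: match +1, mismatch -2, gap open -5, gap extend -2 (a gap of
length g costs open + g x extend). Identity counts gap columns. E-values
use the Karlin--Altschul form E = K m n exp(-lambda S) with K = 0.46,
lambda = 1.28, the published gapped-nucleotide constants for this scoring
scheme; with generic placeholder constants a 32 bp exact hit -- the
smallest compartment transfer the analysis must detect -- could never
reach the 1e-5 threshold at these genome sizes, so the thresholds would
lose their customary meaning. On implanted-segment benchmarks the best
HSP score equals the full Smith--Waterman optimum (checked against an
independent dynamic-programming implementation in the tests); the
guaranteed bound asserted is 95% of the optimum whenever the optimum is
at least 50.

Thresholds follow the analysis conventions: e-value <= 1e-5 with word
size 11 and up to 50,000 hits for transfer calling; e-value <= 1e-10 for
mitogenome structural comparison. The 50,000-hit cap applies after the
e-value filter and before any downstream deduplication.

## Repeats, transfers, synteny

**Exact repeats** (`find_exact_repeats()`): all maximal repeated pairs >=
100 bp, zero mismatches, both orientations, found by left-maximal seed
extension and verified in the tests against an independent offset-scan
oracle; circular genomes are doubled and wrapped pairs deduplicated.
"Length of duplicated regions" is the union of all member intervals --
the one convention that cannot double-count overlapping families; the
sum-of-pair-lengths figure is emitted alongside for comparison.

**Transfer calling** (`call_transfers()`): class follows the role pair
(plastome->mitogenome MTPT, mitogenome->nucleus NUMT, plastome->nucleus
NUPT); direction of mito/nuclear sharing is deliberately not inferred --
every shared segment is a NUMT. One retained HSP is one call.
`dedup_repeat_hits()` removes repeat-induced multiple hits: calls whose
targets overlap reciprocally by >= 50% and whose sources lie in members of
one exact-repeat family collapse to the best-scoring call (idempotent).
The 50% rule and family linkage are conventions of this package; they are
configuration, with the consequence that a call straddling a repeat
boundary can leave a partial secondary hit behind. Plastome-side totals
(`attribute_compartment()`) project IRb hits onto IRa before taking
unions, so the two IR copies count once; mitogenome-side coverage is
reported separately. Note one measurable consequence of shared sequence:
a nuclear NUPT drawn from the plastome IR also matches the mitogenome's
MTPT region, so class-pure precision against the truth log sits slightly
below 1 on the default conditions -- those "false" positives are real
shared segments, exactly what the no-direction-inference rule predicts.

**Summaries and clusters**: `summarize_by_chromosome()` reports count,
mean/median/max/min lengths, the same restricted to >= 250 bp, cumulative
union bp and percent per chromosome plus a genome rollup;
`cluster_large_fragments()` single-links calls >= 1 kb with gaps <= 100 kb
and reports clusters of two or more members; `dotmatrix_report()` lists
large fragments of a nuclear region against an organelle and flags mosaic
regions (fragments from organellar loci > 10 kb apart, or mixed
orientations).

**Synteny** (`find_synteny_blocks()`): HSPs at e-value <= 1e-10 are
chained collinearly (same orientation, gaps <= 500 bp on both genomes,
small overlap tolerance for extension overshoot at breakpoints), then
filtered to blocks > 1 kb containing at least one annotated gene, and
trimmed to be non-overlapping on the first genome. The chaining gap is a
package convention; only the block filter is fixed by the analysis
definition. `conserved_fraction()` partitions each genome's own
coordinates by homology to the other two (duplications make shared
lengths asymmetric, which is why per-genome rather than symmetric lengths
are reported, summing exactly to genome length). `ribbon_map()` bins each
HSP by score / max score at 0.25 / 0.50 / 0.75; the ratio is
scale-invariant, so raw scores and bit scores bin identically.
`find_orfs()` reports ORFs >= 303 bp starting ATG and ending at a stop
(stop included), six frames, honoring circularity, longest ATG per stop
by default.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  inclusive, BED stays 0-based half-open.
* Ties in circularization (nested terminal overlaps) resolve to the
  longest overlap.
* Degenerate inputs: empty read sets warn and flag everything low; empty
  HSP sets are valid results; zero-variance columns make correlations an
  error rather than NaN.
* `N` never matches anything in exact-match contexts (baiting, repeats,
  de Bruijn k-mers): conservative for repeat and baiting logic.
* The derived mitogenome trio used in the structural analyses applies two
  4 kb inversions and one 1 kb novel insertion per variant, keeping the
  trio >97% mutually conserved -- the regime the structural comparison is
  designed for.
* Single global seed; each stage derives an offset stream, so any stage
  reruns byte-identically in isolation.

## Problem sizes

The shipped tests and the acceptance script use the desk-scale defaults
above: 40--42 kb mitogenomes at 200--250x for assembly (about 25,000 read
pairs per seed, twenty seeds in the recovery property), 100 genomes of
0.8--2 kb for the repeat-oracle equivalence, 100 pairs of about 2 kb
against the Smith--Waterman oracle, and 60 nuclear implants across three
100 kb chromosomes for recovery. The full default pipeline (simulate,
assemble, repeats, transfers, synteny) completes in roughly half a minute
on one core.

## Known limitations

* The naive seed table is quadratic-prone on low-complexity sequence and
  unindexed beyond desk scale; gigabase nuclear genomes need an external
  seeder.
* Copy-number estimation assumes roughly uniform coverage; heavy GC bias
  would mislead the multiplicity prior (though pair concordance still
  arbitrates).
* Inverted-repeat flip isomers are reported as ambiguous whenever no
  read pair spans the repeat; this mirrors the biology but means some
  simulated configurations legitimately fail to close.
* Dating of transfers, phylogenetic attribution of transfer origin, and
  hotspot inference are out of scope.
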