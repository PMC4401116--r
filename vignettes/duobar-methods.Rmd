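---
title: "Reconstructing full-length COI barcodes from two multiplexed amplicon fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing full-length COI barcodes from two multiplexed amplicon fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duobar)
library(dplyr)
```

## The problem

The standard animal DNA barcode is the 658-bp 5' region of mitochondrial
cytochrome c oxidase subunit I (COI). A 300 x 2 paired-end short-read run
cannot span 658 bp in one amplicon, so the region is amplified as two
overlapping sub-fragments per specimen -- a 5' fragment ("FC") and a 3'
fragment ("BR") that share 82 bp -- and the full-length barcode is
reconstructed informatically. Thousands of specimens are multiplexed on
one flowcell by tagging every amplicon with a 5-mer well index (MID) at
*both* ends, drawn from two published 20-entry lists (20 for FC, 20 for
BR, 40 distinct 5-mers in all), with plate-level pooling on top.

duobar implements the complete informatic side of this design: paired-end
merging, dual-MID demultiplexing with degenerate-primer trimming,
dereplication, de novo chimera screening, greedy 99%-identity clustering,
FC x BR compatibility screening and overlap assembly, abundance-based
barcode calling, best-hit identification, and K2P/neighbor-joining
distance analysis -- plus a seeded simulator that generates ground-truthed
plates so every stage is testable at desk scale.

## Pipeline stages and their parameters

All defaults are collected in `pipeline_config()` and correspond to the
published operating point of the protocol.

**Merging** (`merge_pairs()`). All ungapped overlaps between the forward
read and the reverse-complemented reverse read are scanned longest-first;
the first overlap of >= 25 bp with <= 2% mismatches is accepted.
Longest-first with first-accept is a deterministic tie-break; the
underlying merger tools do not document theirs. At agreeing overlap
columns the consensus quality is the maximum of the two Phred scores; at
disagreements the higher-quality base wins (ties to the forward read) and
the quality is `|q1 - q2|`, the usual convention for overlap mergers.

**Quality and length gates** (`quality_gate()`, `length_gate()`). The
protocol's "minimum Phred quality score of 20" is read as a mean-quality
filter on the merged read -- the least destructive interpretation, and
deliberately isolated in one function so a per-base reading could replace
it without touching anything else. Length windows of 300-400 bp (FC) and
400-500 bp (BR) are applied to the raw merged read, i.e. before index and
primer removal, matching the published order of operations. A per-base
quality-trimming alternative was considered and rejected as it would
change read lengths before the windows are applied.

**Demultiplexing** (`assign_wells()`). A merged amplicon read carries a
5-mer MID at each end (the 3' one reverse-complemented). The ordered pair
(first 5-mer, revcomp of last 5-mer) is looked up in the plate's mapping
table; both read orientations are tried, and a read whose orientations
resolve to different wells is left unassigned rather than guessed.
MID matching is exact: with 5-mer tags, one tolerated mismatch already
collides with other table entries. Primers are then located within a
30-nt window inward of each MID, allowing 2 mismatches, with IUPAC codes
and inosine matching their base sets; reads whose MIDs matched but whose
primers could not be located are kept with MID-only trimming (flagged
`primer_trimmed = FALSE`) and left to the downstream gates. The published
design does not fix how the 20+20 MID lists encode 96 wells, so the
layout travels explicitly in the mapping file; `default_mapping()`
enumerates ordered in-list pairs `(i, j)` with `i < j`, which guarantees
that a pair and its swap are never both assigned and keeps demultiplexing
orientation-unambiguous.

**Dereplication, chimera screen, clustering** (`dereplicate()`,
`detect_chimeras()`, `greedy_cluster()`). Within each specimen and
fragment, exact duplicates are collapsed with counts retained (singletons
kept). The chimera screen follows the de novo two-parent crossover logic
of UCHIME with its published defaults (parents at >= 2x the query's
abundance, query divergence >= 0.008 from every candidate parent, vote
score h >= 0.28 with "no" votes weighted 8x), since the protocol names the
algorithm but no parameters. Clustering is greedy centroid assignment in
descending-abundance order (ties lexicographic -- full determinism without
a seed) at 99% identity, where identity is matching columns over
alignment columns of a global alignment scored +1/-1 with gap open -2 and
extend -1; identity denominators differ between tools and this one is
fixed and documented. Equal-length pairs with small Hamming divergence
take a direct column-compare fast path under which a gapless alignment is
score-optimal; an always-aligning oracle audits this in the tests. The
order of operations is dereplicate, then chimera-filter, then cluster;
the source protocol interleaves these across two pipelines without fixing
the order, so ours is stated, not inferred.

**Fragment pairing** (`screen_pair()`, `assemble_pair()`,
`pair_specimens()`). Candidate FC x BR cluster pairs must share a
high-scoring ungapped segment (HSP) of >= 25 bp at >= 98% identity with
<= 2 mismatches; the search is an exhaustive diagonal scan, exact by
construction, and both BR orientations are tried. Accepted pairs are
assembled through the best suffix(FC)/prefix(BR) overlap of >= 80 bp with
<= 2% mismatches; overlap disagreements take the base of the larger
cluster (ties to FC). When several clusters exist on each side, pairing
is greedy one-to-one by descending `min(fc_size, br_size)` -- the
protocol pairs "the two fragments of each individual" without defining
multi-cluster behaviour, and greedy-by-support is deterministic and
logged. The support of an assembled barcode is `min(fc_size, br_size)`,
the quantity the abundance rule consumes; the protocol does not define a
per-barcode abundance after assembly, so the most conservative of the two
fragment abundances is used. Assembly is ungapped (merger-style);
indel-bearing amplicons fail assembly and are counted.

**Calling and identification** (`call_barcodes()`, `best_hit()`).
Per specimen, sequences with support strictly greater than 10% of total
support are reported, and the specimen is classified none / single /
multiple. ">10%" is read as a strict inequality and tested at the
boundary. Identification is a local stand-in for a public-database
search: the label of the reference with the highest global-alignment
identity, ties to the earlier record. A composition-based upper bound
(shared base counts over the longer length) prunes references that
cannot beat the current best; the bound is sound, so the result equals
the exhaustive scan.

**Distances and trees** (`k2p()`, `k2p_matrix()`, `nj_tree()`,
`sanger_concordance()`). Kimura 2-parameter distances
(`d = -1/2 ln((1-2P-Q) sqrt(1-2Q))` with transition fraction P and
transversion fraction Q) and Saitou-Nei neighbor joining are computed
with ape; sites with gaps or ambiguities are excluded pairwise, the
standard treatment. Saturated pairs raise errors instead of returning
non-finite distances. Sequence-vs-Sanger concordance uses the
uncorrected p-distance with a strict 2% threshold. Distance functions
require caller-aligned input (all our assembled barcodes are colinear by
construction); aligning heterogeneous field data is left to the caller
because no single alignment strategy suits 1,000+ mixed-order arthropod
sequences.

## The simulator: what it emulates, and what it does not

`simulate_reads()` generates the full study design: plates of wells, one
true 658-nt barcode per specimen, FC = barcode[1..307] and
BR = barcode[226..658] (the unique geometry satisfying 658 total, 82
overlap, and the 300-400/400-500 merged-read windows once 10 nt of MIDs
and ~40 nt of primers are added), amplicons built as
`MID + primer + fragment + revcomp(primer) + revcomp(MID)` with
degenerate primer positions realized per amplicon, and 300-nt read pairs
from both amplicon ends.

Noise model and defaults, chosen once as typical of a well-behaved MiSeq
amplicon run: substitution errors at 0.1% per base, uniform over the
three alternative bases; Phred scores from a truncated normal (mean 35,
sd 3, clamped to [2, 40]); coverage 50 read pairs per fragment per
specimen. Cross-well contamination affects 5% of wells at 30% of reads;
endosymbiont ("Wolbachia-like", a packaged synthetic template >= 15%
divergent from every reference) co-amplicons affect 5% of wells at 25%
of reads; in wells carrying more than one template, each amplicon is
chimeric with probability 2%.

Chimera breakpoints are drawn from the central half of the fragment. A
crossover within a few bases of a fragment end yields a product
indistinguishable from a point-error variant of one parent (its
divergence from that parent falls below any sensible `min_div`), which
no abundance-and-crossover-based de novo detector can or should flag;
the generator therefore models the detectable class of chimeras.

Features of real data the simulator does not emulate: quality-by-cycle
decay and other structured MiSeq error profiles, indels (off by design --
assembly is ungapped), index hopping between pools, primer-binding bias,
and real taxonomic sequence structure (references are uniform-random
with a minimum pairwise divergence of 5%). Passing end-to-end tests
therefore demonstrate the correctness of the pipeline's logic and
thresholds under calibrated noise, not its performance on any particular
field dataset.

## Numerical and degenerate-input choices

* All tie-breaks are deterministic and documented: descending count then
  lexicographic sequence in dereplication and clustering; first (lowest)
  diagonal in the HSP scan; longest-first first-accept in overlap scans;
  forward-read base at equal-quality merge disagreements; FC base at
  equal-size assembly disagreements; earliest reference at best-hit ties.
* Unmerged, unassigned, incompatible and unassembled are values, not
  errors; every such read is counted in the stage report, and
  `n_in == n_out + n_dropped` holds at every stage.
* Saturated K2P distances, empty reference sets, ambiguous mapping rows
  and malformed FASTQ records raise immediate, named errors.
* Phred+33 is the only supported quality encoding; anything else is
  rejected loudly rather than guessed.
* Neighbor joining delegates to ape's Saitou-Nei implementation, which is
  deterministic for a given matrix; its internal tie order on degenerate
  (e.g. equidistant) matrices is ape's own.

## Problem sizes used in the packaged checks

The packaged tests exercise single wells up to two full 96-well plates at
coverage 50 (19,200 read pairs) with 0.1% error, 5% contaminated wells
and 2% chimeras -- the scale at which all thresholds, the chimera screen
and end-to-end parameter recovery are validated. The acceptance script
reproduces the headline geometry (658-bp assembly through an 82-bp
detected overlap) from a single error-free specimen at packaged defaults.

## Known limitations

* Gapped amplicons (real indels) fail ungapped assembly; they are logged,
  not recovered.
* The abundance basis for calling is assembled-barcode support; a
  raw-read basis would require re-mapping reads to assemblies, which the
  pipeline does not do.
* Plate-level (pool) indices are modelled as file-level separation, so
  index hopping between pools is out of scope.
* `best_hit()` is a stand-in for a curated-database search and inherits
  the reference set it is given; it performs no taxonomic rank
  resolution.
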