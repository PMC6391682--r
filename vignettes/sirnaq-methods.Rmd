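---
title: "Quantifying hairpin-derived siRNAs: methods and design notes"
author: "sirnaq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hairpin-derived siRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnaq)
```

# Scope

`sirnaq` analyses small RNA sequencing libraries from cells in which
long double-stranded RNA — typically an inverted-repeat (IR) hairpin
expressed from a transfected plasmid — is processed by Dicer into
21–23-nt siRNAs. The pipeline covers read trimming, perfect-match
placement on genome-plus-plasmid references, fractional-count
quantification, discovery and annotation of 21–23-nt read clusters,
repeat-class aggregation, per-position hairpin arm densities,
selection of reporter-antisense siRNAs, and a modulo-22
phasing-register statistic. A synthetic-data generator with exact
ground truth supports validation end to end.

# Trimming model

NEXTflex-style small RNA reads have the structure
`4N + insert + 4N + 3' adapter`. Trimming is two deterministic
rounds:

1. **Adapter removal.** The read is scanned left to right; at
   position $i$ the adapter prefix of length
   $L = \min(\text{adapter length}, \text{bases remaining})$ is
   compared by Hamming distance. A match is declared when $L \ge 19$
   with at most 1 mismatch, or $8 \le L < 19$ with 0 mismatches, and
   the read is truncated at the leftmost match. This emulates k-mer
   adapter trimmers (k = 19, minimum terminal overlap 8, Hamming
   distance 1) with a rule simple enough to verify against an
   exhaustive position scan, which the test suite does. A read
   without any match is kept unchanged: an untrimmed chimeric read
   cannot survive the perfect-match mapping step anyway, and a
   `require_adapter` switch discards such reads for users who prefer
   strictness.
2. **End removal.** 4 bases are cut from each end (the randomized
   protocol bases), and inserts shorter than 15 nt are discarded.

Quality scores are ignored throughout; the downstream exact-match
contract makes base-quality filtering redundant at these read
lengths. Mismatch tolerance applies only to full-length adapter
matches because a mismatch in a short terminal overlap is
indistinguishable from insert sequence.

# Alignment and fractional counting

The internal aligner reports *every* exact occurrence of a read on
both strands of every contig (Aho–Corasick dictionary matching via
`Biostrings::matchPDict`, grouped by read length). There is no
placement cap: a read at $n$ loci yields $n$ alignments, each
carrying $n$ and the weight $1/n$. Reads containing N never match.
Mismatched placements are deliberately out of scope — every
downstream statistic is defined over perfect matches — but externally
produced SAM/BAM alignments can be ingested with `import_sam()`,
which keeps ungapped, unclipped records with NM ≤ a configurable
limit (default 0) and recomputes $n$ over the retained placements.

The normalization denominator $D$ is the number of distinct reads
with at least one perfect-match placement on the genome *or* a
transfected plasmid, so plasmid-derived siRNAs count as mapped.
Under this policy the library totals exactly $10^6$ RPM, which the
tests assert as an invariant, and fractional weights sum exactly to
the mapped-read count. An `all-reads` denominator policy (total
records, mapped or not) is available because "library size" is
sometimes reported that way; the two differ by the unmappable
fraction only.

Coordinates are 1-based closed `GRanges` throughout, the native
Bioconductor convention; BED export converts to 0-based half-open.

# Cluster discovery

Per sample, on 21–23-nt placements:

1. weight placements by $1/n$;
2. collapse transitively overlapping placements (strand-agnostic)
   into regions spanning their union, summing weights — abutting
   intervals that share no base are *not* merged;
3. discard regions below 3 RPM;
4. join surviving clusters whose gap is ≤ 50 bp, re-deriving counts
   and RPM.

The order matters: filtering precedes joining, so two sub-threshold
regions cannot rescue each other by proximity. "Within 50 bp" is
interpreted as inter-cluster gap ≤ 50 (a 51-bp gap stays split); both
sides of the boundary are pinned by tests. Raising either the RPM
threshold or the join distance can only reduce the number of
clusters, a monotonicity property the suite checks on random data.
The caller is validated against an independent brute-force reference
(explicit pairwise-overlap graph, connected components, exhaustive
join scan) on 200 randomized instances.

Within a genotype, a region is kept only if every replicate
contributes an overlapping cluster; kept coordinates are the union of
the contributing clusters (an `intersection` coordinate mode exists
for conservative interval estimates). Across samples, overlapping
clusters merge transitively by coordinate union, and per-sample RPM
over the merged region is recomputed from that sample's reads rather
than summed from pre-merge clusters — recomputation is exact for the
merged interval, whereas sums double-count reads spanning pre-merge
boundaries.

Annotation assigns the highest-priority category among overlapping
sources: miRNA > transposable elements > mRNA (protein-coding exons)
> misc RNA > other. Overlap is ≥ 1 bp and strand-agnostic; repeat
annotations in particular carry unreliable strand information
relative to read-level sense calls. Cluster summaries are the median
of $\log_{10}$ RPM across samples with zeros floored at 0.1 RPM, so a
cluster absent from a sample appears at the axis floor rather than
dropping out of the median; a `drop` policy returns `NA` for
all-zero clusters instead.

# Hairpin analyses

A `hairpin_spec` names the plasmid contig, the hairpin interval, the
5′ arm / loop / 3′ arm segments, and which strand is antisense to the
targeted reporter. Three statistics are computed over length-filtered
(default 21–23 nt) plasmid alignments whose biological 5′ end — the
alignment start on `+`, the alignment end on `-` — lies in the
hairpin:

* **Arm density**: per-position coverage in CPM, each read
  contributing its fractional weight to every covered base, split by
  the arm containing the read's 5′ end (5′ arm plotted up, 3′ arm
  down with negative sign). Reads whose 5′ end falls in the loop
  join neither profile. Assignment by 5′ end is the one unambiguous
  rule for boundary-spanning reads.
* **Reporter-antisense selection**: the subset on the antisense
  strand — the cleavage-competent guide candidates.
* **Phasing**: scaled position = 5′ end − hairpin start + 1, register
  = ((scaled − 1) mod 22) + 1, proportions = per-register fractional
  sums over their total. The 5′-end convention on each read's own
  strand reflects how Dicer measures its 22-nt step; the period is
  configurable for other step sizes. With zero hairpin reads the
  proportions are `NA` and flagged rather than zero-filled.

Both hairpin strands pool into one register scale. Because the 3′
arm is the reverse complement of the 5′ arm, an arm-internal read
always maps twice (its mirror image on the opposite arm and strand),
with weight ½ each; phasing therefore sees both placements. The
mirror of scaled position $s$ is $T - s + 1$ where $T$ is the
stem-plus-loop length, so mirrored placements share a register
exactly when $T \equiv 1 \pmod{22}$.

# The synthetic-data generator

`simulate_reference()` + `simulate_library()` emulate the structure
such libraries actually have, with every read traceable to its
source:

* **miRNA-like loci** (default 30): unique 23-nt windows with fixed
  5′ ends and multinomial 21/22/23-nt lengths (¼, ½, ¼), log-normal
  relative abundance (meanlog = log 300, sdlog = 1). Planted loci
  keep ≥ 100 nt of clearance from each other and from repeats —
  distinct ground-truth loci closer than the 50-bp join distance
  would be indistinguishable from one cluster, making recovery
  ill-defined. Alternatively, explicit per-locus target RPMs can be
  planted; the remaining miRNA mass then goes to 20 background loci
  so each target realizes approximately its stated RPM.
* **Repeat families** (default 4 families × 4 identical copies of
  300 nt, classes SINE_B2/LINE1/ERVK/ERVL): reads drawn from copy
  interiors multimap with exactly known $n$; an optional per-copy
  mutation rate degrades multimapping deliberately.
* **The IR plasmid**: 400-nt arm, 15-nt loop, reverse-complement
  arm, 500-nt backbone flanks. Stem+loop = 815 ≡ 1 (mod 22), chosen
  so mirrored placements are phase-coherent (see above); with other
  geometries a noise-free terminal library would split between two
  registers. Hairpin reads come in `terminal` mode — 5′ ends on the
  register-1 lattice with abundance decaying by 0.5 per 22-nt step
  (qualitatively: most material from the first cleavage), plus a
  `noise_fraction` (default 0.1) of uniform starts — or
  `distributed` mode with uniform 5′ ends. Default composition is
  20% hairpin, 5% repeat, 2% unmappable, remainder miRNA, at
  100,000 reads per library.
* **Read structure**: each insert is wrapped as
  `4N + insert + 4N + adapter` with constant qualities; replicates
  re-draw reads from the same truth with the seed offset by the
  replicate index. Identical configurations give byte-identical
  outputs.

For terminal mode with uniform contamination fraction $f$, the
expected register-1 proportion has the closed form
$(1-f) + f/22$ (up to a $O(1/T)$ excess because $T \equiv 1$ pmod 22
gives register 1 one extra position); the acceptance tests check
$f \in \{0, 0.25, 0.5\}$ at 10,000 hairpin reads within ±0.02, and a
flat profile (spread < 0.02) for distributed mode at the same depth.

**What the generator does not emulate**: sequencing errors and
quality variation, ligation and PCR bias, isomiR 5′ heterogeneity,
partially decayed repeat families, dsRNA editing, and genome-scale
reference complexity. Passing tests therefore demonstrate algorithmic
correctness on structurally faithful data, not robustness to every
artefact of real libraries — on real data, perfect-match mapping
absorbs sequencing errors by dropping the affected reads, which
lowers the denominator but not the algorithms' validity.

# Statistical choices

Replicate comparison of repeat-class RPM uses a two-sided Welch
t-test per class with a 0.05 flag. Degenerate inputs are defined
rather than erroneous: identical constant values in both groups give
$p = 1$; constant but different values give $p = 0$; fewer than two
replicates per group is an error. No multiple-testing correction is
applied across the handful of repeat classes; users comparing many
classes should adjust downstream (`p.adjust`).

# Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to make the
statistical checks sharp while staying desk-scale: 10,000-read
libraries for trimming closure and conservation, 20,000 reads (10,000
hairpin reads) for phasing closed forms, 200 randomized instances for
each brute-force comparison (cluster caller and aligner, the latter
on contigs up to 50 kb), and a 10⁶-read library for
plant-and-recover, where the 3-RPM threshold equals 3 reads.
Sub-threshold loci are planted at 0.1 RPM — an order of magnitude
below the discard threshold — so that their non-recovery reflects the
threshold rather than sampling luck, and the replicate-intersection
check plants its consistently-present loci at 100 RPM, well above
Poisson dropout at 200,000-read depth. All randomness flows from
explicit seeds; `run_pipeline()` re-runs are byte-identical.

# Known limitations

* The aligner is exact-match by design; analyses requiring mismatch
  tolerance (e.g. editing) need external alignments via SAM import.
* Colorspace (SOLiD) trimming is not implemented; such data enter as
  externally aligned SAM restricted to perfect matches.
* Cluster discovery is strand-agnostic; per-strand cluster calling
  would require a different collapse rule.
* A placement overlapping repeats of several classes is assigned to
  the largest-overlap repeat (ties by annotation order); nested
  repeat annotations can therefore shift class totals slightly.
* `arm_density` is per-position coverage; a 5′-end count profile
  differs for uneven read lengths.
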