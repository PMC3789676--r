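---
title: "Methods: simulating and analysing two-enzyme GBS in RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing two-enzyme GBS in RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsim)
```

## The experiment being emulated

Genotyping-by-sequencing (GBS) reduces a large genome to a reproducible
set of restriction fragments.  In the two-enzyme design, genomic DNA is
co-digested with a rare cutter (PstI, recognition `CTGCAG`, cutting after
base 5 on the top strand) and a frequent cutter (MspI, `CCGG`, cutting
after base 1).  A barcoded forward adapter ligates to the PstI overhang
and a common Y-adapter to the MspI overhang; because the Y-adapter's
unpaired tail only acquires a primer binding site when copied from the
opposite (PstI) end, fragments flanked by MspI on both sides never
amplify.  Every sequenced read therefore starts with a sample barcode
followed by the invariant PstI cut-site remnant `TGCAG`, then genomic
sequence.

The analysis target is a biparental recombinant inbred line (RIL)
population: two inbred parents crossed, an F1 selfed, and lines advanced
by single seed descent (SSD).  For F8-derived lines (7 generations of
selfing after the F1) the expected residual heterozygosity per locus is
$0.5^7 \approx 0.78\%$, and every locus segregates at an expected 50:50
parental allele ratio.

`gbsim` implements both halves: a synthetic-data generator that emulates
the experiment end to end, and the analysis chain (demultiplexing,
placement, calling, filtering, concordance, map construction, order
comparison) that a practitioner would run on real data.

## The synthetic-data generator

`sim_config()` collects all tunables.  The defaults are the study
conditions the package is built around, not free dials:

* **Genome** — i.i.d.-uniform chromosome sequences, tiled by contigs of
  `contig_length_bp` carrying cM anchors obtained by scaling physical
  position linearly to `map_length_cM` per chromosome.  Real genomes have
  non-uniform recombination and repeat structure; neither is modelled, so
  placement ambiguity is far rarer here than in barley-sized genomes.
* **Variants** — planted at `snp_density` per bp.  Parent A equals the
  reference; parent B carries the alternate allele everywhere.  Variants
  are never placed inside a recognition site, and alternate alleles that
  would create a new site are rejected, so digestion is
  genotype-independent and truth coverage per locus is well defined.
  (Real PstI/MspI site polymorphism between cultivars is thereby
  excluded by design; it is noted as a known unmodelled feature.)
* **Population** — each RIL descends from an independent F2; meioses draw
  a Poisson(`map_length_cM`/100) crossover count placed uniformly in cM
  (no interference).  Kosambi is used only downstream for estimation,
  which mirrors how such data are analysed in practice.
* **Library** — complete digestion, PstI–MspI fragments within
  `amplifiable_size_range` (default 50–500 bp, a conventional span for
  PCR- and sequencer-friendly GBS inserts; the protocol itself states no
  range).  Reads start at the PstI end on a haplotype drawn uniformly
  from the individual's two, which is exactly the mechanism that makes a
  heterozygous locus covered by one read look homozygous.
* **Platforms** — `illumina`: fixed 100 bp reads, per-base substitutions
  at `sub_error_rate`; inserts shorter than the read run into the
  reverse adapter, exercising adapter trimming.  `ion`: lengths from a
  truncated normal (mean 120, sd 40, minimum 30 bp), plus
  single-unit insertions/deletions per homopolymer run at
  `hp_indel_rate` per unit, matching the platform's characteristic error
  mode.  Quality strings are flat Phred+33 encodings of the substitution
  rate: the caller consumes depth and allele counts, not per-base
  qualities, so a quality model would be decorative.
* **Pooling** — per-sample read totals are lognormal
  (`depth_meanlog`, `depth_sdlog`); large `depth_sdlog` reproduces the
  order-of-magnitude spread between best- and worst-covered samples seen
  in unevenly pooled libraries.

What passing tests on these data do **not** show: robustness to repeat
families, mapping bias, PCR duplicates, chimeric fragments, polyclonal
artefacts, or base-quality miscalibration — none of which are generated.

## Demultiplexing and trimming

Reads are assigned by an exact match of the barcode (9 bp, all equal
length) followed by the expected prefix (optional `CGAT` spacer plus the
`TGCAG` remnant); no mismatch rescue is attempted, matching the strict
filter the analysis emulates.  Whether the sequenced read contains the
spacer is ambiguous in the published adapter layout, so the simulator
and demultiplexer share one configuration and default to no spacer.
Adapter trimming scans every offset for a semi-global match of the
adapter prefix (minimum overlap 3, mismatch fraction at most 0.1 — the
conventional defaults of read-trimming tools; the leftmost valid match
wins) and discards reads shorter than 30 bases afterwards.

## Placement and genotype calling

`build_index()` hashes every forward k-mer (default k = 21) of the
contigs; k-mers at multiple positions are ambiguous and never seed.
`place_reads()` seeds each read (both strands) with up to four k-mer
windows spaced k apart — so a single variant or sequencing error cannot
block every window — extends ungapped, and accepts a placement only if
the mismatch fraction is at most 0.05 and exactly one strand validates.
This deliberately drops reads straddling contig ends and Ion reads whose
homopolymer indels break ungapped extension; the caller sees slightly
thinner coverage rather than gapped alignments, which keeps the engine
desk-scale and exactly testable.

Calling is a transparent binomial-likelihood rule per sample at each
nominated site (any position with a non-reference observation): with
allele counts $(n_r, n_a)$ and symmetric error rate $e$,

$$L(\mathrm{hom}_r) = (1-e)^{n_r} e^{n_a},\quad
  L(\mathrm{het}) = 0.5^{\,n_r+n_a},\quad
  L(\mathrm{hom}_a) = e^{n_r} (1-e)^{n_a},$$

with a uniform prior by default (a RIL-informed prior that down-weights
the het class is available) and genotype quality
$-10\log_{10}(1-\mathrm{posterior_{max}})$ capped at 99.  Sites where a
third allele reaches a pooled count of two are dropped as multi-allelic;
singleton third observations are treated as errors and excluded from
depth.  The tag-based path truncates reads to 64 bp tags, collapses them
with per-sample counts, places unique tags, and declares a SNP wherever
two co-placed tags differ at exactly one base, converting the tag offset
to contig coordinates by adding the placement offset (the degenerate
no-indel case of coordinate lifting); genotypes then follow the same
binomial rule on tag counts.

## Filtering

Two criteria sets mirror standard RIL practice.  Calling-stage: mask
calls below depth 1/GQ 3 (homozygous) or depth 3/GQ 5 (heterozygous),
then keep sites with at most 90% missing calls, minor allele frequency
at least 5%, and strictly less than 10% heterozygous calls ("less than"
is implemented literally at the boundary).  Comparison-stage: at most
50% missing and MAF at least 30% ("at least" at that boundary).  MAF
counts a heterozygous call as half an allele each — the standard
allele-frequency definition, which the filter specification leaves open.

## Concordance across datasets

Tables are merged by reference coordinate; sites whose ref/alt pair
conflicts between datasets are excluded from genotype comparison (and
counted) rather than re-oriented, since no strand harmonisation rule is
given.  Discordance is computed over shared sites and samples with both
calls present; het-vs-hom disagreements count as discordant, the
conservative choice given that shallow coverage of residual heterozygous
regions is an acknowledged driver of discordance.  Under independent
per-dataset error rates $e_1, e_2$ on homozygous truth the expected
discordance is $\approx e_1 + e_2$, which is the quantity the acceptance
check measures at $e_1 = e_2 = 0.5\%$.

## Map construction

Markers are A/B/H-coded against the parents, pre-filtered (at most 20%
missing; one marker per contig, keeping the least-missing marker with
ties to the lowest position; at most 10% missing-plus-heterozygous),
heterozygous calls are set to missing, and the matrix is treated as
doubled haploids — the recommended treatment for advanced RILs, which
means two-point estimates are used directly rather than corrected by
$R = 2r/(1+2r)$, and cM distances come out roughly doubled.  That
inflation cancels in every order-based comparison the package makes.

Grouping is single linkage at a two-point chi-square p-value of at most
$10^{-5}$, with one addition: the pair must also be in coupling
($\hat r < 0.5$).  The chi-square test is two-sided, and for
parental-coded RIL data a significant *excess* of disagreements cannot
arise from linkage — without the coupling requirement, chance repulsion
associations between unlinked markers occasionally weld chromosomes
together.  Even so, with hundreds of markers the expected number of
sub-$10^{-5}$ chance coupling associations is of order one, and a single
such edge merges two groups; the order-comparison statistics are
computed per group against the group's majority chromosome precisely so
they remain meaningful in that event.

Ordering within a group collapses identical marker vectors into bins,
builds the minimum spanning tree of the complete recombination-fraction
graph, seeds the order with the tree's weighted diameter path, inserts
the remaining bins where they add the least adjacent recombination, and
refines by 2-opt segment reversals minimising the summed adjacent
fraction.  This is a stated stand-in for the published MST-based
ordering objective, judged by order recovery rather than bit-identity;
no correction of singleton double-recombinants is attempted.  Bins share
a cM position (cumulative Kosambi of adjacent fractions,
$d = 25\ln\frac{1+2r}{1-2r}$, with $\hat r$ capped at 0.4999), members
ordered by marker id, and each group's orientation is fixed
deterministically (lexicographically smaller terminal marker first).
With ~94 lines, adjacent bins separated by a single recombination event
carry too little information to be ordered reliably by any
adjacent-fraction objective; exact recovery up to reversal is expected
(and tested) at larger population sizes, while at 94 lines the order is
near-true (rank correlation above 0.999 in error-free data).

Isolated sets of at most `no_map_size` (2) markers are discarded after
grouping; on well-connected simulated data this step is inert.

## Comparing genetic and reference order

Each linkage group is assigned its majority reference chromosome.  Per
group, the absolute Spearman correlation (average ranks for
cosegregating bins; absolute value because group orientation is
arbitrary) is computed between de novo cM and reference cM over
majority-chromosome markers; groups under 3 anchored markers are
skipped.  Displacement first aligns orientation by the sign of the rank
correlation, then fits a tricube-weighted local *linear* regression of
reference on de novo position (span 0.75, the canonical default; groups
too small for a local fit fall back to a global line) and reports
absolute residuals, counting markers beyond 5 cM.  Residual-based
displacement was chosen over raw cM differences because the two maps are
on different scales (DH treatment roughly doubles distances).

## Problem sizes and numerical choices

The packaged checks run the generator at desk scale, chosen so that each
stage is exercised with comfortable statistical resolution: populations
of 94–300 lines, genomes of 0.12–7 Mb, ~0.7–2 k markers, and read sets
of tens of thousands.  The map-recovery check uses 94 lines and ~1,800
markers on 7 chromosomes of 150 cM with 10% missing data and 0.5%
genotype error, mirroring the design of the experiment the package
emulates.  Determinism is enforced throughout: one master seed with
fixed per-stage derivations, so identical configurations produce
byte-identical FASTQ output.  Ties are broken deterministically
everywhere (leftmost adapter match, first-index genotype argmax at exact
posterior ties, marker-id order within bins).

## Known limitations

* Ungapped placement understates Ion coverage rather than modelling
  indel alignment.
* The caller is biallelic and ignores base quality by construction.
* Single-linkage grouping at a fixed p-value cutoff is not robust to
  chance coupling associations at large marker counts (discussed above).
* The generator's uniform-base genome makes read placement easier than
  in repeat-rich crop genomes; absolute SNP counts from the simulator
  are not comparable to real-data yields.
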