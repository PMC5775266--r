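---
title: "In-silico discovery of bacterial cis-antisense RNAs: methods and design notes"
author: "asrnascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico discovery of bacterial cis-antisense RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrnascreen)
```

## The problem

*cis*-antisense RNAs (asRNAs) are transcribed from the DNA strand opposite
a gene and are therefore perfectly complementary to its mRNA over the
overlap. In *Streptomyces coelicolor* — a GC-rich, developmentally complex
antibiotic producer — the double-strand-specific endoribonuclease
RNase III (encoded by *rnc*) binds hundreds of mRNAs, and mRNAs whose
levels rise when *rnc* is deleted are natural candidates for antisense
control: if an mRNA–asRNA duplex is an RNase III substrate, removing the
enzyme should stabilize one or both partners. This package implements the
desk half of that candidate hunt: strand-aware classification of cataloged
small RNA (sRNA) genes against candidate target mRNAs, an evidence funnel
combining *rnc*-mutant differential expression with RNase III
co-immunoprecipitation (BARD) enrichment, design of the gene-specific
oligos used for 5′ RACE and northern probing, virtual RT-PCR for operon
hypotheses, a trans-target similarity scan, and 5S-normalized northern
quantification with a per-transcript call of the response to RNase III
loss.

## Orientation classification

Every gene–sRNA pair receives exactly one of six categories. Two windows
around the gene drive the decision:

* the **5′ window**, from `five_prime_upstream` nt upstream of the start
  codon to `five_prime_downstream` nt into the CDS (defaults −15..+3).
  The defaults cover a typical ribosome binding site plus the start codon —
  the same region the RACE primers and probes are designed over, because an
  asRNA pairing there can block translation initiation.
* the **3′ window**, from `three_prime_inside` nt inside the gene terminus
  to `three_prime_downstream` nt past it (defaults 50/50), where convergent
  overlapping transcripts ("cutoRNAs") act on the messenger's 3′ end.

"Neighboring" is not defined by distance in the source screens, so it is a
parameter: overlap, or a gap of at most `adjacency_window` nt
(default 100). The precedence order is: unknown-strand neighbor →
`AMBIGUOUS`; antisense hitting the 5′ window → `CIS_AS_5PRIME`; antisense
hitting the 3′ window, or a non-overlapping antisense neighbor on the 3′
side → `CUTORNA`; any other antisense neighbor → `CIS_AS_OTHER`; same
strand with overlap → `SENSE_OVERLAP`; everything else → `NONE`.

Three choices here were genuinely open and are worth recording:

* **5′ precedence.** An sRNA spanning a whole gene touches both windows;
  it is called `CIS_AS_5PRIME` because 5′ evidence is what the wet-lab
  follow-up (RACE from the RBS/start region) can confirm.
* **A total partition.** Published category lists cover only the
  configurations that occur in their tables. For the partition to be total
  we added `CIS_AS_OTHER` for antisense neighbors that touch neither
  window (mid-CDS overlaps, or 5′-side gaps beyond the 5′ window), and we
  extended `CUTORNA` to non-overlapping 3′-side neighbors within the
  adjacency window, which is how non-overlapping convergent transcripts
  appear in practice.
* **Same-strand non-overlapping neighbors are `NONE`.** A sense gene
  downstream of another gene is ordinary genome packing, not an antisense
  relationship, so only a true sense *overlap* is reported.

The classifier is verified against an independent brute-force oracle that
re-derives every rule from explicit position sets (`seq`/`intersect`) on
toy chromosomes, over 10,000 random geometries per run, and is checked for
strand-flip symmetry: reverse-complementing a whole locus (mirroring
coordinates, flipping strands) never changes a category.

```{r}
g <- GenomicRanges::GRanges("chr", IRanges::IRanges(1001, 2000), "+")
S4Vectors::mcols(g)$gene_id <- "geneA"
s <- GenomicRanges::GRanges("chr", IRanges::IRanges(950, 1060), "-")
S4Vectors::mcols(s)$srna_id <- "sA"
classify_pair(g, s)
```

## The candidate funnel

`filter_selected()` reads "increased by more than two-fold" strictly: a
fold change of exactly 2.00 does not pass (there is a real borderline case
at 2.00 in the packaged panel, and the strict reading keeps it out, which
matches the published candidate list). Folds are signed; a strong
*decrease* in the *rnc* mutant never counts as "increased", though such a
gene can still enter through BARD enrichment under the default
`fold_or_bard` union. All three thresholds (`fold_threshold`,
`bard_min_ratio`, strictness) are parameters.

Funnel counts are of *distinct genes*: a gene neighbored by several sRNAs
contributes several report rows but one count, which is why the packaged
screen lists 49 gene–sRNA pairs over 45 distinct target genes.

```{r}
summarize_detections(asrna_fixture("sco_detection_results.tsv"))
count_distinct_targets(asrna_fixture("sco_gene_srna_pairs.tsv"))
```

## Oligo design, virtual PCR, trans scanning

`design_race_oligo()` returns an oligo on the mRNA-sense strand whose
genomic footprint contains the full 5′ window, so the same oligo primes
reverse transcription of the antisense transcript and probes it on a
northern. Melting temperature uses the Wallace rule
(2 °C per A/T, 4 °C per G/C): it is deterministic, dependency-free and
adequate at these lengths; the Tm function is pluggable for anyone who
wants nearest-neighbor thermodynamics. Among valid candidates the design
optimizes |Tm − midpoint of the Tm band|, breaking ties toward shorter
oligos and then leftmost genomic position, so results are reproducible to
the base. Failure modes are distinct on purpose: a 5′ window running off
the contig is an *error* (the input is unusable), while constraints that
no candidate can meet return `NULL` (a valid "no solution").

`predict_amplicon()` uses exact primer matching only — the use case is
primers that are literal genome substrings — and reports the shortest
product when several opposing site pairs exist, since the shortest product
dominates a PCR. Both template orientations are searched, so which primer
is called "forward" is irrelevant; this is tested as a strand-symmetry
property.

`find_trans_targets()` scans fixed-length windows on both strands for
ungapped identity ≥ `min_identity` (default 0.9). No indel model: at the
scale of "nearly identical elsewhere in the genome" that motivates the
scan, gapped alignment adds parameters without changing the answer.
Overlapping hits are merged keeping the best identity.

## Northern quantification

Band signals are divided by the same lane's 5S rRNA signal
(`normalize_measurements()`), which makes the values invariant to loading
differences — tested as exact scale invariance. The response of an asRNA
to RNase III loss is summarized by per-time-point ratios
`(rnc + floor) / (wt + floor)` and their geometric mean *G* across shared
time points:

* *G* ≥ `ratio_threshold` → `increased_in_rnc`
* *G* ≤ 1/`ratio_threshold` → `decreased_in_rnc`
* all values in both strains below `detection_floor` → `not_detected`
* otherwise → `unchanged`

No published threshold exists for "increased in the *rnc* strain", so the
default `ratio_threshold = 2` mirrors the two-fold convention used for the
expression filter; the pseudo-floor (`detection_floor = 0.01` on the
normalized scale) keeps ratios finite for blank lanes. The geometric mean
was chosen over the maximum because it is robust to a single-lane artifact
and exactly symmetric under swapping the strain labels (swap maps
*G* → 1/*G*), a property the tests exercise directly. Whether a published
"increased" call referred to one time point or the whole course is not
always decidable; the per-time-point ratios are therefore reported
alongside the summary so either reading can be checked.

## Synthetic data: what it emulates and what it does not

`generate_locus_set()` plants, per category, a gene (random strand) and an
sRNA at a geometry that satisfies the category's defining rule with
generous margins (tens of nt away from every window boundary), on a
GC-rich (72%, *Streptomyces*-like) random chromosome, with loci separated
by several adjacency windows so they cannot cross-talk. Gene length
defaults to 400 nt and sRNA length to 100 nt — short for real genes but
ample for every window to be distinct, which is what the geometry tests
need. `generate_expression_tables()` plants folds at ≥ 3 (above the
2-fold threshold) for selected genes and |fold| ≤ 1.5 for the rest;
`generate_northern_table()` plants rnc/wt ratios of 4× (increased), 0.25×
(decreased) or 1× with multiplicative lognormal noise at a 5% coefficient
of variation over the standard 24/48/72 h course. All generators take a
seed, restore the caller's RNG state, and are byte-deterministic.

Passing recovery tests on these fixtures shows the *geometry and
threshold logic* is correct; it says nothing about the hard parts of real
data — overlapping gene models, condition-dependent transcript boundaries,
catalogs with imprecise sRNA ends, blots with saturated or smeared bands —
none of which the generator attempts to simulate.

## Problem sizes and numerical notes

The verification suite uses 10,000 random toy geometries (300-nt
chromosomes) for the oracle comparison, 18 planted loci (3 per category)
for orientation recovery, and 12 features for northern recovery — sizes at
which every check is exhaustive or exactly determined, and the whole suite
runs in well under a minute. Coordinates are 1-based inclusive throughout
(GFF convention); BED input/output converts at the boundary, and the
round trip is tested for idempotence against an independent reader. Gap
is 0 for touching intervals; overlap > 0 forces gap = 0. Ties in
best-partner selection resolve by smaller gap, larger overlap, then
lexicographic gene id, making batch output order-stable.

## Known limitations

* The two genome-scale checks (the 635-nt operon-spanning RT-PCR product
  between the published primer pair, and the 2,220-nt SCO5737 CDS) need
  the *S. coelicolor* AL645882 chromosome and annotation, which are not
  shipped; point `options(asrnascreen.genome=)` /
  `options(asrnascreen.annotation=)` (or the corresponding environment
  variables) at local copies to run them.
* Orientation is pure interval geometry: no expression-level inference,
  no RNA duplex thermodynamics, no secondary-structure screening of
  designed oligos.
* RACE-measured transcript lengths are sequencing outcomes and are not
  predicted by any function here.
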