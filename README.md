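# asrnascreen

Strand-aware discovery and screening of bacterial *cis*-antisense RNAs
(asRNAs), built around the candidate hunt used in *Streptomyces
coelicolor*: mRNAs that rise in an RNase III deletion (*rnc*) mutant, or
that co-precipitate with a cleavage-dead RNase III (the BARD set), are
screened for cataloged small RNA (sRNA) genes in antisense or adjacent
orientation, and the resulting candidates are carried through primer
design, virtual RT-PCR and northern quantification.

It is for microbial transcriptomics people who have a gene annotation
(GFF3/BED6), an sRNA catalog (BED6, unknown strand allowed), a genome
FASTA, and differential-expression / binding-evidence tables, and want a
reproducible desk pipeline from those inputs to a ranked candidate table
and the oligos to test it.

## What it computes

* **Orientation classification.** Each gene–sRNA pair gets one of six
  categories from strand and interval geometry: `CIS_AS_5PRIME`
  (antisense over the 5′ window, i.e. the ribosome binding site and start
  codon, default −15..+3 around the start), `CUTORNA` (convergent
  antisense at the gene's 3′ end, window ±50 nt around the terminus),
  `CIS_AS_OTHER`, `AMBIGUOUS` (unknown sRNA strand, neighboring),
  `SENSE_OVERLAP`, or `NONE` (beyond the 100-nt adjacency window). The
  familiar arrow notation (`-> <= <-`) is rendered for reports.
* **The candidate funnel.** genes → genes "increased more than two-fold"
  in the *rnc* mutant (strict, signed) or BARD-enriched → those with an
  antisense/ambiguous sRNA neighbor → those also RNase III-bound, counting
  distinct genes at every stage.
* **RACE/probe design.** A gene-specific oligo on the mRNA-sense strand
  covering the RBS and start codon, Wallace-rule Tm
  (2·(A+T) + 4·(G+C) °C), optimized to the center of the Tm band.
* **Virtual RT-PCR** (`predict_amplicon`): exact primer sites, both
  orientations, shortest opposing-site product — for operon tests such as
  "do these two ORFs share a transcript spanning the intergenic asRNA?"
* **Trans-target scan** (`find_trans_targets`): genome windows ≥ 90%
  identical to an asRNA on either strand.
* **Northern quantification**: band / same-lane 5S signal, per-time-point
  rnc/wt ratios, and a geometric-mean call of each transcript's response
  to RNase III loss (`increased_in_rnc` / `decreased_in_rnc` /
  `unchanged` / `not_detected`).
* **Synthetic fixtures**: seeded generators planting loci of every
  category, expression tables and band-intensity tables with
  machine-readable ground truth.

Two curated S. coelicolor tables ship under `inst/extdata/`: the 49-pair
screen of rnc-up-regulated genes vs sRNA neighbors, and the 30-gene
RACE/northern detection panel.

## Worked example

```r
library(asrnascreen)

## a seeded toy genome with one planted locus per category
ls <- generate_locus_set(seed = 7, n_per_category = 1)
tabs <- generate_expression_tables(ls$truth, seed = 7)
# (write tabs$de / tabs$bard to TSV, or use your own tables)
ev <- read_expression_tables(de_path, bard_path)
run_screen(ls$genes, ls$srnas, ev)
```

```
Antisense candidate funnel (distinct genes):
  input genes:              6
  evidence-selected:        4
  with antisense neighbor:  4
  also RNase III-bound:     2
  report rows (pairs):      4
```

The funnel narrows from 6 annotated genes to the 4 with expression or
binding evidence, all 4 of which have an antisense/ambiguous neighbor,
and 2 of which are also in the binding set; `$rows` lists the pairs with
category and arrows:

```
  gene_id srna_id    source      category arrows comment
1 SYNG001 syns001 synthetic CIS_AS_5PRIME  <- =>
2 SYNG002 syns002 synthetic       CUTORNA  -> <= in BARD
3 SYNG003 syns003 synthetic  CIS_AS_OTHER  -> <= in BARD
4 SYNG004 syns004 synthetic     AMBIGUOUS   <- *
```

The packaged detection panel summarizes the published RACE/northern
outcomes — 30 genes tested, 22 with a 5′-detected antisense transcript,
18 northern-positive, and a 17/17 hit rate (16 with 3′ ends) in the
RNase III-bound experimental set:

```r
summarize_detections(asrna_fixture("sco_detection_results.tsv"))
```

```
Detection summary: 30 genes tested; 22 with a 5' RACE-detected antisense
transcript; 21 with a 3' end; 18 northern-positive.
          set n_tested n_5prime_detected n_3prime_detected n_northern_positive
 experimental       17                17                16                  13
      control       13                 5                 5                   5
```

See `vignettes/asrna-discovery.Rmd` for the model, parameter rationale
and design notes.

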