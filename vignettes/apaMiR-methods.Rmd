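---
title: "apaMiR: methods and design"
author: "apaMiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apaMiR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaMiR)
```

## The scientific question

Alternative polyadenylation (APA) lets a transcript end at a proximal
cleavage site instead of the distal one, producing a shortened 3'UTR.  The
classical consequence is *loss* of miRNA binding sites located towards the
distal end.  apaMiR implements the complementary analysis: whether conserved
miRNA seed-match sites are *positionally enriched immediately 5' of APA
sites*, so that 3'UTR shortening moves them close to the new transcript end
and potentiates, rather than removes, miRNA repression — preferentially in
differentiation-associated genes and for sites of proliferation-associated
miRNA clusters such as miR-17-92.

The package covers the full chain: cleavage-site (CS) calling from 3'-end
sequencing read positions, internal-priming artifact filtering, CS-to-3'UTR
assignment and APA calling, perfect 7-mer seed-match scanning, positional
enrichment statistics with three randomization null models, site-score
(P_CT-like / context-like) window comparisons, per-base conservation
profiles, codon-usage based gene-set expansion, and a synthetic-data
generator that emits every input format with ground truth.

## Cleavage-site calling

Reads from all samples are pooled.  *Read runs* are maximal sets of occupied
positions per chromosome and strand in which consecutive occupied positions
are less than `gapMax = 10` nt apart.  Candidate CSs are the local maxima of
each run's per-position counts.  Three deterministic conventions are needed
where "local maxima" alone under-determines the output:

* a position qualifies when its count is `>=` both neighbours; tied adjacent
  candidates (plateaus) collapse to the 5'-most position (strand-aware);
* spacing conflicts (two candidates closer than `minSpacing = 50` nt) are
  resolved greedily by descending support, ties again 5'-most first, so the
  kept sites are pairwise `>= 50` nt apart;
* the support filter (`minSupport = 10` reads at the run maximum) is applied
  *after* spacing resolution.

Internal priming of the oligo-dT primer on genomically A-rich stretches
produces false CS calls.  A site is flagged when the 50-nt genomic window
centered on it — realized as `[pos - 25, pos + 25)` and taken in transcript
sense, i.e. reverse-complemented for minus-strand sites — contains any
10-mer with at least 8 A's and all remaining bases G.  Flagged sites are
retained in the output but marked, and excluded from APA assignment by
default.  Whether "spacing of at least 50 nt" means `>= 50` (used here) or
`> 50` is configurable; the distinction moves no conclusions.

## APA assignment

A CS is assigned to a gene if it falls inside the gene's 3'UTR intervals or
within 20 nt 3' of the annotated transcript-sense UTR end (slack sites are
clamped to the last UTR base for distance computations).  A gene is
APA-positive iff at least two CSs are assigned; the analysis anchor is the
5'-most assigned site in UTR coordinates.  When a gene has several
transcript accessions, its longest UTR is used; a CS falling in two
overlapping genes' UTRs is assigned to both and flagged.  For analyses
anchored at the full-length UTR end, the distal assigned CS defines that end
(the annotated end is the fallback).  Per-sample APA calls (a gene counted
APA-positive within a sample iff two of its sites have `>= 10` reads in that
sample) are available alongside pooled calls.

## Seed-match sites

A binding site is a perfect 7-mer: the DNA reverse complement of miRNA bases
2–8.  Every exact occurrence in the sense-oriented UTR sequence is reported,
including overlapping occurrences and multiple families at one position; `N`
never matches.  Conservation status and per-site scores are *input
channels*, joined by (gene, position, family); the coordinate system of each
table is validated by re-extracting the 7-mer at every listed position
(mismatch above 5% aborts, as it indicates an annotation/coordinate
mismatch).  A site's position is its 5' base; distances to anchors are
computed from it.

## Positional statistics

All profiles bin the distance `utr_start - anchor` into 100-nt bins over
±1000 nt; a site exactly at the anchor belongs to the first downstream bin.
Genes are pre-filtered to have at least the full flank of UTR sequence on
both sides of the anchor, so every gene covers every bin.  300-nt analysis
windows align with bin boundaries by construction.

**Randomized-APA null.**  Per iteration, every participating gene (UTR
longer than twice the flank) receives a pseudo-APA position drawn uniformly
from `[flank, length - flank)`, and conserved sites are re-binned.  The
per-bin one-sided p-value asks whether the observed count at that distance
is as high or higher at the true APA sites than at random ones.

**Two-set partition test.**  For two disjoint gene sets (e.g.
pro-proliferation vs pro-differentiation), the per-bin statistic is the
difference in conserved sites *per contributing gene* (per-gene density
makes unequal set sizes comparable).  The null re-partitions the union into
sets of the original sizes, 10,000 times by default.

**Cluster-versus-all test.**  The target set is the profiled genes with at
least one conserved site of the given families (e.g. the four miR-17-92
seed families).  The statistic compares the mean per-gene *site share* —
the fraction of a gene's in-window conserved sites in each bin — between the
target set and the comparison universe; the null redraws same-size gene
subsets.  Two design choices keep this test exact: the universe is
restricted to genes with at least one in-window conserved site (matching the
target's conditioning on carrying a site), and the share normalization
cancels per-gene site-abundance differences, isolating positional structure.
Without both, genes selected for carrying sites are systematically
site-richer than random subsets and the test is anti-conservative.  When the
cluster comprises all families the statistic is identically zero.

**P-value estimator.**  All three tests report the +1-corrected one-sided
estimator `p = (1 + #{null >= observed}) / (1 + n_iter)`, which is never
zero and is the field-standard conservative choice; with a discrete
statistic, ties make it strictly conservative.  A tie-randomized variant
(`ties = "randomized"`, the observed value ranked uniformly within its tie
group) is exactly uniform under the null and is used when *calibrating* the
ensembles; it never exceeds the conservative value.  Raw per-bin p-values
are reported without multiple-testing correction; correction across bins is
left to the caller.

**Score and relative-position comparisons.**  Sites within 300 nt 5' versus
3' of the APA (genes with `>= 500` nt on each side) are compared by a
pooled-variance two-sided Student t-test on the requested score (Welch
available via a flag); sidedness is reported with the direction, not
assumed.  The APA-versus-non-APA comparison maps each conserved site to its
relative position `utr_start / utr_length` in the full-length 3'UTR and
applies the same t-test, plus decile profiles for plotting.

## Conservation profiles

Profiles average track scores at strand-aware genomic bases at each
transcript-sense offset from the anchors; positions without track coverage
are *missing* and excluded from the mean (never imputed as zero), with the
per-offset contributor count reported.  Site-anchored profiles use a 30-base
window realized as offsets `[-12, +19)`, so the 7-mer occupies offsets
0–6; the exact split is a convention and configurable.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
ground-truth bookkeeping, and emits every input through the package's own
writers.  The defaults are the study conditions; they were chosen once, as
follows, and are not tuned per analysis:

* **Cohort**: 1,000 genes; log-normal UTR lengths (median 1,500 nt, sdlog
  0.7, truncated to 300–10,000 — matching the long right tail of human
  3'UTRs); 60% of genes get a proximal CS uniform in 0.2–0.8 of the UTR, in
  addition to the distal CS at the UTR end.
* **Reads**: negative-binomial support per CS (mean 60, truncated 20–200);
  half of a site's reads fall exactly at the CS and half jitter by rounded
  N(0, 2) nt, emulating the major-site-plus-fluctuation structure of 3'-end
  read runs; two samples.
* **Sites**: 100 seed families (the scale of real conserved-family
  catalogues), 70% conserved, 4 designated "cluster" families; planted
  density 4 sites/kb of which 70% conserved.  The enriched class
  ("prodiff", 25% of genes) receives 3x conserved-site density in the 300
  nt 5' of its proximal CS, with 60% of those excess sites drawn from
  cluster families.  Non-APA genes receive 2x conserved density in their
  last 300 nt (the distal-end enrichment seen in genes not using APA).
  Class fractions are unequal (25% / 35%) as real expanded
  differentiation/proliferation sets are; unequal arms also avoid a
  degenerate tie lattice in the partition statistic.
* **Artifacts**: 10% of genes get an A-rich 10-mer written into the genome
  with a read cluster on it (internal-priming decoys, support ~18); 30% get
  a low-support (3–8 reads) noise cluster.
* **Scores and conservation**: P_CT-like scores Beta(6,4) for conserved
  sites in the 5'-of-APA window vs Beta(4,6) elsewhere; context-like scores
  N(-0.35, 0.08) vs N(-0.15, 0.08); conservation track 0.9 on conserved
  site bases over a 0.2 base level, emitted only over UTR spans so missing
  positions exercise the NA path.
* **Codon usage**: a non-uniform baseline (base-composition product with a
  fixed per-codon preference pattern — in real transcriptomes all genes
  share most of their codon-usage structure), two class centers 0.08 apart
  (L2), per-gene Dirichlet concentration 4,000, CDS lengths 400–900 codons.
  Under these settings competing-set expansion at correlation 0.75 recovers
  the class labels with >= 95% accuracy.
* **Genome**: one contig per 50 genes, 200-nt gaps, 40% GC; single-interval
  UTR models (spliced multi-exon models are exercised by hand-built
  fixtures in the tests, not by the generator).

An `annotation` mode generates the same truth (lengths, classes, CS
positions, sites, scores, sets) without sequences or reads; it is the fast
path for the statistical calibration and power studies, which do not
exercise sequence-level steps (those are validated separately on full-mode
cohorts).

What the generator does *not* emulate: real hg19 coordinates, sequencing
error, alignment ambiguity, expression-dependent read depth, isoform
mixtures within a gene, correlated site placement between paralogs, and
biologically structured conservation.  Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the planted
model, not performance on real libraries.

## Problem sizes in the test-suite studies

Calibration of the three randomization tests is assessed on 50 no-signal
cohorts (enrichment factors 1) of 2,000 genes with 1,000 iterations per
test, pooling per-bin p-values across cohorts into a Kolmogorov–Smirnov
test against uniformity.  Power is assessed on 50 enriched-preset cohorts
of 2,000 genes: 2,000 genes yield ~60 flank-passing genes per class arm,
which an a priori normal approximation puts at per-bin power ~0.99 for the
3x planted effect (z ~ 4), so the all-three-window-bins criterion is met
reliably; at 1,000 genes the arms (~30 genes) sit near z ~ 3 and joint
power is materially lower.  Oracle-equivalence checks run 1,000 random
instances; the internal-priming scan is cross-checked on 10,000 random
windows.

## Numerical and degenerate-input conventions

* UTR-relative coordinates are 0-based (position 0 = 5'-most base);
  genomic coordinates follow the 1-based GRanges convention internally,
  with BED's 0-based half-open convention handled at the rtracklayer IO
  boundary.
* Identical score multisets in both windows return t = 0, p = 1 without
  calling the t-test (which rejects constant data).
* Empty bins, empty gene sets, missing scores, truncated internal-priming
  windows at contig ends, and zero-gene cohorts follow the documented
  error/fallback behaviour and are covered by tests.
* All stochastic outputs are bit-reproducible given a seed; the generator's
  file bundle is byte-identical on regeneration.

## Known limitations

* The CS caller assumes cleavage positions are stable enough that a 10-nt
  gap rule separates sites; closely spaced genuine sites (< 50 nt) are
  merged into the better-supported one by design.
* Conservation labels and site scores are consumed from input tables; the
  package does not re-derive them from alignments.
* The cluster-versus-all statistic deliberately tests positional structure
  only; a cluster whose targets simply have *more* sites everywhere (with
  the same spatial distribution) is, by design, not flagged.
* Quantitative APA usage indices (proximal/distal ratios) are out of scope;
  APA calls are binary per gene (and per sample when sample counts are
  available).
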