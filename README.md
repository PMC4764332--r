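# apaMiR

Positional enrichment of conserved miRNA seed-match sites around
alternative polyadenylation (APA) sites, from 3'-end sequencing to
permutation statistics.

## The problem

Alternative polyadenylation shortens a transcript's 3'UTR by cleaving at a
proximal poly(A) site.  The textbook consequence is the *loss* of miRNA
binding sites that lie distal to the new end.  apaMiR implements the
complementary genome-scale analysis: testing whether conserved miRNA
seed-match sites cluster *immediately 5' of APA sites*, where 3'UTR
shortening relocates them next to the new transcript end and can
*potentiate* repression — and whether this signal is concentrated in
differentiation-associated genes and in sites of proliferation-associated
miRNA clusters (miR-17-92).  It is aimed at computational biologists
working with 3'-end sequencing (3'seq / PAS-seq-style) data and
TargetScan-style site annotations.

The pipeline:

1. **Cleavage-site calling** — pooled 3'-end read positions are clustered
   into *read runs* (consecutive occupied positions < 10 nt apart); run
   local maxima become candidate cleavage sites (CS); candidates closer
   than 50 nt resolve to the better-supported one; sites need >= 10 reads
   at the maximum.  Sites whose 50-nt genomic window contains a 10-mer of
   >= 8 A's (remainder G) are flagged as oligo-dT internal-priming
   artifacts.
2. **APA assignment** — a CS belongs to a gene if it falls in its 3'UTR
   (plus 20 nt of tail slack); genes with >= 2 assigned sites are
   APA-positive, anchored at the 5'-most site.
3. **Seed-match scanning** — perfect 7-mers (reverse complement of miRNA
   bases 2–8) in the UTR sequences; conservation flags and per-site
   P_CT-like / context-like scores join from external tables.
4. **Statistics** — binned site profiles around the APA anchor; a
   randomized-APA null (random anchor per gene, 10,000 iterations); a
   two-gene-set partition permutation test; a cluster-versus-all
   permutation test; 5'-vs-3' score-window Student t-tests; an
   APA-vs-non-APA relative-position comparison; mean conservation profiles
   around sites and APA anchors.
5. **Synthetic data** — a generator emitting every input format (genome
   FASTA, UTR BED12, reads BED6, seed/site/score TSVs, bedGraph
   conservation, CDS FASTA, gene sets) with planted ground truth, used by
   the test suite for oracle, calibration and power studies.

## Worked example

```r
library(apaMiR)

## a synthetic cohort at the default study conditions (1,000 genes)
sim   <- simulateApaData(simConfig(seed = 1))
paths <- writeSimBundle(sim, "demo_bundle")

ends  <- readReadEnds(paths[["reads"]])
utrs  <- readUtrModels(paths[["utrs"]], paths[["genome"]])
sites <- callCleavageSites(ends, paths[["genome"]])
calls <- assignApa(sites, utrs)
truthReport(sim, sites, calls)[c("cs_recall", "cs_precision")]
#> $cs_recall
#> [1] 0.9943785
#> $cs_precision
#> [1] 1

seeds <- readSeedTable(paths[["seeds"]])
ss    <- scanSeedSites(utrs, seeds)
ss    <- labelConserved(ss, readSiteTable(paths[["conserved"]]), utrs, seeds)

flanked <- filterFlank(calls, 1000)
nullRes <- randomizedApaNull(flanked, ss, nIter = 10000, seed = 102)
nullRes
#> PermTestResult ('randomized_apa'): 10000 iterations, seed 102
#>   20 bin(s); 2 with one-sided p < 0.05
round(pValues(nullRes)[8:10], 4)   # the three bins spanning [-300, 0)
#> [-300,-200) [-200,-100)    [-100,0)
#>      0.0296      0.2721      0.0081
```

The bins immediately 5' of the APA anchor carry the planted excess of
conserved sites (the generator plants 3x density in the 300 nt 5' of the
proximal site of differentiation-like genes); bins further away stay at
null levels.  `scoreWindowCompare()` on the same cohort shows higher
P_CT-like scores (t = 15.0, pooled Student t) and stronger (more negative)
context-like scores 5' of the APA site, and
`relativePositionCompare()` shows conserved sites of APA genes sitting less
distally than those of non-APA genes — the three signatures the statistics
layer is built to detect.

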