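# mitopause

Single-base calling of mitochondrial RNA polymerase (mtRNAP) pause sites
from nascent-transcription (PRO-seq) 3′-end coverage on the circular
mitochondrial genome, G-quadruplex (G4) propensity scoring of the
underlying sequence, and the statistics that connect the two.

## Who this is for

PRO-seq marks the active site of an engaged RNA polymerase by the 3′ end of
each nascent RNA read. On the 16.6 kb circular mitochondrial genome this
gives deep single-base occupancy profiles per strand, from which pause
sites — bases where the polymerase accumulates far above its local
neighbourhood — can be called. Guanine-rich sequence upstream of such sites
can fold into G-quadruplexes (four-stranded structures built from stacked
guanine quartets), a candidate cause of the pausing. This package provides
the full computational chain: coverage extraction, pause calling,
G4 scoring, and association statistics, plus a synthetic-data generator
with planted ground truth so every stage is testable without any download.

## The statistics at the core

**Pause calling.** For each base *i* of a per-strand, RPM-normalized
3′-end coverage track *c*, compute a Z-score against the centered circular
window of width *W* = 201 nt:

    Z_i = (c_i − mean_W(i)) / sd_W(i)

with population standard deviation and the center base included (sd = 0 ⇒
Z = 0). Bases with Z ≥ 3 and coverage ≥ 1 RPM are peaks; bases that are
peaks in ≥ 2 samples are consensus bases, and runs of consecutive consensus
bases merge into pause sites with the summit at the maximal summed Z. An
isolated spike on a zero background scores Z = √200 ≈ 14.14 regardless of
its height.

**G4 propensity.** Two strand-aware scores: (i) a run-based per-base score
(+min(run, 4) inside guanine runs, −min(run, 4) inside cytosine runs, 0
elsewhere) averaged in a 25-nt circular window; (ii) enumeration of
four-tract motifs G_x N_ℓ1 G_x N_ℓ2 G_x N_ℓ3 G_x with x ≥ 2 and loops of
1–7 nt, scored by `20(x−2) + Σ(8−ℓ_i) − (max ℓ − min ℓ)` (more tetrads,
shorter loops, uniform loops) and reduced to the best non-overlapping set.

**Association.** Metaprofiles of either score in transcription orientation
around pause summits (offset −k = k nt upstream on the nascent RNA);
Wilcoxon rank-sum comparison of upstream guanine counts at pause versus
random control summits; χ² test of the strand split of pause counts;
Kruskal–Wallis plus pairwise rank tests of polymerase abundance across
upstream-G bins; wrap-aware interval overlap with variant positions; and
same-strand gene annotation with 5′/body/3′ classification.

## Worked example

```r
library(mitopause)
res <- runPipeline(defaultConfig(outDir = "demo_run", seed = 1))
res$recovery
#> $nCalled [1] 35   $nTruth [1] 35   $matched [1] 35
#> $precision [1] 1   $recall [1] 1

res$asymmetry$chisq
#> [1] 0.02857143
mp <- res$metaHunter
mp$offset[which.max(mp$mean)]
#> [1] -35
```

The default configuration simulates a 16,569-nt circular genome with
strand-asymmetric guanine content (13% vs 31%), 40 planted G4 motifs,
pauses 20–40 nt downstream of a motif's 3′ end (probability 0.8), and
3 replicate negative-binomial coverage tracks with a 30-fold mean elevation
at pause bases. The run above recovers all 35 planted pauses (some motifs
are unpaired by chance) at ±1 nt with no false calls, and the windowed G4
score around the called summits peaks 35 nt upstream — inside the 20–40 nt
upstream band where the motifs were planted. `demo_run/` contains the site
BED, per-sample peak tables, threshold sweep, metaprofiles, test results
and a Markdown report.

For real data, point the YAML config at a genome FASTA and per-sample
stranded bedGraph pairs of 3′-end counts (see
`inst/scripts/run_pipeline.R` for a shell entry point); SAM/BAM input with
optional UMI deduplication is supported through `readAlignments()`,
`dedupUMI()` and `extractThreePrimeEnds()`.

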