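---
title: "Pause calling and G-quadruplex association on a circular genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pause calling and G-quadruplex association on a circular genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopause)
```

## The problem and the model

Nascent-transcription sequencing (PRO-seq) reports the position of each
engaged RNA polymerase through the 3′ end of its nascent RNA. On the
circular mitochondrial genome, two polycistronic transcripts — one
guanine-rich, one guanine-poor — are transcribed in opposite directions,
and the single-subunit mitochondrial polymerase accumulates at discrete
bases. This package models a pause site as a base whose 3′-end count is a
local outlier: for per-strand coverage $c$ and an odd window $W$ (default
201 nt, circular wrap),

$$Z_i = \frac{c_i - \mu_W(i)}{\sigma_W(i)},$$

with $\mu_W$, $\sigma_W$ the mean and *population* standard deviation of
the $W$ values centered at $i$, the center base included. Including the
center is the simpler reading of a "centered window" and changes $Z$
negligibly at $W = 201$; when $\sigma_W = 0$ the center equals its window
mean and $Z$ is defined as 0. Bases with $Z \ge 3$ and coverage
$\ge 1$ RPM are per-sample peaks; bases that are peaks in at least 2
samples are consensus bases; maximal runs of consecutive consensus bases on
one strand merge into a site. The summit is the base of maximal summed $Z$,
ties broken by the first base in transcription direction. Since site width
is a convention (single-base sites are common), both merged-site and
consensus-base counts are reported, and the threshold sweep ($Z$ = 3–6)
shows how counts shrink with stricter thresholds.

Two normalization modes exist because the right denominator depends on the
experiment: `rpm_total` (reads per million mapped) for steady-state
comparisons, and `rpm_nuclear` (per million *nuclear* reads) when the
treatment itself changes mitochondrial transcription, so mitochondrial
totals are not a stable yardstick. The denominator is supplied by the
caller — alignment and genome-wide read counting happen upstream of this
package.

## Coordinates on a circle

All coordinates are 0-based, half-open; an interval with start > end wraps
the origin, and width is computed mod $L$. Windows, runs of consensus
bases, rolling statistics, motif searches and interval overlaps are all
wrap-aware, so nothing is lost at the origin and every operation is
rotation-equivariant (verified by property tests). "Upstream" always means
5′ on the nascent RNA: minus-strand windows are reverse-complemented and
minus-strand metaprofile offsets flipped. BED output is native 0-based
half-open; a wrapped site is split into two BED lines sharing a name.

The canonical real instance is the human mitochondrial genome. The tests
use the copy shipped with the seqinr package (NC_001807.4, 16,571 nt, the
hg19-era chrM): its reference strand is 13% guanine and its complement 31%,
the strand asymmetry that motivates the strand-aware design. The rCRS
(NC_012920.1) is 2 nt shorter; the package takes whatever FASTA it is
given and does not attempt to reconcile reference builds.

## G-quadruplex scoring

Two complementary scores, both strand-aware:

* **Run-based windowed score** (G4Hunter-style, defaults: window 25 nt):
  each base in a guanine run of length $n$ scores $+\min(n, 4)$, in a
  cytosine run $-\min(n, 4)$ (G4 propensity of the complementary strand),
  otherwise 0; N scores 0 and breaks runs. The windowed mean is a centered
  circular moving average. The minus-strand track is computed from the
  reverse complement and mapped back to reference coordinates; by G/C
  antisymmetry it equals the negated plus-strand track, which the tests
  assert rather than assume.
* **Four-tract motif enumeration** (QGRS-style): all substrings
  $G_x N_{\ell_1} G_x N_{\ell_2} G_x N_{\ell_3} G_x$ with $x \ge 2$, each
  loop in 1–7 nt (loops may contain G; zero-length loops excluded by
  default but configurable) and total width ≤ 45 nt. The original G-score
  is published as criteria, not a closed form; this package uses
  $20(x-2) + \sum_i (8-\ell_i) - (\max_i \ell_i - \min_i \ell_i)$, which
  rewards more tetrads, shorter loops and uniform loops. The coefficient 1
  on the uniformity term keeps the score monotone: lengthening any single
  loop never raises it (with coefficient 2, raising a unique shortest loop
  would). Only the relative ordering of scores is used downstream.
  Overlapping candidates are reduced greedily (score, then leftmost); the
  full candidate list is available via `keepCandidates = TRUE` and is
  checked against an independent regex-based oracle in the tests.

For metaprofiles, qgrs mode assigns each base the maximum G-score over
covering motifs (an aggregation convention recorded in output metadata);
hunter mode uses the windowed mean directly.

## Association statistics

* **Metaprofile**: mean ± SEM of a per-strand signal at offsets −100..+100
  around summits, transcription-oriented. On a circle every site
  contributes every offset, so $n$ is constant across offsets.
* **Upstream-G enrichment**: two-sided Wilcoxon rank-sum on guanine counts
  in the 50 nt upstream of summits (summit excluded), pause versus random
  controls, pooled and per strand. Controls are uniform over non-pause
  positions with the query's strand proportions; a coverage-matched mode
  (controls restricted to bases ≥ 1 RPM) is provided because the choice of
  control matching is not canonical.
* **Strand asymmetry**: 1-df χ² goodness of fit of the plus/minus site
  split; (60, 40) against 0.5 gives exactly χ² = 4.
* **Grouping by upstream G**: quartile bins of the upstream-G count
  (fixed edges available), pairwise rank tests of summit coverage with
  Benjamini–Hochberg adjustment (unadjusted values also emitted, since
  reporting conventions differ) and a global Kruskal–Wallis test.
* **Variant overlap**: wrap-aware half-open interval intersection; both
  percent conventions (variants/sites and sites-with-variant/sites) are
  reported because the two differ once a site contains several variants.
* **Annotation**: same-strand gene containment of the summit; in-gene
  sites are classed 5′ end / body / 3′ end by relative position with a 10%
  end window — a configurable convention, since no standard cut-off exists.

### Calibration and its limits

Under the null (both site sets drawn from one G-count distribution) the
rank tests reject at 5% within Monte-Carlo error; the acceptance tests
verify 4–6% over 1,000 seeded replicates. One subtlety: on a
composition-asymmetric genome the *pooled* two-group comparison with
strand-balanced groups is a stratified design — each group holds exactly
half plus-strand (G-poor upstream) and half minus-strand (G-rich upstream)
values — so the rank-sum statistic varies less than the permutation null
assumes and pooled p-values are conservative. Calibration is therefore run
on a composition-symmetric genome; on real, asymmetric data the per-strand
tests are the better-calibrated readout (and are what the analysis
reports). Discreteness of G counts makes all these tests mildly
conservative, never anti-conservative.

## The synthetic-data generator

`simParams()` defaults define the study conditions: $L = 16{,}569$;
reference-strand base probabilities (A, C, G, T) = (0.31, 0.31, 0.13,
0.25), emulating the 13%/31% guanine asymmetry; 20 motifs per strand
(tracts of 2 or 3, loops uniform 1–7 nt from A/C/T); pause probability 0.8
per motif; pause offset uniform 20–40 nt downstream of the motif's 3′-most
base in transcription direction (so the motif lies 20–40 nt upstream of the
pause on the nascent RNA); 5 uncoupled noise pauses; negative-binomial
background (mean 5, size 10) with a 30-fold mean elevation at pause bases —
multiplicative rather than additive, keeping the dispersion structure
uniform; 3 replicates sharing pause positions with independent count draws;
and a library size of $2 \times 10^7$, placing the mitochondrial contig at
a realistic fraction of a deep run so that the 1-RPM gate (= 20 counts) is
meaningful: background (~5 counts) fails it, pause bases (~150 counts) pass.

Motifs are planted with ≥ 100 nt margins, and same-sense guanines are
scrubbed from a loop-width buffer around each motif so no candidate can
chain a planted tract to a background run — each planted motif is then the
unique top-scoring candidate over its footprint and is recovered exactly.

What the generator does *not* emulate: real gene order and polycistronic
structure, position-dependent background (steps at promoters), read-level
artefacts (UMI logic is tested with hand-built SAM fixtures instead), or
sequence-dependent count biases. Passing the recovery test therefore shows
the caller's statistic and consensus logic work at realistic depths and
effect sizes — not that real mitochondrial PRO-seq is this clean.

One geometric consequence worth knowing: the per-base G4 metaprofile
around called summits rises over offsets −40..−20 because motif *3′ ends*
are 20–40 nt upstream, but motif *bodies* (11–33 nt wide) extend further
upstream, so the profile's maximum sits near the −40 edge of the band and,
with finitely many sites and 25-nt smoothing, can fall a base or two
outside it on some seeds. The upstream band's mean always dominates the
mirrored downstream band by a wide margin.

## Numerical choices

* Rolling statistics center the track on its global mean before
  accumulating (cancellation guard), use `stats::filter(..., circular =
  TRUE)` for the moving sums, and agree with a naive per-base loop to well
  below $10^{-9}$ relative error; an isolated spike on zero background
  gives $Z = \sqrt{200}$ at $W = 201$ independent of height, which the
  tests assert against the closed form.
* Window widths must be odd so "centered" is unambiguous.
* Degenerate inputs: all-N sequences have undefined composition (error);
  all-tied rank tests return p = 1 with a warning; empty site lists are an
  error for metaprofiles and a no-op for overlap counting; normalizing an
  already-normalized track is an error rather than a silent double scale.
* Problem sizes in the test suite (genomes of 2–16.6 kb, 1,000-replicate
  calibrations, 50-track oracle comparisons) were chosen so the whole suite
  runs in about two minutes on one CPU while keeping Monte-Carlo error
  well inside the asserted bands.

## Known limitations

Single-contig only (multi-record FASTA uses the first record with a
warning); no GFF parsing — annotation is BED6+biotype; no pause-duration
modeling or condition comparisons beyond running the caller per condition;
no thermodynamic G4 folding prediction or two-tetrad/bulged motif classes.
External signal tracks (e.g. a G4 ChIP-seq bedGraph) can be profiled around
sites via `readBedGraphPair()` + `metaprofile()`, but peak calling for such
data is out of scope.
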