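---
title: "Methods: models, parameters, and design choices in cistromer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in cistromer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cistromer)
```

cistromer implements the downstream analysis chain used in
transcription-factor ChIP-seq studies of monomeric nuclear receptors:
model-based peak calling, summit-based genomic annotation, motif scanning
with a genome-wide z-score baseline, cistrome co-occupancy testing, and
running-sum enrichment of peak-associated genes in ranked expression
lists. This vignette documents the statistical models, every tunable
parameter, and the design decisions made where the underlying procedures
are conventionally under-specified.

All coordinates are 0-based half-open (BED convention). An interval's
length is always `end - start`; adjacent intervals share no base.

## The synthetic study world

Real nuclear-receptor cistrome datasets are large and often unavailable;
every stage here is therefore validated against a synthetic world with
known ground truth, built by `simulate_world()` from a `sim_config()`.

The generator emulates the statistical structure such an experiment
produces:

* **Genome** — i.i.d. bases on a 1 Mb two-chromosome genome
  (`chrom_lengths = c(chr1 = 600000, chr2 = 400000)`) at GC fraction
  0.42, the mammalian bulk value.
* **Gene models** — 60 non-overlapping transcripts of 2–8 kb with 1–4
  exons, a 5'UTR, CDS, and 3'UTR, strands assigned at random. This is
  denser than a mammalian genome (about 10 genes per Mb) so that
  promoter-planting and gene-assignment statistics have usable counts at
  desk scale; consequences of the density are noted below.
* **Planted motif sites** — 200 copies of the 9-bp nuclear-receptor
  half-site consensus `CCAAGGTCA` are written into the genome (reverse
  complement for minus-strand placements), overwriting rather than
  inserting so gene coordinates stay valid. Each site is
  promoter-proximal with probability 0.241 — placed inside a 2 kb window
  upstream of a random TSS — and otherwise placed uniformly outside all
  promoter windows, so the realized promoter fraction is a binomial draw
  around 0.241.
* **Tags** — for each site, `Poisson(30)` forward-strand tags have their
  5' ends centred at `center - d/2` and an independent `Poisson(30)`
  reverse-strand set at `center + d/2`, with `d = 152` bp. Jitter is a
  discretized normal with SD `d/4`, which produces the unimodal
  per-strand pileups the peak model assumes; no fragment-length
  distribution is imposed beyond this. Reads are 39 bp. Uniform
  background tags at 0.001 tags/bp are added to both the treatment and
  an IgG-like control; the control carries background only, since the
  background structure of a real IgG library is not characterized here.
* **Expression** — per-gene fold changes are standard normal; genes with
  a planted site within 2 kb of their TSS ("bound genes") are shifted up
  by `expression_effect = 2`.

Every generator draws from a stage-specific RNG stream derived from one
seed (`derive_seed(seed, stage)`), so a single integer reproduces the
whole world byte-for-byte, and stages can be regenerated in isolation.

What the generator does **not** emulate: sequencing error, mappability
and repeat structure, GC bias, copy-number variation, chromatin-state
correlation between sites, and realistic gene density. Tests passing on
this world demonstrate the correctness and calibration of the
algorithms, not their robustness to those artefacts of real libraries.

## Peak calling

`estimate_fragment_shift()` recovers the fragment shift `d`: sliding
windows of twice the 300 bp bandwidth are scanned in steps of
`bandwidth/3`; windows whose tag count reaches `mfold` (default 32)
times the expected background count become model regions. Within each,
`d` is estimated as the mode of minus-strand 5' positions minus the mode
of plus-strand 5' positions (modes from a 21-bp moving-average smoothed
position histogram), and the final `d` is the median over regions.

The background rate for the `mfold` filter is estimated as the mean
count over the lower 80% of windows rather than the global mean. In a
desk-scale world the planted signal occupies a non-negligible fraction
of the genome, so a global mean is signal-inflated and `mfold = 32`
times it would exceed every real site's count; the trimmed estimate
tracks the background component that the enrichment multiple is meant to
be measured against. On signal-sparse data the two estimates coincide.

`call_peaks()` shifts every tag `d/2` toward its 3' end and scores each
window by the Poisson upper tail of the treatment count with
`lambda = max(depth-scaled control count, genome-wide treatment rate ×
window width)`; the flooring guards against windows where a thin control
would make the test anti-conservative. Overlapping significant windows
merge and the merged region is re-scored over its full extent. The
summit is the leftmost position of maximum coverage after extending each
tag to `d` bp from its 5' end — ties break to the leftmost base. The FDR
is the sample-swap estimate: peaks are called with treatment and control
exchanged, and `fdr(p)` is the ratio of swap peaks to treatment peaks at
least as significant as `p`. Defaults follow stringent practice:
`p <= 1e-10` and `fdr <= 1%`.

This caller is a deliberate simplification of full model-based callers:
there is no multi-scale local lambda, no duplicate-tag removal, and no
broad-peak mode. The window step of `bandwidth/3` is a resolution/cost
compromise; results are insensitive to it once the step is well below
the window width.

## Annotation

`classify_peaks()` assigns one feature class per peak from its **summit**
— the best estimate of the protein–DNA contact — rather than from the
whole interval, whose extent reflects fragment size more than biology.
Classes are promoter (2 kb 5' of the TSS), 5'UTR, exon, intron, 3'UTR,
downstream (2 kb 3' of the transcript end), else intergenic. UTRs are
exon intersections with the region between transcript and CDS bounds,
strand-swapped for minus-strand genes; "exon" means the CDS-overlapping
remainder. When a summit hits features of several genes, precedence is
promoter > 5'UTR > exon > intron > 3'UTR > downstream, making the
categories exclusive and their fractions sum to one.

`summit_to_tss_distances()` reports `summit - TSS` with the sign flipped
for minus-strand genes, so negative always means upstream. The TSS of a
minus-strand gene is `tx_end - 1`, the last transcribed base in
half-open coordinates. Nearest is by absolute distance; ties go to the
lower-coordinate gene.

`random_background_peaks()` supplies the null for both annotation and
co-occupancy: sets that preserve the observed peak-length multiset, with
chromosomes chosen proportional to length and starts uniform over valid
placements. Placements may overlap each other and real peaks — the null
is fully unconstrained by design.

## Motif discovery and scanning

Discovery is an exhaustive, deterministic k-mer screen
(`find_enriched_kmer()`, default `k = 9`): every k-mer in the peak
sequences is counted in canonical form (the lexicographically smaller of
the k-mer and its reverse complement) and scored by observed frequency
over its expected frequency. Expected frequencies come from a 0-order
(base-composition) model of the background sequences: at useful `k`, raw
background counts of any single k-mer are near zero and dividing by them
would let Poisson noise pick the winner. The recommended background is a
per-sequence nucleotide shuffle of the peaks (`shuffle_sequences()`),
which preserves composition exactly. Probabilistic motif refinement (EM,
E-values) is intentionally out of scope; the screen recovers a planted
half-site exactly and is fully oracle-checkable. Scanning at other `k`
recovers secondary motifs (e.g. GC-box-like signals) but is not a
pipeline default.

`build_pwm()` turns the aligned occurrences into per-position letter
probabilities with a pseudocount (default 0.5) per letter and position.
Scores are `sum(log2(p[i, base]/0.25))` — a uniform scoring background;
the subsequent standardization absorbs this choice.

`genome_baseline()` computes the mean and SD of that score over *every*
window of the genome, both strands (for symmetry with scanning),
excluding windows that touch an N or overlap an exclusion set (default:
CDS-overlapping exon intervals; a repeat mask can be supplied where one
exists). A window's z-score is `(score - mean)/sd` and its one-sided p
the standard-normal upper tail. The operative hit threshold is
`z >= 4.29`; note that the normal upper tail at 4.29 is about `9e-6`,
and that is the p-value reported. Within a peak, overlapping same-strand
hits are resolved greedily to the higher z (ties to the leftmost), so
per-peak motif counts never double-count one genomic element.

`summit_site_distances()` scores the distance from each peak's best hit
to its summit as 0 when the summit falls inside the site and the
distance to the nearer site edge otherwise, and compares against one
uniformly placed site of the same length per peak.

## Co-occupancy

`intersect_peaksets()` counts an A peak as co-occupied when its
interval, extended by `slop_bp` (default 0), intersects a B interval by
at least 1 bp. "Close to" has no standard definition; direct
intersection with configurable slop is the most conservative reading,
and both directions (A-in-B and B-in-A) plus the raw pair count are
reported because the fraction and the pair count answer different
questions. `overlap_significance()` draws `n_resamples` size-matched
random placements of A and reports the add-one empirical p-value
`(1 + #{resamples >= observed}) / (n_resamples + 1)`, which can never be
zero and is uniformly distributed under the null. Resampling preserves
lengths but not chromosome of origin. Conditional co-occupancy within an
annotation class is obtained by filtering A on `feature_class` first.

## Ranked-list enrichment

`ks_running_enrichment()` walks the expression table in rank order
(descending fold change, or descending absolute fold change), stepping
up `1/n_hits` at hit-set genes and down `1/(n_total - n_hits)`
otherwise. The enrichment score `es` is the deviation of maximum
absolute value with its sign retained (first occurrence on ties). The
classic unweighted running sum is used — no fold-change weighting —
because the statistic is then an exact two-sample Kolmogorov–Smirnov
deviation with a clean permutation null.

Significance is by permutation of hit positions, one-sided in the
direction of the observed `es`: exhaustively over all
`choose(n_total, n_hits)` placements when that is at most 5000 (exact,
no add-one), otherwise Monte Carlo with the add-one rule. The one-sided
convention is what makes the exhaustive 4-gene example come out at
exactly 1/6 — a two-sided count would also include the perfectly
*depleted* placement. A two-sample asymptotic KS p-value (`ks.test` on
hit versus non-hit ranks) is reported alongside as an independent
approximation.

`peaks_to_genes()` builds the hit set: a gene qualifies when its
transcript extended by 10 kb touches a peak (the window rule), or in
nearest-gene mode when it is the closest gene within the window. In the
dense synthetic world the 10 kb window can saturate — every gene is near
some peak, leaving the statistic undefined — in which case the pipeline
falls back to the TSS-proximal gene set (genes whose promoter or 5'UTR
holds a peak summit). On genomes of realistic density the window rule
behaves as intended.

`hypergeometric_overlap()` performs the companion gene-list overlap
test; the universe size is a required argument and never inferred,
because the choice of universe dominates the p-value.

## Numerical and degenerate-input conventions

* Poisson tail probabilities are computed in log space, so scores like
  `-log10(p)` remain finite and exact for counts far into the tail.
* A PWM whose baseline score SD is zero (e.g. a uniform matrix) raises a
  degenerate-baseline error rather than returning infinite z-scores.
* Empty treatment collections, hit sets that are empty or exhaust the
  ranked list, and resample counts below 19 are rejected with typed
  errors.
* All greedy tie-breaks (summit position, overlapping hits) resolve to
  the leftmost candidate so results are order-independent.
* `fdr` estimates are capped at 1; peaks with no swap competitor get 0.

## Problem sizes used in the test suite

The shipped tests run the full chain on the default 1 Mb / 200-site
world (one fixed seed), plus: 100-case Poisson oracle checks, a
hand-derived 5-gene annotation table, exhaustive motif-scan enumeration
on 100 random peaks up to 2 kb, 100 null replicates with 99 resamples
for co-occupancy calibration, 200 null replicates for enrichment
calibration, and 40 background draws for the summit-distance
comparison. These sizes give the calibration assertions binomial
standard errors of 2-3 percentage points, which the 3-SD acceptance
bands reflect.

A property of the z statistic worth knowing when interpreting per-peak
hit fractions: when the PWM is built from near-identical occurrences,
the baseline score distribution on an i.i.d. genome places a window
matching the consensus at 8 of 9 positions at roughly z = 4.4,
marginally above the 4.29 operating point, independent of the
pseudocount (both the mismatch penalty and the baseline SD scale
together). Exact matches sit near z = 5.3 and dominate calls, but
single-mismatch chance windows accumulate with scanned width — about
0.1 expected false hits per kb of peak per strand in this world. The
fraction of site-free peaks showing a hit therefore depends directly on
how wide the scanned intervals are; specificity statements in the test
suite use motif-core-width intervals (twice the fragment shift) for
that reason.

## Known limitations

* The peak caller's single-scale local lambda understates local biases
  that multi-scale models absorb; on real data with strong chromatin
  artefacts it will admit more false positives than a full caller.
* The 0-order discovery background cannot separate motifs from strong
  compositional skew (e.g. CpG islands); the z-score scan, standardized
  against the real genome, is the corrective downstream filter.
* Randomized placement nulls ignore mappability, GC and chromatin
  structure; empirical p-values are exact only against the uniform
  null they sample.
* The synthetic world's gene density (60 genes/Mb) inflates
  gene-assignment saturation relative to real genomes, as discussed
  above.
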