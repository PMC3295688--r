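# cistromer

Downstream analysis of transcription-factor ChIP-seq cistromes in R,
built for the kind of study where a monomeric nuclear receptor (one that
binds a 9-bp half-site such as 5'-CCAAGGTCA-3') is profiled in tissue
chromatin against an IgG control and then related to a second
transcription factor's binding sites and to expression data.

The package covers the full chain after read alignment:

1. **Peak calling** — a simplified model-based caller: the fragment
   shift *d* is estimated from the separation of forward- and
   reverse-strand tag modes in enriched windows (`mfold` filter,
   2×bandwidth windows); tags are shifted *d*/2 toward their 3' ends and
   windows scored by the Poisson upper tail
   *P*(*X* ≥ *k* | λ), with λ the depth-scaled control count floored at
   the genome-wide rate; FDR by sample swap.
2. **Annotation** — each peak classified from its summit into
   promoter / 5'UTR / exon / intron / 3'UTR / downstream / intergenic
   (2 kb flanks, promoter-first precedence), signed summit-to-TSS
   distances, and size-matched random peak sets as the null.
3. **Motif analysis** — deterministic k-mer discovery (canonical over
   reverse complement, observed/expected ratio against a shuffled
   background), a letter-probability PWM, and scanning standardized by
   the genome-wide score baseline: *z* = (*s* − μ)/σ with μ, σ computed
   over every genomic window, hits at *z* ≥ 4.29.
4. **Co-occupancy** — overlap of two peak sets with an empirical
   p-value from random placements that preserve the peak-length
   multiset (add-one rule).
5. **Ranked-list enrichment** — the classic running-sum (KS) statistic
   walking a fold-change-ranked expression table (+1/*n*<sub>hit</sub>
   on hits, −1/*n*<sub>miss</sub> otherwise), with exhaustive or
   Monte-Carlo permutation p-values, plus a hypergeometric gene-list
   overlap test.
6. **Synthetic data** — a fully deterministic generator
   (`simulate_world()`) that plants half-sites, emits bimodal
   strand-shifted tags (*d* = 152 bp, 39-bp reads), gene models and an
   expression table with known bound genes, so every stage is testable
   against ground truth.

Everything takes and returns tibbles (genomes are
`Biostrings::DNAStringSet`), composes with dplyr, and exposes
broom-style `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

```r
library(cistromer)

world <- simulate_world(sim_config(seed = 42))
model <- estimate_fragment_shift(world$treatment, world$genome)
model
#> Peak model: fragment shift d = 145 bp from 178 model regions

peaks <- call_peaks(world$treatment, world$control, model,
                    peak_calling_config(), world$genome)
nrow(peaks)
#> [1] 146

# was the planted signal recovered?
glance(intersect_peaksets(world$truth$sites, peaks))[
  , c("fraction_a", "fraction_b")]
#> # A tibble: 1 × 2
#>   fraction_a fraction_b
#>        <dbl>      <dbl>
#> 1      0.925          1
```

92.5% of the 200 planted half-sites fall inside a called peak and every
called peak contains a planted site; the estimated shift (145 bp) is
within jitter of the simulated 152 bp. Continuing through the motif and
enrichment stages:

```r
chars <- as.character(world$genome)
seqs <- unname(substring(chars[peaks$chrom], peaks$start + 1, peaks$end))
kmer <- find_enriched_kmer(seqs, k = 9,
                           background_sequences = shuffle_sequences(seqs))
kmer$consensus
#> [1] "CCAAGGTCA"

pwm <- build_pwm(kmer$occurrences)
baseline <- genome_baseline(pwm, world$genome,
                            coding_intervals(world$genes))
scan <- scan_peaks(peaks, world$genome, pwm, baseline, scan_config())
scan$fraction_with_hit
#> [1] 1

ks <- ks_running_enrichment(world$expression, world$truth$bound_genes,
                            n_permutations = 999, seed = 1)
ks
#> Running-sum enrichment: 48 hits in 60 genes, ES = 0.667 at rank 32
#>   permutation p = 0.001 (Monte Carlo, 999 placements); asymptotic KS p = 0.0003936
```

The discovery step returns the planted half-site exactly; every peak
carries a site with *z* ≥ 4.29; and the genes bound near planted sites
concentrate at the top of the simulated expression ranking (ES > 0,
permutation p at the add-one floor of 1/1000).

One call runs all stages and writes BED/bedGraph/TSV/JSON outputs plus a
`report.json`:

```r
run <- run_pipeline(pipeline_config(seed = 42, outdir = "run42"))
```

A thin command-line front end with `simulate`, `callpeaks`, `annotate`,
`motif`, `cooccupy`, `ksenrich` and `run-all` subcommands is installed
at `inst/cli/cistromer.R`.

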