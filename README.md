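# bindscape

Some transcription factors bind DNA not as monomers or dimers but as
higher-order oligomers, and losing that ability can reshape where they
bind genome-wide. `bindscape` implements the comparative ChIP-seq
analysis that quantifies such a change: it normalizes coverage tracks
for two genotypes (a factor with intact oligomerization and an
oligomerization-dead point mutant) against a non-transgenic control,
computes a per-region **coverage fold reduction (CFR)**, characterizes
the binding-site landscape of the bound regions with a position weight
matrix (PWM) and a data-driven affinity threshold, and asks how the
fold reduction relates to site affinity, site density, site spacing,
and chromatin accessibility (DNase I hypersensitivity).

It is aimed at regulatory genomicists comparing genome-wide occupancy
between protein variants, and it ships a synthetic-data generator that
plants all of this structure with known ground truth, so the entire
pipeline is testable end to end without any external data.

## The statistics at the core

**Two-step normalization.** Within a genotype, replicate 2 is regressed
on replicate 1 over the bound-region coverages (least squares through
the origin), giving the replicate scale factor *m*, and the replicates
are fused:

    fused(x) = ( rep1(x) + rep2(x) / m ) / 2

Between genotypes, "background peaks" called in the control sample by a
deliberately rudimentary signal-cutoff peak finder (cutoff 20) carry no
specific signal, so regressing fused genotype coverage on control
coverage over them gives the depth factor *m′*, and

    normalized(x) = fused(x) / m′

**CFR.** For each bound region, with coverage defined as the area of
the extended-read count curve over the region,

    CFR = coverage_ref / coverage_alt

capped at 300 when the mutant coverage falls below the area of a single
extended read (130 bp by default).

**Affinity threshold.** Sites are 19-bp windows scored additively by a
max-0 PWM (0 = optimal site, every other window negative). Instead of
an arbitrary score cutoff, per-region site densities in unit score
windows [0;−1], [−1;−2], … are compared between bound regions and a
GC-matched random negative set with one-sided Mann–Whitney tests; the
threshold is the deepest score reached by the contiguous run of
significant windows starting at [0;−1].

**Landscape and chromatin.** Regions are stratified into CFR deciles;
best site score, site density, 1-bp-gap site pairs (the spacing that
favours tetramer formation), the fraction of closed regions (a region
is *open* iff its centred half is entirely covered by open-chromatin
intervals), and the Pearson correlation of CFR with quantitative DHS
signal are compared across deciles.

## Worked example

Generate the default synthetic study condition (one 2-Mb chromosome,
300 bound regions, 100 background peaks, Poisson read noise, planted
replicate scale 1.3 and mutant depth factor 1.8) and run the full
pipeline:

```r
library(bindscape)

fx <- gen_fixture(sim_config(seed = 42L), "fixture")
cfg <- pipeline_config(
  ref_rep1 = fx$paths$ref_rep1, ref_rep2 = fx$paths$ref_rep2,
  alt_rep1 = fx$paths$alt_rep1, alt_rep2 = fx$paths$alt_rep2,
  control  = fx$paths$control,  regions  = fx$paths$regions,
  genome   = fx$paths$genome,   pwm      = fx$paths$pwm,
  open_bed = fx$paths$open_bed, dhs_bedgraph = fx$paths$dhs_bedgraph,
  seed = 42L)
res <- run_pipeline(cfg, "out")

res$scale_factors
#>   genotype     m m_prime n_peaks_m n_background_peaks
#> 1      ref 1.301  0.9952       300                102
#> 2      alt 1.301  1.7902       300                102
```

The planted factors (m = 1.3; depth 1.0 and 1.8) are recovered from the
noisy tracks. The per-region CFR table:

```r
head(res$cfr[, c("id", "cov_ref", "cov_alt", "cfr", "capped")], 4)
#>        id cov_ref cov_alt    cfr capped
#> 1 reg_001    8034    2834  2.835  FALSE
#> 2 reg_002   14898    1466 10.164  FALSE
#> 3 reg_003    8863    2535  3.497  FALSE
#> 4 reg_004   13666    6149  2.222  FALSE
```

The data-driven affinity threshold lands at the planted enrichment
floor (sites planted down to score −20):

```r
res$threshold
#> threshold_result: threshold = -21 (43/95 windows significant)
```

High-CFR regions lack high-affinity sites (extreme-decile Mann–Whitney
p = 6.5e-07), are enriched ~4-fold in 1-bp-gap site pairs
(counts by decile: 1 1 3 3 6 9 16 21 37 43), sit in closed chromatin
(closed fraction 0.10 in the lowest decile vs 0.93 in the highest), and
CFR falls as accessibility rises (Pearson r = −0.18, p = 0.0013) —
each the direction planted by the generator.

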