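---
title: "Methods: occupancy fold reduction and binding-site landscape analysis"
author: "bindscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy fold reduction and binding-site landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A transcription factor that assembles into higher-order oligomers can
reach genomic regions that a monomeric or dimeric variant cannot:
regions with only low-affinity recognition sites, regions with clusters
of closely spaced sites bound cooperatively, and regions buried in
closed chromatin. `bindscape` quantifies these effects from ChIP-seq of
two protein variants — a reference with intact oligomerization and a
mutant that cannot oligomerize — expressed in the same tissue, plus a
non-transgenic control.

The package deliberately starts downstream of read mapping and peak
calling: its inputs are per-base coverage tracks (bedGraph), ranked
bound regions (BED), the genome (FASTA), a position weight matrix
(TSV), and optionally open-chromatin intervals and a quantitative DNase
I hypersensitivity (DHS) signal track.

# Model and procedure

## Coverage and the two-step normalization

Reads are conceptually extended to the expected fragment length
(130 bp by default) from their 5' end; the track value at a base is the
number of extended reads covering it, and the *coverage* of a region is
the area of that curve (the per-base sum) over the region.
`extend_reads()` builds such tracks when read-level input is available;
the pipeline itself consumes tracks.

Two libraries never have the same depth, so coverages are made
comparable in two steps, both based on peak coverage comparisons:

1. **Within genotype.** Replicate-2 bound-region coverages are
   regressed on replicate-1 coverages. The fit is least squares
   through the origin, `m = sum(x*y)/sum(x^2)`: a region with no signal
   in one replicate should have none in the other, so a free intercept
   has no physical meaning here (one is still available via
   `intercept = TRUE` for diagnostics). Replicates are then fused
   position-wise as `fused = (rep1 + rep2/m)/2`. The fusion is
   anchored on replicate 1 rather than symmetrized; this convention
   makes fusing a genotype with itself an exact identity, which is the
   property the test suite pins.
2. **Between genotypes.** The control genotype carries no transgene,
   so peaks in the control track — found by `rudimentary_peak_find()`,
   a deliberately simple cutoff caller (signal >= 20; nearby runs
   merged when separated by fewer than `min_gap` bases, 30 in the
   pipeline, to keep Poisson jitter from fragmenting one peak into
   many) — are *background*: shared, non-specific enrichment. The
   depth factor `m'` is the through-origin slope of fused genotype
   coverage on control coverage over those background peaks, and the
   fused track is divided by it.

After both steps, both genotypes sit on the control's depth scale and
their coverages can be compared directly.

## The coverage fold reduction

For each bound region the CFR is the ratio of normalized reference
coverage to normalized mutant coverage. When the mutant coverage is
essentially zero the ratio is unstable or infinite, so records whose
mutant coverage falls below `min_alt_coverage` are set to the cap value
(300) and flagged. The default floor is the area contributed by one
extended read (`fragment_length`), i.e. "less than one read of
evidence": an explicit, testable version of capping "very low
coverage" denominators. The cap value itself is arbitrary by design —
capped records mean "no measurable mutant binding", not a measured
ratio, and downstream decile analyses treat them via ranks, where any
value above the observable range is equivalent.

## PWM scoring and the data-driven threshold

The PWM is an L x 4 matrix (L = 19 here) in max-0 convention: each row's
maximum is 0, so the optimal L-mer scores exactly 0 and every other
window scores negative, down to `min_score` (the sum of row minima).
`pwm(normalize = TRUE)` rescales any additive log-odds matrix into this
convention by subtracting row maxima — the convention, not a
particular matrix, is what the pipeline needs. Scanning scores every
offset on both strands (via the reverse-complemented matrix applied to
the forward sequence) and by default reports only the better-scoring
strand per offset, so palindromic matches are not double-counted;
windows containing N are skipped.

Rather than an arbitrary score cutoff, the threshold is computed from
the data. A negative set is sampled: for each bound region, a random
interval of the same length, with GC content within `gc_tol = 0.05`,
not overlapping any bound region; its annotation category (CDS,
intron, upstream, downstream, intergenic) is recorded but deliberately
not constrained. Per-region site densities (sites/kb) are tabulated in
unit score windows [0;-1], [-1;-2], ..., and each window is tested with
a one-sided Mann-Whitney test (bound > negative), uncorrected at
alpha = 0.05 (a Benjamini-Hochberg option exists but is off by default,
matching the per-window convention of the procedure this implements).
The threshold is the deepest score of the maximal contiguous
significant run starting at [0;-1]; if even the first window fails, the
result is "none".

Two numerical choices deserve a note. First, significance requires
`p < alpha` *and* a positive direction on window means, not medians: in
sparse windows the median density is 0 in both sets even under
overwhelming enrichment, so a median-based direction guard would veto
every sparse window regardless of evidence. Second, ties in the
Mann-Whitney test follow the standard mid-rank treatment: the exact
null distribution is used only when both samples have at most 8
observations and no ties, otherwise the normal approximation with tie
and continuity corrections (this is `stats::wilcox.test`'s behaviour,
pinned by the wrapper); two samples whose pooled values are all
identical carry no rank information and return p = 1, which is what an
empty score window should do.

## Spacing, deciles, and chromatin

The distance between two sites is the *gap between their footprints*,
`start_downstream - (start_upstream + L)`: "separated by 1 bp" means
one spacer base, the configuration that favours tetramer formation.
Start-to-start distances would shift every value by L and blur the
1-bp signal; overlapping sites (negative gaps) are excluded from the
histogram by default.

Decile machinery is shared by every stratified analysis: records are
ordered by the key (CFR, DHS, best score, ...), ties broken by peak
rank then id for determinism, and split into 10 groups whose sizes
differ by at most one, the remainder going to the lowest deciles.
Extreme-decile comparisons are two-sided Mann-Whitney tests of the
value between the first and last decile (the sidedness of the original
decile comparisons is not documented anywhere; two-sided is the
conservative choice).

A bound region is *open* iff its centred half — the middle 50%,
`[start + floor(len/4), end - floor(len/4))` — is entirely covered by
the union of open intervals; a single uncovered base closes it (the
strict reading of "entirely"). Openness is therefore invariant to any
splitting or merging of the open intervals that preserves their union,
and monotone under shrinking the open set; both properties are tested.
Quantitative DHS signal over a region is the same area-of-the-curve
sum as ChIP coverage (a mean would only rescale every value by region
length, which is constant here; the sum keeps one definition of
"coverage" package-wide). The CFR-DHS relation is reported as a
Pearson correlation on raw values (a log10 option exists) plus the
Mann-Whitney comparison of CFR between the lowest- and highest-DHS
deciles.

# The synthetic study condition

`gen_fixture()` emits every input the pipeline consumes, with ground
truth recorded in a JSON manifest. Defaults — fixed once, as the
package's study condition:

| parameter | default | why |
|---|---|---|
| genome | 1 chromosome, 2 Mb, GC 0.36 | Arabidopsis-like GC; large enough for GC-matched sampling, small enough for minutes-scale runs |
| GC heterogeneity | Beta blocks, sd 0.08, 1 kb | real genomes are GC mosaics; without it GC matching is trivially easy and motif-rich regions become unmatchable |
| bound regions | 300 x 300 bp | enough regions for decile rank tests with sparse per-window counts |
| background peaks | 100, amplitude 40, width 400 | the control peak finder's cutoff (20) falls mid-flank |
| background floor | 0.25 expected reads/base | nonspecific sequencing background |
| region amplitude | U(50, 100) | >= ~50 expected reads per peak at fragment length 130 |
| replicate scale `m_true` | 1.3 | typical library-depth imbalance |
| mutant depth `mprime_true` | 1.8 | reference emitted at control depth, so its fitted m' should be 1 |
| PWM | L = 19, penalties U(1.5, 6) | sharp ("highly predictive") matrix: random background rarely scores above -25, so planted enrichment is what the threshold procedure sees |
| site scores | best site U(-16, 0) per region; extra sites and 1-bp pairs U(floor, best); floor -20 | every called peak carries at least one moderate site; enrichment extends to the floor, which is what threshold recovery should find |
| zero-occupancy regions | 3 | exercise the CFR cap exactly |
| noise | per-base Poisson on expected extended-read counts | `noise = "none"` makes all recoveries exact, the basis of the identity tests |

Fold reduction is generated *from* the planted covariates —
`log f = log 2 + 0.8(-best/10) + 0.7 * unit_pairs + 0.15(n_sites - 4) + N(0, 0.35)`,
clipped to [1.3, 60] — and closedness is Bernoulli with a logistic
link in `log f`. DHS signal decreases with f for open regions. So high
fold reduction co-occurs with poor best sites, 1-bp-gap pairs, high
site density, and closed chromatin: exactly the directions the decile
analyses are supposed to detect, which is the generator's acceptance
surface.

Two structural notes on the site model. All non-best sites are drawn
at or below the region's best-site score; keeping best scores at or
above -16 while the threshold lands near -20 means a +/-3-unit
threshold shift never strips a region of all its sites, so the decile
conclusions are robust across that band (tested). And planting works
by hill-climbing single-base substitutions from the consensus until
the window scores within `tol` (0.5) of the target, so every manifest
score re-scores exactly from the emitted FASTA.

What the generator does *not* emulate: fragment-length distributions
(per-base Poisson noise is independent across bases, unlike real
read pileups, which are locally correlated), GC bias and mappability,
peak-shape diversity (one triangular kernel), motif self-overlap
structure, and biological replicate variability beyond a global scale
factor. Passing recovery tests therefore demonstrates correctness of
the computations and sensible statistical behaviour at realistic
signal-to-noise — not performance on any particular real data set.

# Degenerate inputs and tie-breaks

* bedGraph records that overlap are rejected, not summed: normalized
  tracks are non-overlapping by construction, so overlap indicates a
  malformed input.
* Chromosome-namespace mismatches (a region on a chromosome absent
  from a track or genome) are hard errors, never silent zeros.
* Equal-scoring strands at one offset report "+".
* Regions shorter than L cannot be scanned and error; regions of
  length < 2 have no centred half and error.
* `decile_partition` requires >= 10 records; remainder rule and tie
  order are deterministic, so reruns are byte-identical.
* All generator and pipeline randomness flows from explicit seeds; the
  caller's RNG state is saved and restored around every seeded
  operation.

# Problem sizes

The test suite runs the default 300-region condition once (shared
across acceptance checks), a 100-region condition for unit tests, a
noise-free condition for the exact identities, a 200-region condition
with the enrichment floor at -25, and twenty 120-region null repeats
for the no-enrichment case. These sizes were chosen so the rank tests
have clear power at the planted effect sizes while the whole suite
stays in the minutes range on a single CPU.

# Known limitations

* The replicate-fusion formula is reference-anchored by convention;
  a fully symmetric variant would differ by O((m-1)^2) terms. The
  choice is documented and isolated in `fuse_replicates()`.
* The threshold procedure assumes the significant run is contiguous
  from [0;-1]; an enrichment pattern with a gap in score space would
  be truncated at the gap (this is intentional and tested).
* `sample_negative_set` is rejection sampling; pathological inputs
  (a bound region far outside the genome's GC range) exhaust
  `max_tries` and error with the offending region named rather than
  silently relaxing the match.
* Mann-Whitney p-values under heavy ties use the normal approximation;
  at the suite's sample sizes this is standard practice, but exact
  conditional p-values under ties are not implemented.
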