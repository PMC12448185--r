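---
title: "Integrating somatic copy-number profiles: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating somatic copy-number profiles: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnseg)
```

## The problem

Somatic copy-number alteration (SCNA) profiles are lists of genomic
segments with copy-number (CN) states, either allele-specific
(major/minor) or total. Profiles called by different tools, on different
platforms, in different cohorts are not directly comparable: they cover
different parts of the genome, place breakpoints at slightly different
positions, and differ in resolution. `cnseg` turns a heterogeneous
collection of such profiles into a single samples-by-segments matrix plus
per-sample feature tables, through five stages: imputation, feature
extraction, sample filtering, consistent segmentation, and aggregation,
followed by exploratory statistics on the shared matrix.

All coordinates are 0-based half-open (BED-compatible) internally;
1-based inclusive inputs are converted at the I/O boundary by the
`segment_dialect()` `base` flag.

## Sex-aware genome model

The package distinguishes an X-like and a Y-like chromosome. The expected
"normal" CN is a pure function of (chromosome, allele, sex): autosomes
(1, 1); male X and Y (1, 0); female X (1, 1); female Y (0, 0). When no
sex is declared, a sample is called male iff it carries at least one
Y-chromosome segment with non-missing CN > 0. The `> 0` clause is a
deliberate choice: some callers emit explicit CN = 0 rows on Y for female
samples, and counting bare row presence would misclassify them. This is a
convention, not something the upstream definition settles.

A female sample's linear genome excludes the Y-like chromosome from
**both** numerators and denominators of every statistic. This single rule
makes the rest of the system consistent: post-imputation CN-coverage is
exactly 1.0 for both sexes, and female chrY never contributes to loss of
heterozygosity (its normal value is zero).

## Imputation

Three methods fill missing territory so that segments tile every
chromosome exactly; covered bases are never altered and all methods are
idempotent.

* **extension** (default): segments are pruned to the genome, the first
  and last segment of each chromosome are stretched to its ends, each
  interior gap is split at `gap_start + floor(gap_len / 2)` with the two
  halves taking the flanking CNs, fully missing chromosomes are set to 0,
  and abutting equal-CN segments are merged.
* **diploid**: newly created territory takes the sex-expected normal CN.
* **null**: newly created territory is 0.

Numerical conventions worth stating:

* The floor-midpoint rule gives the odd base of an odd-length gap to the
  right neighbor; a 1-base gap goes entirely right.
* A segment row whose CN columns are all `NA` carries no information and
  is treated as missing territory, not coverage.
* Neighbor merging uses exact equality per allele (`NA` matches `NA`);
  fractional consensus CNs merge only when bit-equal. Any tolerance here
  would silently change downstream breakpoint counts.

## Per-sample features

Six statistics, each computed for autosomes, sex chromosomes, and the
whole genome: monoallelic/biallelic CN-coverage, genome-not-diploid
(GnD), hemizygous/nullizygous LoH, allelic imbalance (AI), breakpoint
counts (per chromosome, per allele, plus distinct pooled positions), and
the mean absolute breakpoint step.

Design choices:

* All "proportion of the genome" features are weighted by base length,
  never by segment count, and denominators are always the full scope
  length — so coverage stays meaningful on unimputed profiles.
* LoH counts an allele only where its normal value is nonzero. On male
  sex chromosomes only the major allele is relevant, so a male X at
  (0, 0) is simultaneously hemizygous and nullizygous; nullizygous means
  "every relevant allele lost".
* A breakpoint is an interior position where an allele's CN changes
  between *abutting* segments; boundaries across gaps do not count
  (impute first to avoid missingness fabricating breaks) and a change
  between `NA` and a value is not a CN change.
* `breakpoint_step` pools the absolute jumps of both alleles into one
  mean rather than averaging per-allele means; the alternative is equally
  defensible but must be fixed once.
* In total-CN mode, GnD is a lower bound of the allele-specific value
  (copy-neutral events are invisible), AI and hemizygous LoH are
  reported `NA` rather than zero.

## Consistent segmentation

Four optional steps build one disjoint segment list shared by the cohort:

1. **Regions of interest** — whole chromosomes (default), chromosome
   arms or cytobands from a UCSC cytoBand file, or any BED (gene sets are
   user-supplied; they are licensed resources and not bundled).
2. **Exclusion subtraction with filter `f`** — exclusion regions shorter
   than `f` are dropped first; fragments created by the subtraction that
   are shorter than `f` are dropped afterwards. Regions the subtraction
   never touched survive regardless of length.
3. **Breakpoint pooling and greedy merging with distance `m`** — the
   union of all samples' breakpoints per chromosome is clipped to the
   surviving regions (breakpoints inside excluded territory are dropped)
   and merged: starting at the leftmost breakpoint, every breakpoint
   within `m` of that *anchor* (inclusive) joins the cluster, which is
   replaced by the floor of its mean; the loop restarts at the leftmost
   unmerged breakpoint. Membership is tested against the anchor, not
   chained between neighbors — chained semantics can swallow arbitrarily
   long runs. Merged positions may in pathological chains end up closer
   than `m`; the algorithm does not guarantee otherwise and we do not
   assert it.
4. **Binning with split size `s`** — three strategies: `"start"`
   (boundaries every `s` from the region start; a final remainder bin
   shorter than `s/2`, strictly, merges into its predecessor),
   `"centered"` (the remainder is split across both ends; end bins
   shorter than `s/2` merge into their neighbors), and `"same_size"`
   (with `c` bins counting the padding bin, emit `c - 1` equal bins when
   the padding is at most `s/2`, inclusive, else `c`; integer boundaries
   by rounding cumulative positions half-up, so bin lengths differ by at
   most one base). The strict-vs-inclusive `s/2` asymmetry between the
   strategies is intentional and matches their stated definitions.
   Regions shorter than `s` stay whole.

## Aggregation

Profiles are first split at the segmentation boundaries, then combined
per target segment and allele by `min`, `max`, or length-weighted `mean`
(or not at all, `how = "none"`, which returns the refined pieces).
Aggregation runs over covered, non-missing bases only; a segment with no
covered base is `NA` — "no data" is never conflated with "CN 0". `mean`
is the programmatic default because it conserves each sample's overall
copy number; `min` is the recommended mode for gene regions, where a
partially deleted gene is unlikely to yield a functional copy.

## Sample filtering

`zscore_filter()` standardizes a feature and removes samples with
`|z| >= k` (default 3, the boundary inclusive). The standard deviation is
the population formula (divide by N) — the choice is not settled
upstream, so it is fixed and documented here. Zero variance keeps every
sample and flags the result degenerate.

`knee_point()` finds qualitative thresholds: sorted distinct feature
values form `T`, cumulative counts `|f(S) <= t|` form `Y`, both are
unit-normalized, and each interior candidate is scored by the angle
between the vector from the origin to the point and the vector from the
point to (1, 1). The maximum absolute angle wins; ties resolve to the
smallest threshold. The sign of the cross product classifies the optimum:
negative (clockwise; curve above the diagonal) is a knee, positive an
elbow. This sign convention presumes the usual x-right/y-up frame and is
our documented choice. A perfectly linear curve is degenerate (no knee).
Restricting the curve to a sub-range (e.g. "samples below 1% GnD") is an
explicit `upper` argument, never hidden behavior.

## Scores on the aggregated matrix

* **NMD** — each vector is divided by its sum before taking the
  Manhattan distance, which cancels whole-genome doubling exactly. NMD is
  a pseudometric bounded by 2. Missing cells are an error: aggregate
  imputed profiles.
* **Outlier score** — mean NMD from a sample to a cluster's members. The
  divisor is the cluster size after self-exclusion: including the
  sample's zero self-distance would deflate scores purely by cluster
  membership. On allele-specific matrices scores default to total CN.
* **Contrastive outlier score** — `OS(S, C2) - OS(S, C1)`; low or
  negative values flag samples resembling the other class (candidate
  mislabels). Whether to cut the score distribution at a knee or an
  elbow, and on which tail, is data-dependent and left to the caller.
* **Peak score** — the discrete second difference with reflected
  boundaries (`s_0 = s_1`, `s_{n+1} = s_n`), computed independently per
  chromosome; it telescopes to zero over each chromosome and requires
  contiguous, comparably sized bins. Note an intrinsic tie: an event
  spanning k >= 2 bins gives its edge bins and their flanking valleys
  equal |PS|, so the argmax localizes the event only to within one bin.
  A one-bin event's peak strictly dominates its valleys.
* **Discriminatory features** — per-segment two-sided Mann-Whitney U
  with normal approximation and tie correction (no continuity
  correction), Benjamini-Hochberg adjusted across all segments as one
  family. Constant pooled values give p = 1 by convention. Tests validate
  the approximation against exact enumeration for small groups.

## Synthetic cohorts

`simulate_cohort()` generates seeded cohorts with ground truth: a diploid
baseline per sample, class-specific events (arm-level gains/losses, focal
amplifications, LoH tracts, each with a carrier probability), optional
whole-genome doubling, per-segment jitter (profiles stay piecewise
constant), and one missing gap per chromosome sized to `gap_fraction`,
placed around the chromosome midpoint to mimic the concentration of real
missingness near centromeres (uniform placement is available).

Defaults state the emulated world once: 25 samples per class, 5% missing
genome (public pan-cancer cohorts cover ~91–98% before gap filtering),
25% WGD samples (a typical pan-cancer fraction), no jitter. The generator
reproduces the *structure* real cohorts show — class-mean profiles with
arm and focal events, coverage gaps, WGD scale shifts. It does not
emulate caller-specific noise, subclonal mixtures, correlated event
co-occurrence, or chromothripsis; a green recovery test therefore
establishes that the statistics recover clean planted signals, not that
they are robust to every real-data pathology.

## Degenerate inputs and numerical notes

* `knee_point()` needs >= 3 distinct values; `zscore_filter()` >= 2
  samples.
* `nmd()` rejects zero-sum vectors (a profile that is all zeros has no
  normalized direction).
* `breakpoint_step` over a scope without breakpoints is `NA`, not 0.
* Empty scopes (sex scope on a genome without sex chromosomes) report
  `NA` features.
* Merge/bin arithmetic is integer-valued throughout (floors and half-up
  rounding), so segmentations are reproducible byte-for-byte across
  platforms; cohort results are independent of the worker count used.

## Known limitations

* Total-CN and allele-specific profiles cannot be mixed in one cohort.
* No liftover: cohorts must already share a reference genome.
* The greedy merge is order-dependent by construction (left to right);
  it is the stated algorithm, not a globally optimal clustering.
* Gene-level aggregation treats genes as plain intervals (no exon
  awareness).
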