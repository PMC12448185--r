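# cnseg

Integration, consistent segmentation and feature extraction for somatic
copy-number (SCNA) profiles.

Most cancers carry somatic copy-number alterations — gains and losses of
chromosomal regions. Public cohorts publish them as per-sample segment
tables (sample, chromosome, start, end, major/minor or total copy
number), but tables from different callers and platforms cover different
parts of the genome, place breakpoints differently, and use different
resolutions, so they cannot be compared or pooled directly. `cnseg` is
for anyone who wants to put heterogeneous SCNA callsets — consensus WGS
calls, SNP-array calls, WES calls — into one analysis: it imputes missing
territory, computes sex-aware per-sample QC statistics, builds a single
segmentation shared by every sample, and projects all profiles onto it,
yielding a samples × segments matrix ready for statistics or machine
learning.

## What it computes

* **Imputation** — fill gaps so segments tile the genome: `extension`
  (stretch flanking segments; interior gaps split at
  `gap_start + ⌊gap/2⌋`), `diploid` (sex-expected normal CN), or `null`
  (0). Covered bases are never altered; the operation is idempotent.
* **Features** (per sample × scope ∈ {autosomes, sex chromosomes,
  genome}) — mono-/biallelic CN-coverage; genome-not-diploid
  GnD = fraction of the genome where an allele deviates from the normal
  CN of the sample's sex; hemizygous/nullizygous LoH (an allele counts
  only where its normal value is nonzero); allelic imbalance
  (major ≠ minor); breakpoint counts per allele plus distinct pooled
  positions; mean absolute breakpoint step.
* **Consistent segmentation** — regions of interest (chromosomes, arms,
  cytobands, BED) → exclusion subtraction with fragment filter *f* →
  greedy merging of the cohort's pooled breakpoints within distance *m*
  (anchored clusters, replaced by the floor of their mean) → binning with
  split size *s* (start-anchored, centered, or same-size strategies).
* **Aggregation** — per segment and allele: min, max, or length-weighted
  mean over covered bases; uncovered segments are `NA`, never 0.
* **Sample filtering** — z-score outlier removal
  (`z = (f − μ)/σ`, remove at `|z| ≥ k`, default k = 3) and knee/elbow
  detection: the threshold maximizing the angle between the vectors
  origin→(t′, y′) and (t′, y′)→(1, 1) on the unit-normalized cumulative
  feature curve.
* **Scores** — normalized Manhattan distance
  `NMD(S, R) = Σ |sᵢ/ΣS − rᵢ/ΣR|` (invariant to whole-genome doubling);
  outlier score `OS(S, C)` = mean NMD to a cluster; contrastive
  `OS(S, C1, C2) = OS(S, C2) − OS(S, C1)`; peak score
  `PS(S, i) = (sᵢ − sᵢ₋₁) − (sᵢ₊₁ − sᵢ)` with reflected boundaries;
  per-segment Mann-Whitney U tests with Benjamini-Hochberg correction.
* **Synthetic cohorts** — a seeded generator with ground truth (class
  events, WGD, jitter, centromere-concentrated gaps) so everything is
  testable without downloads.

hg19 and hg38 chromosome tables ship with the package; any genome can be
supplied as a `chrom.sizes` file.

## Worked example

```r
library(cnseg)

g <- toy_genome()                                   # 3 autosomes + X + Y
sim <- simulate_cohort(sim_config(genome = g, n_samples = 4, seed = 42))
cohort <- impute(sim$cohort)                        # tile every chromosome

feats <- cn_features(cohort)
feats[scope == "genome", .(sample_id, sex, gnd, loh_hemi, ai, breakpoints)][1:4]
#>      sample_id    sex       gnd   loh_hemi        ai breakpoints
#> 1: arm_gain_01 female 0.2364931 0.06896552 0.2364931           2
#> 2: arm_gain_02 female 0.2413793 0.06896552 0.2413793           2
#> 3: arm_gain_03 female 0.2413793 0.06896552 0.2413793           2
#> 4: arm_gain_04   male 0.2275194 0.06451613 0.4533258           2
```

The `arm_gain` class carries a gain on the distal half of chr1 and a
copy-neutral LoH tract on proximal chr1; together they alter ~24% of the
genome (GnD ≈ 0.24), and the LoH tract alone covers ~7%
(`loh_hemi` ≈ 0.069). The male sample's X and Y at (1, 0) raise its
allelic imbalance but, being the normal male state, add nothing to GnD.

```r
seg <- consistent_segmentation(load_region_set("chromosomes", g),
                               split_size = 20e3)
seg
#> <cn_segmentation> 15 segments on 5 chromosomes (f=0, m=0, s=20000, same_size)

mat <- aggregate_cohort(cohort, seg, how = "mean")
m <- total_matrix(mat)                              # major + minor
round(m[1:3, 1:5], 2)
#>             [,1] [,2] [,3] [,4] [,5]
#> arm_gain_01    2    2 2.43    3    3
#> arm_gain_02    2    2 2.50    3    3
#> arm_gain_03    2    2 2.50    3    3
```

Bin 3 straddles the gain's breakpoint at 50 kb, so its value is the
length-weighted mean of CN 2 and CN 3 (2.50; 2.43 for the sample whose
random gap shifted the covered weights). Downstream, the matrix feeds the
scores directly, e.g. `nmd(m[1, ], 2 * m[1, ])` is exactly `0`
(whole-genome doubling is invisible to NMD), and
`discriminatory_features(m[groupA, ], m[groupB, ])` ranks segments by
BH-adjusted Mann-Whitney q-values.

## Command line

Every stage is a subcommand of the wrapper in `inst/cli/cnseg`
(`simulate`, `impute`, `stats`, `filter`, `segment`, `aggregate`,
`score`, `pipeline`), e.g.

```sh
Rscript inst/cli/cnseg impute --method extension --genome hg19 \
    --in segs.tsv --out imputed.tsv
Rscript inst/cli/cnseg segment --regions chromosomes --split 5000000 \
    --strategy same_size --genome hg19 --out segments.bed
```

Exit codes: 0 ok, 1 validation failure, 2 usage error. `pipeline
--config pipe.json` runs a declared stage list reproducibly
(see `?run_pipeline`).

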