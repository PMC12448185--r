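# Per-sample statistics, each computed over three scopes: autosomes, sex
# chromosomes, and the whole (sex-aware) genome. The linear genome of a
# female sample excludes the Y-like chromosome, so scope denominators — and
# numerators — depend on the sample's sex. All "proportion of the genome"
# statistics are weighted by base length; denominators are always the full
# scope length, so values remain comparable between imputed and gapped
# profiles.

scope_segments <- function(profile, scope) {
  chroms <- scope_chroms(profile$genome, scope, profile$sex)
  list(seg = profile$segments[profile$segments$chrom %in% chroms, , drop = FALSE],
       chroms = chroms,
       length = sum(profile$genome$lengths[chroms]))
}

#' CN-coverage: fraction of the scope with an assigned copy number
#'
#' Monoallelic coverage counts bases where any allele has a value,
#' biallelic coverage where both do. In total-CN mode the two coincide.
#'
#' @param profile A [cn_profile].
#' @param scope `"genome"`, `"autosomes"` or `"sex"`.
#' @return Named numeric `c(mono =, bi =)`; `NA` when the scope is empty
#'   (e.g. sex scope on a genome without sex chromosomes).
#' @export
cn_coverage <- function(profile, scope = c("genome", "autosomes", "sex")) {
  scope <- match.arg(scope)
  sc <- scope_segments(profile, scope)
  if (sc$length == 0) return(c(mono = NA_real_, bi = NA_real_))
  seg <- sc$seg
  len <- seg$end - seg$start
  if (profile$mode == "total") {
    cov <- sum(len[!is.na(seg$cn_total)])
    return(c(mono = cov, bi = cov) / sc$length)
  }
  any_cn <- !is.na(seg$cn_major) | !is.na(seg$cn_minor)
  both_cn <- !is.na(seg$cn_major) & !is.na(seg$cn_minor)
  c(mono = sum(len[any_cn]), bi = sum(len[both_cn])) / sc$length
}

# per-row (major, minor) normal expectation for a profile's segments
normal_cols <- function(seg, profile) {
  g <- profile$genome
  pairs <- vapply(seg$chrom, normal_pair, numeric(2), sex = profile$sex,
                  genome = g)
  list(major = pairs[1, ], minor = pairs[2, ])
}

#' Genome-not-diploid: fraction of the scope deviating from normal CN
#'
#' Fraction of scope bases where any allele differs from the copy number a
#' normal cell of the sample's sex would carry. In total-CN mode the
#' deviation of the total from the expected total is used, a lower bound
#' on the allele-specific value (balanced events like copy-neutral LoH are
#' invisible to totals).
#'
#' @inheritParams cn_coverage
#' @return A fraction in `[0, 1]`, `NA` on an empty scope.
#' @export
genome_not_diploid <- function(profile, scope = c("genome", "autosomes", "sex")) {
  scope <- match.arg(scope)
  sc <- scope_segments(profile, scope)
  if (sc$length == 0) return(NA_real_)
  seg <- sc$seg
  if (nrow(seg) == 0L) return(0)
  len <- seg$end - seg$start
  norm <- normal_cols(seg, profile)
  if (profile$mode == "total") {
    dev <- !is.na(seg$cn_total) & seg$cn_total != (norm$major + norm$minor)
  } else {
    dev <- (!is.na(seg$cn_major) & seg$cn_major != norm$major) |
           (!is.na(seg$cn_minor) & seg$cn_minor != norm$minor)
  }
  sum(len[dev]) / sc$length
}

#' Loss of heterozygosity: hemizygous and nullizygous fractions
#'
#' A base counts as LoH on an allele iff that allele's CN is 0 while its
#' normal value is nonzero (so the Y-like chromosome of a female sample,
#' or the minor allele of a male sex chromosome, never counts). Hemizygous:
#' at least one such allele lost; nullizygous: every allele with nonzero
#' normal value lost. In total-CN mode only the nullizygous fraction is
#' computable (total = 0); hemizygous is reported `NA`.
#'
#' @inheritParams cn_coverage
#' @return Named numeric `c(hemi =, nulli =)`.
#' @export
loh <- function(profile, scope = c("genome", "autosomes", "sex")) {
  scope <- match.arg(scope)
  sc <- scope_segments(profile, scope)
  if (sc$length == 0) return(c(hemi = NA_real_, nulli = NA_real_))
  seg <- sc$seg
  if (nrow(seg) == 0L)
    return(c(hemi = if (profile$mode == "total") NA_real_ else 0, nulli = 0))
  len <- seg$end - seg$start
  norm <- normal_cols(seg, profile)
  if (profile$mode == "total") {
    nul <- !is.na(seg$cn_total) & seg$cn_total == 0 &
           (norm$major + norm$minor) > 0
    return(c(hemi = NA_real_, nulli = sum(len[nul]) / sc$length))
  }
  lost_major <- !is.na(seg$cn_major) & seg$cn_major == 0 & norm$major > 0
  lost_minor <- !is.na(seg$cn_minor) & seg$cn_minor == 0 & norm$minor > 0
  relevant_minor <- norm$minor > 0  # on male sex chromosomes only major counts
  hemi <- lost_major | lost_minor
  nulli <- lost_major & (!relevant_minor | lost_minor)
  c(hemi = sum(len[hemi]), nulli = sum(len[nulli])) / sc$length
}

#' Allelic imbalance: fraction where one allele strictly exceeds the other
#'
#' @inheritParams cn_coverage
#' @return A fraction; `NA` in total-CN mode (alleles are not resolved).
#' @export
allelic_imbalance <- function(profile, scope = c("genome", "autosomes", "sex")) {
  scope <- match.arg(scope)
  if (profile$mode == "total") return(NA_real_)
  sc <- scope_segments(profile, scope)
  if (sc$length == 0) return(NA_real_)
  seg <- sc$seg
  if (nrow(seg) == 0L) return(0)
  len <- seg$end - seg$start
  imb <- !is.na(seg$cn_major) & !is.na(seg$cn_minor) &
         seg$cn_major != seg$cn_minor
  sum(len[imb]) / sc$length
}

# Interior positions where an allele's CN changes between abutting segments.
# Gapped boundaries are not breakpoints (impute first to avoid spurious
# gaps); a change from NA to a value is not a comparable CN change.
breakpoint_positions <- function(profile, scope = "genome") {
  sc <- scope_segments(profile, scope)
  seg <- sc$seg
  cols <- cn_columns(profile)
  out <- lapply(cols, function(cc) {
    if (nrow(seg) < 2L)
      return(data.table::data.table(chrom = character(), pos = numeric()))
    n <- nrow(seg)
    abut <- seg$chrom[-1] == seg$chrom[-n] & seg$start[-1] == seg$end[-n]
    a <- seg[[cc]][-n]; b <- seg[[cc]][-1]
    change <- abut & !is.na(a) & !is.na(b) & a != b
    data.table::data.table(chrom = seg$chrom[-n][change],
                           pos = seg$end[-n][change])
  })
  names(out) <- sub("cn_", "", cols)
  out
}

#' Breakpoint counts per chromosome and allele
#'
#' A breakpoint is an interior position where an allele's copy number
#' changes between abutting segments. The `total` column counts distinct
#' positions where any allele changes, so it is at most the sum of the
#' per-allele counts (both alleles may break at the same position).
#'
#' @inheritParams cn_coverage
#' @return A list with `per_chrom` (data.table chrom x allele counts) and
#'   `total` (named vector over alleles plus `"total"`).
#' @export
breakpoint_counts <- function(profile, scope = c("genome", "autosomes", "sex")) {
  scope <- match.arg(scope)
  pos <- breakpoint_positions(profile, scope)
  chroms <- scope_chroms(profile$genome, scope, profile$sex)
  per <- data.table::data.table(chrom = chroms)
  for (al in names(pos))
    per[[al]] <- vapply(chroms, function(ch) sum(pos[[al]]$chrom == ch), 0)
  pooled <- unique(data.table::rbindlist(pos))
  per$total <- vapply(chroms, function(ch) sum(pooled$chrom == ch), 0)
  totals <- if (profile$mode == "allele")
    c(vapply(pos, nrow, 0L), total = nrow(pooled))
  else c(total = nrow(pooled))
  list(per_chrom = per, total = totals)
}

#' Mean absolute copy-number step across breakpoints
#'
#' The mean, over every breakpoint of every allele (pooled), of the
#' absolute CN difference between the right and left segment. Impute first:
#' gapped boundaries contribute nothing.
#'
#' @inheritParams cn_coverage
#' @return Mean step, or `NA` when the scope has no breakpoints.
#' @export
breakpoint_step <- function(profile, scope = c("genome", "autosomes", "sex")) {
  scope <- match.arg(scope)
  sc <- scope_segments(profile, scope)
  seg <- sc$seg
  if (nrow(seg) < 2L) return(NA_real_)
  n <- nrow(seg)
  abut <- seg$chrom[-1] == seg$chrom[-n] & seg$start[-1] == seg$end[-n]
  steps <- numeric(0)
  for (cc in cn_columns(profile)) {
    a <- seg[[cc]][-n]; b <- seg[[cc]][-1]
    change <- abut & !is.na(a) & !is.na(b) & a != b
    steps <- c(steps, abs(b[change] - a[change]))
  }
  if (!length(steps)) return(NA_real_)
  mean(steps)
}

#' Full feature table for a cohort
#'
#' Computes every per-sample statistic for all three scopes: CN-coverage
#' (mono/bi), genome-not-diploid, LoH (hemi/nulli), allelic imbalance,
#' breakpoint count and mean breakpoint step.
#'
#' @param x A [cn_cohort] or [cn_profile].
#' @param workers Parallel workers over samples.
#' @return data.table with one row per (sample, scope).
#' @export
cn_features <- function(x, workers = 1L) {
  if (inherits(x, "cn_profile")) x <- cn_cohort(list(x))
  stopifnot(inherits(x, "cn_cohort"))
  rows <- cohort_apply(x, function(p) {
    data.table::rbindlist(lapply(c("autosomes", "sex", "genome"), function(sc) {
      cov <- cn_coverage(p, sc)
      lo <- loh(p, sc)
      bp <- breakpoint_counts(p, sc)
      data.table::data.table(
        sample_id = p$sample_id, scope = sc, sex = p$sex,
        coverage_mono = cov[["mono"]], coverage_bi = cov[["bi"]],
        gnd = genome_not_diploid(p, sc),
        loh_hemi = lo[["hemi"]], loh_nulli = lo[["nulli"]],
        ai = allelic_imbalance(p, sc),
        breakpoints = unname(bp$total[["total"]]),
        breakpoint_step = breakpoint_step(p, sc))
    }))
  }, workers)
  data.table::rbindlist(rows)
}
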