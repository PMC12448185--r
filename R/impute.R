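# Gap imputation. Profiles from heterogeneous callers rarely tile the whole
# genome; imputation fills every base so that downstream breakpoint and
# aberration statistics are not driven by missingness.
#
# The "extension" method: (i) prune segments to the genome, (ii) stretch the
# first/last segment of each chromosome to its ends, (iii) split each
# interior gap at gap_start + floor(gap_len / 2) and give each half the CN
# of its flanking segment, (iv) set fully missing chromosomes to 0,
# (v) merge abutting segments with identical CN. "diploid" and "null"
# instead fill all newly created territory with the sex-expected normal CN
# or with 0, respectively. Originally covered bases are never altered.

#' Impute missing territory of a copy-number profile
#'
#' After imputation the segments of every chromosome tile `[0, length)`
#' exactly; bases covered in the input keep their copy number unchanged,
#' and the operation is idempotent.
#'
#' @param x A [cn_profile] or [cn_cohort].
#' @param method `"extension"` (stretch flanking segments into gaps, split
#'   interior gaps at the floor midpoint), `"diploid"` (fill new territory
#'   with the normal copy number of the sample's sex) or `"null"` (fill
#'   with 0).
#' @param workers Parallel workers for cohorts (results are identical for
#'   any worker count).
#' @return The imputed object of the same class.
#' @examples
#' g <- toy_genome()
#' p <- cn_profile("s1", data.frame(chrom = "chr1", start = 10e3, end = 40e3,
#'                                  cn_major = 2, cn_minor = 1), g)
#' impute(p)$segments
#' @export
impute <- function(x, method = c("extension", "diploid", "null"), workers = 1L) {
  method <- match.arg(method)
  if (inherits(x, "cn_cohort"))
    return(cn_cohort(cohort_apply(x, function(p) impute(p, method), workers)))
  stopifnot(inherits(x, "cn_profile"))
  genome <- x$genome
  cols <- cn_columns(x)
  fill_values <- function(chrom) {
    switch(method,
      extension = ,  # extension's whole-chromosome fallback is 0
      null = stats::setNames(rep(0, length(cols)), cols),
      diploid = {
        pair <- normal_pair(chrom, x$sex, genome)
        if (x$mode == "allele")
          c(cn_major = pair[1], cn_minor = pair[2])
        else c(cn_total = sum(pair))
      })
  }
  # a row with no CN value on any allele is missing data, not coverage
  has_value <- Reduce(`|`, lapply(cols, function(cc) !is.na(x$segments[[cc]])))
  segments <- x$segments[has_value, , drop = FALSE]
  per_chrom <- lapply(genome$chroms, function(ch) {
    len <- chrom_length(genome, ch)
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) {
      vals <- if (method == "diploid") fill_values(ch)
              else stats::setNames(rep(0, length(cols)), cols)
      return(data.table::data.table(chrom = ch, start = 0, end = len,
                                    t(vals)))
    }
    if (method == "extension") {
      seg$start[1] <- 0
      seg$end[nrow(seg)] <- len
      pieces <- list(seg[1])
      if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
        gap <- seg$start[i] - seg$end[i - 1]
        if (gap > 0) {
          # left half = floor(gap/2); a 1-base gap goes entirely right
          mid <- seg$end[i - 1] + floor(gap / 2)
          if (mid > seg$end[i - 1]) {
            left <- data.table::copy(seg[i - 1])
            left[, c("start", "end") := .(seg$end[i - 1], mid)]
            pieces <- c(pieces, list(left))
          }
          right <- data.table::copy(seg[i])
          right[, c("start", "end") := .(mid, seg$start[i])]
          pieces <- c(pieces, list(right))
        }
        pieces <- c(pieces, list(seg[i]))
      }
      out <- data.table::rbindlist(pieces)
    } else {
      vals <- fill_values(ch)
      gaps <- list()
      add_gap <- function(s, e) {
        if (e > s)
          gaps[[length(gaps) + 1L]] <<- data.table::data.table(
            chrom = ch, start = s, end = e, t(vals))
      }
      add_gap(0, seg$start[1])
      if (nrow(seg) > 1) for (i in 2:nrow(seg))
        add_gap(seg$end[i - 1], seg$start[i])
      add_gap(seg$end[nrow(seg)], len)
      out <- data.table::rbindlist(c(list(seg), gaps), use.names = TRUE)
      data.table::setorder(out, start)
    }
    out
  })
  seg <- data.table::rbindlist(per_chrom, use.names = TRUE)
  data.table::setcolorder(seg, c("chrom", "start", "end", cols))
  out <- cn_profile(x$sample_id, seg, genome, sex = x$declared_sex,
                    mode = x$mode)
  out$sex <- x$sex  # imputation must not flip an inferred sex
  merge_equal_neighbors(out)
}

#' Merge abutting segments with identical copy number
#'
#' Two consecutive segments of the same chromosome are merged when they
#' abut (end == next start) and agree exactly on every copy-number column
#' (`NA` matches `NA`; fractional values merge only when bit-equal — any
#' tolerance would silently change breakpoint counts). The per-base
#' copy-number function is unchanged.
#'
#' @param profile A [cn_profile].
#' @return A [cn_profile] with no mergeable neighbors.
#' @export
merge_equal_neighbors <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  seg <- profile$segments
  if (nrow(seg) < 2L) return(profile)
  cols <- cn_columns(profile)
  same_val <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  n <- nrow(seg)
  joinable <- seg$chrom[-1] == seg$chrom[-n] & seg$start[-1] == seg$end[-n]
  for (cc in cols)
    joinable <- joinable & same_val(seg[[cc]][-1], seg[[cc]][-n])
  # run id increments whenever a row does not join its predecessor
  run <- cumsum(c(TRUE, !joinable))
  merged <- seg[, {
    .(chrom = chrom[1], start = start[1], end = end[.N])
  }, by = .(run_id = run)][, -"run_id"]
  firsts <- which(!duplicated(run))
  for (cc in cols) merged[[cc]] <- seg[[cc]][firsts]
  out <- profile
  out$segments <- merged
  out
}
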