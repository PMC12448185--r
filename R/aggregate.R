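# Projection of profiles onto a shared segmentation: the samples x
# segments matrix that downstream statistics and classifiers consume.

new_cn_matrix <- function(sample_ids, segments, values, how) {
  structure(list(sample_ids = sample_ids,
                 segments = data.table::as.data.table(segments),
                 values = values, how = how),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("<cn_matrix> %d samples x %d segments (%s; %s aggregation)\n",
              length(x$sample_ids), nrow(x$segments),
              paste(names(x$values), collapse = "+"), x$how))
  invisible(x)
}

#' Total-CN matrix of an aggregated cohort
#'
#' For allele-specific matrices, the elementwise sum of the major and minor
#' matrices; for total-mode matrices, the matrix itself.
#' @param mat A [cn_matrix].
#' @return Numeric matrix, samples x segments.
#' @export
total_matrix <- function(mat) {
  stopifnot(inherits(mat, "cn_matrix"))
  if ("total" %in% names(mat$values)) return(mat$values$total)
  mat$values$cn_major + mat$values$cn_minor
}

# Overlap pieces of a profile's segments with one target region
region_pieces <- function(seg, r) {
  hit <- seg$chrom == r$chrom & seg$start < r$end & seg$end > r$start
  p <- seg[hit, , drop = FALSE]
  if (nrow(p) == 0L) return(p)
  p$start <- pmax(p$start, r$start)
  p$end <- pmin(p$end, r$end)
  p
}

#' Aggregate one profile onto a segmentation
#'
#' The profile's segments are first split at the segmentation boundaries;
#' within each target segment the covered pieces are then combined per
#' allele: `min`, `max`, or length-weighted `mean`. `how = "none"` skips
#' combination and returns the refined pieces restricted to the
#' segmentation. Copy numbers aggregate over covered (non-missing) bases
#' only; a target segment with no covered base is `NA` — "no data" is
#' never conflated with "CN 0".
#'
#' @param profile A [cn_profile].
#' @param seg A [cn_segmentation] (or [cn_regions]).
#' @param how `"mean"` (default, length-weighted), `"min"`, `"max"`, or
#'   `"none"`.
#' @return For min/max/mean: a named list of numeric vectors, one per CN
#'   column. For `"none"`: a data.table of refined segments.
#' @export
aggregate_profile <- function(profile, seg,
                              how = c("mean", "min", "max", "none")) {
  how <- match.arg(how)
  regs <- if (inherits(seg, "cn_segmentation")) seg$regions else seg
  cols <- cn_columns(profile)
  sseg <- profile$segments
  if (how == "none") {
    pieces <- lapply(seq_len(nrow(regs)), function(i)
      region_pieces(sseg, regs[i]))
    return(data.table::rbindlist(pieces))
  }
  vals <- lapply(cols, function(cc) rep(NA_real_, nrow(regs)))
  names(vals) <- cols
  for (i in seq_len(nrow(regs))) {
    p <- region_pieces(sseg, regs[i])
    if (nrow(p) == 0L) next
    w <- p$end - p$start
    for (cc in cols) {
      v <- p[[cc]]
      ok <- !is.na(v)
      if (!any(ok)) next
      vals[[cc]][i] <- switch(how,
        min = min(v[ok]),
        max = max(v[ok]),
        mean = sum(v[ok] * w[ok]) / sum(w[ok]))
    }
  }
  vals
}

#' Aggregate a cohort into a samples x segments matrix
#'
#' @param cohort A [cn_cohort] (one shared mode; mixing total and
#'   allele-specific profiles is rejected by [cn_cohort()]).
#' @param seg A [cn_segmentation].
#' @param how Aggregation mode, see [aggregate_profile()]. `"min"` is the
#'   recommended mode for gene regions (a partially deleted gene is
#'   unlikely to yield a functional copy); `"mean"` is the default for
#'   bins because it preserves each sample's overall copy number.
#' @param workers Parallel workers over samples.
#' @return A [cn_matrix]: row order follows the cohort, column order the
#'   segmentation; allele-specific cohorts carry one matrix per allele.
#' @export
aggregate_cohort <- function(cohort, seg, how = c("mean", "min", "max"),
                             workers = 1L) {
  how <- match.arg(how)
  stopifnot(inherits(cohort, "cn_cohort"))
  per <- cohort_apply(cohort, function(p) aggregate_profile(p, seg, how),
                      workers)
  cols <- if (attr(cohort, "mode") == "allele") c("cn_major", "cn_minor")
          else "cn_total"
  values <- lapply(cols, function(cc)
    do.call(rbind, lapply(per, `[[`, cc)))
  names(values) <- sub("cn_total", "total", cols)
  ids <- names(cohort)
  for (i in seq_along(values)) rownames(values[[i]]) <- ids
  regs <- if (inherits(seg, "cn_segmentation")) seg$regions else seg
  new_cn_matrix(ids, regs, values, how)
}
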