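# Per-sample copy-number profiles and cohorts. A profile is an ordered,
# non-overlapping segment table in one of two modes: "allele" (cn_major /
# cn_minor, either may be missing per segment) or "total" (cn_total).

#' Construct a single-sample copy-number profile
#'
#' @param sample_id Sample identifier.
#' @param segments A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and either `cn_major`/`cn_minor` or `cn_total`.
#'   Copy numbers may be fractional (consensus callers emit non-integer CN)
#'   and missing (`NA`); they must be non-negative when present.
#' @param genome A [cn_genome] the coordinates live on.
#' @param sex Optional declared sex (`"female"`/`"male"`); when omitted the
#'   sex is inferred from Y-chromosome presence via [infer_sex()].
#' @param mode `"allele"` or `"total"`; inferred from the columns present
#'   when omitted.
#'
#' @return An object of class `cn_profile` with fields `sample_id`,
#'   `segments` (sorted data.table), `mode`, `sex`, `genome`.
#' @export
cn_profile <- function(sample_id, segments, genome, sex = NULL, mode = NULL) {
  stopifnot(inherits(genome, "cn_genome"))
  seg <- data.table::as.data.table(segments)
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(seg)))
    stop("segments must have columns chrom, start, end", call. = FALSE)
  if (is.null(mode)) {
    mode <- if ("cn_total" %in% names(seg) &&
                !all(c("cn_major", "cn_minor") %in% names(seg))) "total"
            else "allele"
  }
  mode <- match.arg(mode, c("allele", "total"))
  cols <- if (mode == "allele") c("cn_major", "cn_minor") else "cn_total"
  for (cc in cols) if (!cc %in% names(seg)) seg[[cc]] <- NA_real_
  seg <- seg[, c(required, cols), with = FALSE]
  seg[, c("start", "end") := .(as.numeric(start), as.numeric(end))]
  for (cc in cols) seg[[cc]] <- as.numeric(seg[[cc]])
  validate_segments(seg, sample_id, genome, cols)
  seg[, chrom := factor(chrom, levels = genome$chroms)]
  data.table::setorder(seg, chrom, start)
  seg[, chrom := as.character(chrom)]
  if (!is.null(sex)) sex <- match.arg(sex, c("female", "male"))
  p <- structure(list(sample_id = as.character(sample_id), segments = seg,
                      mode = mode, declared_sex = sex, genome = genome),
                 class = "cn_profile")
  p$sex <- infer_sex(p)
  p
}

validate_segments <- function(seg, sample_id, genome, cn_cols) {
  bad <- setdiff(unique(seg$chrom), genome$chroms)
  if (length(bad))
    stop(sprintf("sample %s: unknown chromosome(s) %s for genome %s",
                 sample_id, paste(bad, collapse = ", "), genome$name),
         call. = FALSE)
  if (any(!is.finite(seg$start)) || any(!is.finite(seg$end)) ||
      any(seg$start < 0) || any(seg$start >= seg$end))
    stop(sprintf("sample %s: segments require 0 <= start < end", sample_id),
         call. = FALSE)
  over_end <- seg$end > genome$lengths[seg$chrom]
  if (any(over_end))
    stop(sprintf("sample %s: segment %s:%g-%g extends past the chromosome end",
                 sample_id, seg$chrom[which(over_end)[1]],
                 seg$start[which(over_end)[1]], seg$end[which(over_end)[1]]),
         call. = FALSE)
  for (cc in cn_cols) {
    v <- seg[[cc]]
    if (any(v[!is.na(v)] < 0))
      stop(sprintf("sample %s: negative copy number in %s", sample_id, cc),
           call. = FALSE)
  }
  ord <- order(match(seg$chrom, genome$chroms), seg$start)
  s <- seg[ord]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (nrow(s) > 1 && any(same & s$start[-1] < s$end[-nrow(s)])) {
    i <- which(same & s$start[-1] < s$end[-nrow(s)])[1]
    stop(sprintf("sample %s: overlapping segments on %s at %g-%g / %g-%g",
                 sample_id, s$chrom[i], s$start[i], s$end[i],
                 s$start[i + 1], s$end[i + 1]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s (%s mode, %s, genome %s): %d segments\n",
              x$sample_id, x$mode, x$sex, x$genome$name, nrow(x$segments)))
  print(x$segments, topn = 3)
  invisible(x)
}

cn_columns <- function(profile) {
  if (profile$mode == "allele") c("cn_major", "cn_minor") else "cn_total"
}

#' Construct a cohort of copy-number profiles
#'
#' @param profiles A list of [cn_profile] objects sharing one genome and
#'   one mode (mixing total-CN and allele-specific samples is rejected).
#' @return An object of class `cn_cohort`: a named list of profiles.
#' @export
cn_cohort <- function(profiles) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0,
            all(vapply(profiles, inherits, TRUE, "cn_profile")))
  modes <- unique(vapply(profiles, `[[`, "", "mode"))
  if (length(modes) > 1)
    stop("cohort mixes total-CN and allele-specific profiles", call. = FALSE)
  genomes <- unique(vapply(profiles, function(p) p$genome$name, ""))
  if (length(genomes) > 1)
    stop("cohort profiles use different genomes: ",
         paste(genomes, collapse = ", "), call. = FALSE)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicated sample ids in cohort", call. = FALSE)
  structure(stats::setNames(profiles, ids), class = "cn_cohort",
            mode = modes, genome = profiles[[1]]$genome)
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat(sprintf("<cn_cohort> %d samples (%s mode, genome %s)\n",
              length(x), attr(x, "mode"), attr(x, "genome")$name))
  invisible(x)
}

#' @export
`[.cn_cohort` <- function(x, i) {
  cn_cohort(unclass(x)[i])
}

cohort_apply <- function(cohort, fn, workers = 1L) {
  out <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(cohort, fn, mc.cores = workers)
  } else {
    lapply(cohort, fn)
  }
  out
}

# One flat segment table for a cohort (used by I/O and plotting)
cohort_table <- function(cohort) {
  data.table::rbindlist(lapply(cohort, function(p) {
    cbind(data.table::data.table(sample_id = p$sample_id), p$segments)
  }), fill = TRUE)
}
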