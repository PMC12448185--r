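# Segment-table and matrix I/O. Segment tables are TSV with a header; the
# column names and coordinate base differ between callers, so a small
# "dialect" object maps them onto the internal layout (0-based half-open,
# columns sample_id/chrom/start/end/cn_major/cn_minor/cn_total).

#' Describe the column layout of a segment table
#'
#' @param sample_id,chrom,start,end Column names in the file.
#' @param cn_major,cn_minor,cn_total Copy-number column names; set those
#'   the file does not carry to `NULL`. Files with both allele columns are
#'   read in allele mode, otherwise `cn_total` is required.
#' @param base `"zero"` for 0-based half-open input (BED-like), `"one"`
#'   for 1-based inclusive (ASCAT-like); 1-based starts are shifted down
#'   by one on read.
#' @return A `cn_dialect` list.
#' @examples
#' # ASCAT-style headers
#' segment_dialect(sample_id = "sample", chrom = "chr", start = "startpos",
#'                 end = "endpos", cn_major = "nMajor", cn_minor = "nMinor",
#'                 cn_total = NULL, base = "one")
#' @export
segment_dialect <- function(sample_id = "sample_id", chrom = "chrom",
                            start = "start", end = "end",
                            cn_major = "cn_major", cn_minor = "cn_minor",
                            cn_total = "cn_total",
                            base = c("zero", "one")) {
  structure(list(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, cn_major = cn_major, cn_minor = cn_minor,
                 cn_total = cn_total, base = match.arg(base)),
            class = "cn_dialect")
}

#' Read a cohort of copy-number profiles from a TSV segment table
#'
#' @param path TSV file with a header row.
#' @param genome A [cn_genome].
#' @param dialect A [segment_dialect()] describing the columns; the default
#'   expects the package's own layout.
#' @param sex Optional named character vector (sample id -> "female"/"male")
#'   of declared sexes; samples not named are inferred via [infer_sex()].
#' @return A [cn_cohort]. Overlapping segments within a sample, negative
#'   copy numbers and start >= end are validation errors naming the sample.
#' @export
read_segments <- function(path, genome, dialect = segment_dialect(), sex = NULL) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = dialect$chrom))
  need <- c(dialect$sample_id, dialect$chrom, dialect$start, dialect$end)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segment table lacks mapped column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  have_allele <- !is.null(dialect$cn_major) && dialect$cn_major %in% names(tab)
  have_total <- !is.null(dialect$cn_total) && dialect$cn_total %in% names(tab)
  if (!have_allele && !have_total)
    stop("segment table carries neither allele-specific nor total CN columns",
         call. = FALSE)
  out <- data.table::data.table(
    sample_id = as.character(tab[[dialect$sample_id]]),
    chrom = tab[[dialect$chrom]],
    start = as.numeric(tab[[dialect$start]]),
    end = as.numeric(tab[[dialect$end]]))
  if (dialect$base == "one") out[, start := start - 1]
  mode <- if (have_allele) "allele" else "total"
  if (have_allele) {
    out[, cn_major := as.numeric(tab[[dialect$cn_major]])]
    out[, cn_minor := if (!is.null(dialect$cn_minor) &&
                          dialect$cn_minor %in% names(tab))
                        as.numeric(tab[[dialect$cn_minor]]) else NA_real_]
  } else {
    out[, cn_total := as.numeric(tab[[dialect$cn_total]])]
  }
  ids <- unique(out$sample_id)
  profiles <- lapply(ids, function(id) {
    cn_profile(id, out[sample_id == id, -"sample_id"], genome,
               sex = if (!is.null(sex) && id %in% names(sex)) sex[[id]] else NULL,
               mode = mode)
  })
  cn_cohort(profiles)
}

#' Write a cohort back to a TSV segment table
#'
#' Inverse of [read_segments()] under the default dialect: coordinates are
#' written 0-based half-open and copy-number values are printed at full
#' precision, so read-back reproduces the cohort exactly.
#'
#' @param cohort A [cn_cohort] or single [cn_profile].
#' @param path Output TSV path.
#' @export
write_segments <- function(cohort, path) {
  if (inherits(cohort, "cn_profile")) cohort <- cn_cohort(list(cohort))
  tab <- cohort_table(cohort)
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

segment_label <- function(chrom, start, end, allele = NULL) {
  base <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  if (is.null(allele)) base else paste(base, allele, sep = ":")
}

#' Write an aggregated matrix as TSV
#'
#' One row per sample, one column per segment named `chrom:start-end`;
#' allele-specific matrices emit paired columns `chrom:start-end:major` /
#' `...:minor`. Values are printed at full precision so [read_matrix()]
#' reproduces them exactly.
#'
#' @param mat A [cn_matrix] from [aggregate_cohort()].
#' @param path Output TSV path.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "cn_matrix"))
  seg <- mat$segments
  cols <- list()
  for (al in names(mat$values)) {
    lab <- if (length(mat$values) == 1L && al == "total")
      segment_label(seg$chrom, seg$start, seg$end)
    else segment_label(seg$chrom, seg$start, seg$end, al)
    m <- mat$values[[al]]
    colnames(m) <- lab
    cols[[al]] <- m
  }
  wide <- do.call(cbind, cols)
  if (length(mat$values) == 2L) {  # interleave major/minor per segment
    n <- nrow(seg)
    wide <- wide[, as.vector(rbind(seq_len(n), n + seq_len(n))), drop = FALSE]
  }
  out <- data.table::data.table(sample_id = mat$sample_ids)
  out <- cbind(out, data.table::as.data.table(wide))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an aggregated matrix written by [write_matrix()]
#' @param path TSV path.
#' @return A [cn_matrix].
#' @export
read_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(tab[[1]])
  labs <- names(tab)[-1]
  m <- as.matrix(tab[, -1, with = FALSE])
  rownames(m) <- ids
  parts <- data.table::tstrsplit(labs, ":", fixed = TRUE)
  coords <- data.table::tstrsplit(parts[[2]], "-", fixed = TRUE)
  seg <- data.table::data.table(chrom = parts[[1]],
                                start = as.numeric(coords[[1]]),
                                end = as.numeric(coords[[2]]))
  if (length(parts) >= 3) {
    allele <- parts[[3]]
    values <- lapply(split(seq_along(labs), allele), function(ix)
      m[, ix, drop = FALSE])
    seg <- unique(seg)
  } else {
    values <- list(total = m)
  }
  new_cn_matrix(ids, seg, values, how = "unknown")
}
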