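# Region sets: sorted interval tables used for regions of interest
# (chromosomes, arms, cytobands, gene sets) and exclusion tracks.

#' Construct a region set
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`. Coordinates are 0-based half-open.
#' @param genome A [cn_genome]; regions are clipped to chromosome bounds
#'   and rows on chromosomes absent from the genome are an error.
#' @param kind A label recording provenance (`"chromosomes"`, `"arms"`,
#'   `"cytobands"`, `"custom"`, ...).
#' @param allow_overlap Gene sets may overlap; coordinate tracks may not.
#' @return A data.table of class `cn_regions`, sorted by (chrom, start).
#' @export
cn_regions <- function(regions, genome, kind = "custom", allow_overlap = FALSE) {
  r <- data.table::as.data.table(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(r)))
  if (!"name" %in% names(r))
    r[, name := sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))]
  r <- r[, .(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), name = as.character(name))]
  bad <- setdiff(unique(r$chrom), genome$chroms)
  if (length(bad))
    stop("region chromosome(s) absent from genome ", genome$name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  r[, start := pmax(start, 0)]
  r[, end := pmin(end, genome$lengths[chrom])]
  r <- r[start < end]
  data.table::setorder(r[, chrom := factor(chrom, levels = genome$chroms)],
                       chrom, start)
  r[, chrom := as.character(chrom)]
  if (!allow_overlap && nrow(r) > 1) {
    same <- r$chrom[-1] == r$chrom[-nrow(r)]
    if (any(same & r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping regions in a non-overlapping region set", call. = FALSE)
  }
  data.table::setattr(r, "class", c("cn_regions", class(r)))
  data.table::setattr(r, "kind", kind)
  data.table::setattr(r, "genome", genome$name)
  r
}

#' Load a predefined or custom region set
#'
#' Five kinds are understood: `"chromosomes"` (one region per chromosome,
#' the default elsewhere), `"arms"` and `"cytobands"` (derived from a UCSC
#' cytoBand-format file; arm = union of bands sharing the p/q prefix), and
#' custom BED files (used for COSMIC / Ensembl gene sets, which are not
#' redistributable and therefore user-supplied).
#'
#' @param kind `"chromosomes"`, `"arms"`, `"cytobands"`, or a BED file path.
#' @param genome A [cn_genome].
#' @param cytoband Path to a UCSC cytoBand.txt-style file (required for
#'   arms/cytobands): columns chrom, chromStart, chromEnd, name, gieStain.
#' @param allow_overlap Passed to [cn_regions()] for BED input.
#' @return A [cn_regions] set.
#' @export
load_region_set <- function(kind, genome, cytoband = NULL, allow_overlap = TRUE) {
  if (kind == "chromosomes") {
    return(cn_regions(data.table::data.table(
      chrom = genome$chroms, start = 0, end = unname(genome$lengths),
      name = genome$chroms), genome, kind = "chromosomes"))
  }
  if (kind %in% c("arms", "cytobands")) {
    if (is.null(cytoband))
      stop("kind '", kind, "' needs a cytoband file", call. = FALSE)
    bands <- read_cytoband(cytoband, genome)
    if (kind == "cytobands")
      return(cn_regions(bands, genome, kind = "cytobands"))
    arms <- bands[, .(start = min(start), end = max(end)),
                  by = .(chrom, arm = substr(name, 1, 1))]
    arms[, name := paste0(chrom, arm)]
    return(cn_regions(arms[, .(chrom, start, end, name)], genome, kind = "arms"))
  }
  if (file.exists(kind))
    return(read_bed(kind, genome, allow_overlap = allow_overlap))
  stop("unknown region set kind '", kind,
       "' (not a predefined name or an existing BED file)", call. = FALSE)
}

#' Read a BED3/BED4 file as a region set
#' @param path BED file (tab-separated, no header; browser/track lines and
#'   `#` comments are skipped).
#' @param genome A [cn_genome].
#' @param allow_overlap Allow overlapping intervals (gene sets).
#' @return A [cn_regions] set.
#' @export
read_bed <- function(path, genome, allow_overlap = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(cn_regions(data.table::data.table(
      chrom = character(), start = numeric(), end = numeric(),
      name = character()), genome))
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  r <- data.table::data.table(chrom = parts[[1]],
                              start = as.numeric(parts[[2]]),
                              end = as.numeric(parts[[3]]))
  if (length(parts) >= 4) r[, name := parts[[4]]]
  cn_regions(r, genome, kind = basename(path), allow_overlap = allow_overlap)
}

#' Write a region set (or segmentation) as BED4
#' @param regions A [cn_regions] or [cn_segmentation].
#' @param path Output file.
#' @export
write_bed <- function(regions, path) {
  if (inherits(regions, "cn_segmentation")) regions <- regions$regions
  out <- sprintf("%s\t%d\t%d\t%s", regions$chrom, as.integer(regions$start),
                 as.integer(regions$end), regions$name)
  writeLines(out, path)
  invisible(path)
}

#' Read a UCSC cytoBand or gap track
#'
#' Both tracks share the leading column layout chrom, chromStart, chromEnd,
#' name (cytoBand adds gieStain; gap adds size/type/bridge), so one reader
#' serves exclusion regions and arm/cytoband definitions.
#'
#' @param path Track file, plain TSV without header.
#' @param genome A [cn_genome]; rows on chromosomes absent from the genome
#'   are dropped.
#' @return data.table with columns chrom, start, end, name.
#' @export
read_cytoband <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) < 4)
    stop("expected at least 4 tab-separated columns in ", path, call. = FALSE)
  r <- data.table::data.table(chrom = parts[[1]],
                              start = as.numeric(parts[[2]]),
                              end = as.numeric(parts[[3]]),
                              name = parts[[4]])
  r <- r[chrom %in% genome$chroms]
  data.table::setorder(r[, chrom := factor(chrom, levels = genome$chroms)],
                       chrom, start)
  r[, chrom := as.character(chrom)]
  r[]
}
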