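# Cohort-consistent segmentation: a single disjoint set of genomic
# segments shared by every sample, built in four optional steps:
#   (i)  regions of interest (chromosomes, arms, cytobands, BED),
#   (ii) subtraction of exclusion regions with a fragment filter f,
#   (iii) pooling of the cohort's breakpoints and greedy merging within
#         distance m,
#   (iv) subdivision into ~s-base bins (start-anchored, centered, or
#        same-size strategies).

#' Subtract exclusion regions with a fragment filter
#'
#' Exclusion regions shorter than `filter_size` are dropped before
#' subtraction; fragments created by the subtraction that end up shorter
#' than `filter_size` are dropped afterwards. Regions the subtraction never
#' touched are kept regardless of their length.
#'
#' @param regions A [cn_regions] set of regions of interest.
#' @param exclusions A [cn_regions] set to remove (e.g. the UCSC gap track).
#' @param filter_size Minimum length `f` in bases; 0 disables both filters.
#' @return A [cn_regions] set (possibly empty).
#' @export
subtract_exclusions <- function(regions, exclusions, filter_size = 0) {
  ex <- exclusions[(exclusions$end - exclusions$start) >= filter_size, ,
                   drop = FALSE]
  pieces <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i]
    hits <- ex[ex$chrom == r$chrom & ex$start < r$end & ex$end > r$start, ,
               drop = FALSE]
    if (nrow(hits) == 0L) return(r)
    hits <- hits[order(hits$start)]
    cur <- r$start
    out <- list()
    for (j in seq_len(nrow(hits))) {
      if (hits$start[j] > cur)
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = r$chrom, start = cur, end = hits$start[j])
      cur <- max(cur, hits$end[j])
    }
    if (cur < r$end)
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = r$chrom, start = cur, end = r$end)
    if (!length(out)) return(NULL)
    frag <- data.table::rbindlist(out)
    frag <- frag[(end - start) >= filter_size]
    if (nrow(frag) == 0L) return(NULL)
    frag[, name := sprintf("%s_%d", r$name, seq_len(.N))]
    frag
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  res <- if (length(pieces)) data.table::rbindlist(pieces, use.names = TRUE)
         else data.table::data.table(chrom = character(), start = numeric(),
                                     end = numeric(), name = character())
  # rebuild as cn_regions without re-clipping (coordinates already valid)
  data.table::setattr(res, "class", c("cn_regions", class(data.table::data.table())))
  data.table::setattr(res, "kind", attr(regions, "kind"))
  data.table::setattr(res, "genome", attr(regions, "genome"))
  res
}

#' Greedy breakpoint merging
#'
#' Starting from the leftmost breakpoint, every breakpoint within `m` bases
#' of that anchor is accumulated into one cluster, which is replaced by a
#' single breakpoint at the floor of the cluster mean; the procedure
#' restarts at the leftmost not-yet-merged breakpoint. Membership is tested
#' against the anchor (inclusive, `p - anchor <= m`), not chained between
#' neighbors.
#'
#' @param positions Sorted numeric base offsets (duplicates collapsed).
#' @param m Merge distance in bases.
#' @return Strictly increasing numeric positions, never more than the input.
#' @examples
#' merge_breakpoints(c(10, 12, 30), 5)  # 11, 30
#' @export
merge_breakpoints <- function(positions, m) {
  pos <- sort(unique(as.numeric(positions)))
  if (length(pos) <= 1L || m <= 0) return(pos)
  out <- numeric(0)
  i <- 1L
  n <- length(pos)
  while (i <= n) {
    j <- i
    while (j < n && pos[j + 1L] - pos[i] <= m) j <- j + 1L
    out <- c(out, floor(mean(pos[i:j])))
    i <- j + 1L
  }
  unique(out)
}

#' Subdivide a region into fixed-width bins
#'
#' Three strategies for a region of length `L` and split size `s`:
#' * `"start"` (a): boundaries every `s` bases from the region start; a
#'   final remainder bin shorter than `s/2` is merged into its predecessor.
#' * `"centered"` (b): the remainder is split in half and padded onto both
#'   ends; end bins shorter than `s/2` are merged into their neighbors.
#' * `"same_size"` (c): all bins get the same length close to `s`. With
#'   `c` bins counting the padding bin, the region is split into `c - 1`
#'   equal bins when the padding is at most `s/2`, else into `c` bins;
#'   integer boundaries come from rounding cumulative positions, so bin
#'   lengths differ by at most one base.
#'
#' Regions shorter than `s` are returned as a single bin under every
#' strategy. Bins always tile the region exactly.
#'
#' @param region One-row data.frame (chrom, start, end) or a numeric
#'   `c(start, end)` pair.
#' @param s Split size in bases (> 0).
#' @param strategy `"start"`, `"centered"`, `"same_size"` (or `"a"`,
#'   `"b"`, `"c"`).
#' @return data.table of bins (chrom, start, end) tiling the region.
#' @export
bin_region <- function(region, s,
                       strategy = c("same_size", "start", "centered",
                                    "a", "b", "c")) {
  strategy <- match.arg(strategy)
  if (strategy %in% c("a", "b", "c"))
    strategy <- c(a = "start", b = "centered", c = "same_size")[[strategy]]
  if (is.numeric(region)) region <- data.frame(chrom = NA_character_,
                                               start = region[1], end = region[2])
  stopifnot(s > 0, nrow(region) == 1L)
  a <- as.numeric(region$start); b <- as.numeric(region$end)
  L <- b - a
  stopifnot(L > 0)
  bounds <- if (L <= s) {
    c(a, b)
  } else if (strategy == "start") {
    inner <- a + seq_len(ceiling(L / s) - 1L) * s
    r <- L %% s
    if (r > 0 && r < s / 2) inner <- inner[-length(inner)]
    c(a, inner, b)
  } else if (strategy == "centered") {
    r <- L %% s
    lp <- floor(r / 2)
    inner <- seq(a + lp, b, by = s)
    inner <- inner[inner > a & inner < b]
    if (length(inner)) {
      if (inner[1] - a < s / 2) inner <- inner[-1]
      if (length(inner) && b - inner[length(inner)] < s / 2)
        inner <- inner[-length(inner)]
    }
    c(a, inner, b)
  } else {  # same_size
    c_bins <- ceiling(L / s)
    pad <- L %% s
    n_bins <- if (pad == 0) c_bins else if (pad <= s / 2) c_bins - 1L else c_bins
    n_bins <- max(n_bins, 1L)
    # integer boundaries by rounding cumulative positions (round half up)
    c(a, a + floor(seq_len(n_bins - 1L) * L / n_bins + 0.5), b)
  }
  data.table::data.table(chrom = region$chrom,
                         start = bounds[-length(bounds)],
                         end = bounds[-1])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build a cohort-consistent segmentation
#'
#' Applies the four steps in order, each optional: regions of interest,
#' exclusion subtraction with fragment filter `filter_size`, pooling of the
#' union of all samples' breakpoints (clipped to the surviving regions and
#' merged greedily within `merge_distance` per region), and fixed-width
#' binning with `split_size` and `strategy`. The result is one disjoint,
#' sorted region list shared by every sample.
#'
#' @param regions A [cn_regions] set (step i), e.g.
#'   `load_region_set("chromosomes", genome)`.
#' @param cohort A [cn_cohort]; required only when
#'   `use_cohort_breakpoints = TRUE`. Breakpoints should come from imputed
#'   profiles so that missing data does not fabricate breaks.
#' @param exclusions Optional [cn_regions] to subtract (step ii).
#' @param filter_size Fragment filter `f` in bases for step ii.
#' @param merge_distance Merge distance `m` in bases for step iii (0 keeps
#'   every pooled breakpoint).
#' @param split_size Split size `s` in bases for step iv; 0 skips binning.
#' @param strategy Binning strategy, see [bin_region()].
#' @param use_cohort_breakpoints Enable step iii.
#' @return An object of class `cn_segmentation`: list with `regions` (a
#'   [cn_regions] table) and `params`.
#' @export
consistent_segmentation <- function(regions, cohort = NULL, exclusions = NULL,
                                    filter_size = 0, merge_distance = 0,
                                    split_size = 0,
                                    strategy = "same_size",
                                    use_cohort_breakpoints = FALSE) {
  regs <- regions
  if (!is.null(exclusions))
    regs <- subtract_exclusions(regs, exclusions, filter_size)
  if (use_cohort_breakpoints) {
    if (is.null(cohort) || length(cohort) == 0L)
      stop("use_cohort_breakpoints requires a non-empty cohort", call. = FALSE)
    bp <- data.table::rbindlist(lapply(cohort, function(p)
      data.table::rbindlist(breakpoint_positions(p, "genome"))))
    bp <- unique(bp)
    pieces <- lapply(seq_len(nrow(regs)), function(i) {
      r <- regs[i]
      inside <- sort(unique(bp$pos[bp$chrom == r$chrom &
                                   bp$pos > r$start & bp$pos < r$end]))
      cut <- merge_breakpoints(inside, merge_distance)
      cut <- cut[cut > r$start & cut < r$end]
      bounds <- c(r$start, cut, r$end)
      data.table::data.table(chrom = r$chrom, start = bounds[-length(bounds)],
                             end = bounds[-1])
    })
    regs <- as_region_table(data.table::rbindlist(pieces), regs)
  }
  if (split_size > 0) {
    pieces <- lapply(seq_len(nrow(regs)), function(i)
      bin_region(regs[i], split_size, strategy))
    regs <- as_region_table(data.table::rbindlist(pieces), regs)
  }
  out <- data.table::data.table(chrom = regs$chrom, start = regs$start,
                                end = regs$end)
  out[, name := sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))]
  structure(list(regions = out,
                 params = list(filter_size = filter_size,
                               merge_distance = merge_distance,
                               split_size = split_size, strategy = strategy,
                               source = attr(regions, "kind"),
                               use_cohort_breakpoints = use_cohort_breakpoints)),
            class = "cn_segmentation")
}

as_region_table <- function(dt, template) {
  dt[, name := sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))]
  data.table::setattr(dt, "class", c("cn_regions", class(data.table::data.table())))
  data.table::setattr(dt, "kind", attr(template, "kind"))
  data.table::setattr(dt, "genome", attr(template, "genome"))
  dt
}

#' @export
print.cn_segmentation <- function(x, ...) {
  cat(sprintf("<cn_segmentation> %d segments on %d chromosomes (f=%g, m=%g, s=%g, %s)\n",
              nrow(x$regions), length(unique(x$regions$chrom)),
              x$params$filter_size, x$params$merge_distance,
              x$params$split_size, x$params$strategy))
  invisible(x)
}
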