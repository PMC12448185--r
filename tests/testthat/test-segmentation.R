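region1 <- function(len = 100) {
  g <- cn_genome("t1", "chr1", len, NULL)
  list(g = g, r = load_region_set("chromosomes", g))
}

test_that("subtract_exclusions applies the fragment filter on both sides", {
  x <- region1(100)
  ex <- function(s, e) cn_regions(data.frame(chrom = "chr1", start = s, end = e),
                                  x$g)
  plain <- subtract_exclusions(x$r, ex(40, 60), filter_size = 0)
  expect_equal(data.frame(plain[, c("start", "end")]),
               data.frame(start = c(0, 60), end = c(40, 100)))

  # exclusion shorter than f is dropped before subtraction
  kept <- subtract_exclusions(x$r, ex(40, 45), filter_size = 10)
  expect_equal(data.frame(kept[, c("start", "end")]),
               data.frame(start = 0, end = 100))

  # fragments shorter than f are dropped after subtraction
  empty <- subtract_exclusions(x$r, ex(5, 95), filter_size = 10)
  expect_equal(nrow(empty), 0)

  # untouched regions survive even when shorter than f
  g2 <- cn_genome("t2", c("chr1", "chr2"), c(100, 8), NULL)
  r2 <- load_region_set("chromosomes", g2)
  ex2 <- cn_regions(data.frame(chrom = "chr1", start = 40, end = 60), g2)
  res <- subtract_exclusions(r2, ex2, filter_size = 10)
  expect_true(any(res$chrom == "chr2"))
})

test_that("greedy breakpoint merging follows the anchored loop", {
  expect_equal(merge_breakpoints(numeric(0), 5), numeric(0))
  expect_equal(merge_breakpoints(c(10, 12, 30), 5), c(11, 30))
  # anchor semantics: 0 captures 4 (not 8); 8 captures 12
  expect_equal(merge_breakpoints(c(0, 4, 8, 12), 5), c(2, 10))
  expect_equal(merge_breakpoints(c(7, 3, 7), 0), c(3, 7))  # m=0: dedup only
})

test_that("greedy merging equals an independent re-simulation on random sets", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    pos <- sort(sample(0:5000, n))
    m <- sample(c(0, 1, 10, 100, 500), 1)
    got <- merge_breakpoints(pos, m)
    expect_identical(got, oracle_merge_bp(pos, m))
    expect_lte(length(got), length(unique(pos)))
    expect_true(all(diff(got) > 0))
    expect_true(all(got >= min(pos) & got <= max(pos)))
  }
})

test_that("binning tiles regions exactly under all strategies", {
  expect_equal(bin_region(c(0, 20), 5, "same_size")$end, c(5, 10, 15, 20))
  # L=22, s=5: padding 2 <= 2.5 -> 4 bins of 5.5, rounded boundaries
  expect_equal(bin_region(c(0, 22), 5, "same_size")$end, c(6, 11, 17, 22))
  # L=29, s=5: padding 4 > 2.5 -> 6 bins of ~4.83
  b29 <- bin_region(c(0, 29), 5, "same_size")
  expect_equal(nrow(b29), 6)
  expect_true(all(abs((b29$end - b29$start) - 29 / 6) <= 1))
  # strategy a: remainder 2 < 2.5 merged into the last bin
  expect_equal(bin_region(c(0, 22), 5, "start")$end, c(5, 10, 15, 22))
  # strategy a: remainder 3 >= 2.5 stays its own bin
  expect_equal(bin_region(c(0, 23), 5, "start")$end, c(5, 10, 15, 20, 23))
  # strategy b: padding split across both ends and merged into neighbors
  expect_equal(bin_region(c(0, 22), 5, "centered")$end, c(6, 11, 16, 22))
  # short regions are a single bin under every strategy
  for (st in c("start", "centered", "same_size"))
    expect_equal(nrow(bin_region(c(0, 3), 5, st)), 1)
})

test_that("binning geometry holds for random regions and sizes", {
  set.seed(42)
  for (i in 1:60) {
    a <- sample(0:1000, 1)
    L <- sample(1:500, 1)
    s <- sample(c(7, 10, 33), 1)
    for (st in c("start", "centered", "same_size")) {
      b <- bin_region(c(a, a + L), s, st)
      expect_equal(b$start[1], a)
      expect_equal(b$end[nrow(b)], a + L)
      expect_true(all(b$start < b$end))
      expect_equal(b$start[-1], b$end[-nrow(b)])  # exact tiling
      if (st == "same_size") {
        lens <- b$end - b$start
        expect_lte(max(lens) - min(lens), 1)
      }
    }
  }
  # boundary cases L = q*s +- ceil(s/2) exercise the merge thresholds
  for (s in c(7, 10, 33)) for (q in 1:3) for (d in c(-1, 1)) {
    L <- q * s + d * ceiling(s / 2)
    if (L <= 0) next
    for (st in c("start", "centered", "same_size")) {
      b <- bin_region(c(0, L), s, st)
      expect_equal(sum(b$end - b$start), L)
    }
    # strict rule checks on strategy a: remainder r < s/2 merges
    b <- bin_region(c(0, L), s, "start")
    r <- L %% s
    if (L > s && r > 0) {
      last <- b$end[nrow(b)] - b$start[nrow(b)]
      if (r < s / 2) expect_equal(last, s + r) else expect_equal(last, r)
    }
  }
})

test_that("consistent segmentation chains the four optional steps", {
  g <- cn_genome("t1", c("chr1", "chr2"), c(100, 80), NULL)
  regions <- load_region_set("chromosomes", g)

  # all steps skipped: segmentation == whole chromosomes
  seg0 <- consistent_segmentation(regions)
  expect_equal(data.frame(seg0$regions[, c("chrom", "start", "end")]),
               data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                          end = c(100, 80)))

  # cohort breakpoints {10}, {12} on chr1, m=5 -> split at 11
  mk <- function(id, bp) cn_profile(id, data.frame(
    chrom = "chr1", start = c(0, bp), end = c(bp, 100),
    cn_major = c(2, 3), cn_minor = 1), g)
  cohort <- cn_cohort(list(mk("a", 10), mk("b", 12)))
  seg <- consistent_segmentation(regions, cohort = cohort, merge_distance = 5,
                                 use_cohort_breakpoints = TRUE)
  chr1 <- seg$regions[seg$regions$chrom == "chr1"]
  expect_equal(chr1$start, c(0, 11))
  expect_equal(chr1$end, c(11, 100))

  expect_error(consistent_segmentation(regions, cohort = NULL,
                                       use_cohort_breakpoints = TRUE),
               "non-empty cohort")

  # exclusion then binning: region minus center gap -> two arms -> ~s bins
  excl <- cn_regions(data.frame(chrom = "chr1", start = 40, end = 60), g)
  seg2 <- consistent_segmentation(regions, exclusions = excl,
                                  split_size = 15, strategy = "same_size")
  chr1 <- seg2$regions[seg2$regions$chrom == "chr1"]
  expect_true(all(chr1$end <= 40 | chr1$start >= 60))
  lens <- chr1$end - chr1$start
  expect_true(all(lens >= 10 & lens <= 20))  # ~s-sized bins on both arms

  # determinism: identical inputs give identical segmentations
  seg3 <- consistent_segmentation(regions, cohort = cohort, merge_distance = 5,
                                  use_cohort_breakpoints = TRUE)
  expect_identical(seg$regions, seg3$regions)
})
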