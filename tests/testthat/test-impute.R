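test_that("extension imputation splits gaps at the floor midpoint", {
  g <- cn_genome("t1", "chr1", 100, NULL)
  p <- cn_profile("s", data.frame(chrom = "chr1", start = c(10, 60),
                                  end = c(40, 90), cn_major = c(2, 3),
                                  cn_minor = c(1, 1)), g)
  imp <- impute(p, "extension")
  expect_equal(as.data.frame(imp$segments),
               data.frame(chrom = "chr1", start = c(0, 50), end = c(50, 100),
                          cn_major = c(2, 3), cn_minor = c(1, 1)))
})

test_that("fully missing chromosomes fill per method, sex-aware for diploid", {
  g <- toy_genome()
  male <- cn_profile("m", data.frame(chrom = c("chr1", "chrY"),
                                     start = c(0, 0), end = c(100e3, 20e3),
                                     cn_major = c(2, 1), cn_minor = c(1, 0)), g)
  # drop chrY to leave it fully missing but keep the declared male sex
  male_gapped <- cn_profile("m", male$segments[1], g, sex = "male")

  ext <- impute(male_gapped, "extension")
  ychr <- ext$segments[ext$segments$chrom == "chrY"]
  expect_equal(as.numeric(unlist(ychr[, c("start", "end", "cn_major", "cn_minor")])),
               c(0, 20e3, 0, 0))

  dip <- impute(male_gapped, "diploid")
  ychr <- dip$segments[dip$segments$chrom == "chrY"]
  expect_equal(as.numeric(unlist(ychr[, c("cn_major", "cn_minor")])), c(1, 0))
  xchr <- dip$segments[dip$segments$chrom == "chrX"]
  expect_equal(as.numeric(unlist(xchr[, c("cn_major", "cn_minor")])), c(1, 0))

  nul <- impute(male_gapped, "null")
  expect_true(all(nul$segments$cn_major[nul$segments$chrom != "chr1"] == 0))

  # female diploid fill: X gets (1,1), Y (0,0)
  fem <- cn_profile("f", male$segments[1], g, sex = "female")
  dipf <- impute(fem, "diploid")
  expect_equal(as.numeric(unlist(dipf$segments[chrom == "chrX", c("cn_major", "cn_minor")])),
               c(1, 1))
  expect_equal(as.numeric(unlist(dipf$segments[chrom == "chrY", c("cn_major", "cn_minor")])),
               c(0, 0))
})

test_that("already-complete profiles are unchanged by all methods", {
  g <- cn_genome("t1", c("chr1", "chr2"), c(100, 80), NULL)
  p <- cn_profile("s", data.frame(chrom = c("chr1", "chr1", "chr2"),
                                  start = c(0, 40, 0), end = c(40, 100, 80),
                                  cn_major = c(2, 3, 2), cn_minor = c(1, 1, 2)), g)
  for (m in c("extension", "diploid", "null"))
    expect_equal(impute(p, m)$segments, p$segments)
})

test_that("merge_equal_neighbors joins only abutting identical-CN segments", {
  g <- cn_genome("t1", "chr1", 100, NULL)
  p <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 10),
                                  end = c(10, 20), cn_major = 2, cn_minor = 1), g)
  m <- merge_equal_neighbors(p)
  expect_equal(as.numeric(unlist(m$segments[, c("start", "end")])), c(0, 20))

  # minor differs: no merge
  p2 <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 10),
                                   end = c(10, 20), cn_major = 2,
                                   cn_minor = c(1, 0)), g)
  expect_equal(nrow(merge_equal_neighbors(p2)$segments), 2)

  # NA matches NA; fractional values merge only when bit-equal
  p3 <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 10, 20),
                                   end = c(10, 20, 30),
                                   cn_major = c(1.5, 1.5, 1.5 + 1e-12),
                                   cn_minor = NA_real_), g)
  expect_equal(nrow(merge_equal_neighbors(p3)$segments), 2)
})

test_that("merging preserves the per-base CN function on random profiles", {
  set.seed(21)
  g <- micro_genome()
  for (i in 1:5) {
    p <- rand_profile(g, "r", seg_size = 60, p_gap = 0.2)
    m <- merge_equal_neighbors(p)
    expect_true(nrow(m$segments) <= nrow(p$segments))
    expect_identical(expand_profile(m), expand_profile(p))
  }
})

test_that("imputation matches the per-base oracle and its invariants", {
  set.seed(22)
  g <- micro_genome()
  for (i in 1:10) {
    sex <- sample(c("male", "female", NA), 1)
    p <- rand_profile(g, "r", sex = if (is.na(sex)) NULL else sex)
    before <- expand_profile(p)
    for (method in c("extension", "diploid", "null")) {
      imp <- expect_matches_oracle_impute(p, method)
      # conservation: originally covered bases keep their CN
      after <- expand_profile(imp)
      for (ch in g$chroms) {
        cov <- !is.na(before[[ch]]$cn_major) | !is.na(before[[ch]]$cn_minor)
        expect_identical(after[[ch]]$cn_major[cov], before[[ch]]$cn_major[cov])
        expect_identical(after[[ch]]$cn_minor[cov], before[[ch]]$cn_minor[cov])
      }
      # idempotence and full coverage
      expect_equal(impute(imp, method)$segments, imp$segments)
      expect_equal(unname(cn_coverage(imp, "genome")["mono"]), 1)
    }
  }
})

test_that("empty profiles impute to all-zero genomes under extension", {
  g <- toy_genome()
  p <- cn_profile("e", data.frame(chrom = "chr1", start = 0, end = 1,
                                  cn_major = NA_real_, cn_minor = NA_real_), g)
  imp <- impute(p, "extension")
  expect_equal(nrow(imp$segments), length(g$chroms))
  expect_true(all(imp$segments$cn_major == 0))
  expect_true(all(imp$segments$end - imp$segments$start ==
                    unname(g$lengths[imp$segments$chrom])))
})
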