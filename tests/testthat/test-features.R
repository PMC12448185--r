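test_that("hand-worked feature values reproduce", {
  g <- cn_genome("t1", "chr1", 100, NULL)
  # half the chromosome covered on both alleles
  p <- cn_profile("s", data.frame(chrom = "chr1", start = 0, end = 50,
                                  cn_major = 2, cn_minor = 2), g)
  expect_equal(cn_coverage(p, "genome"), c(mono = 0.5, bi = 0.5))
  expect_equal(allelic_imbalance(p, "genome"), 0)

  # a sample with no minor-allele values anywhere: biallelic coverage 0
  p2 <- cn_profile("s2", data.frame(chrom = "chr1", start = c(0, 60),
                                    end = c(40, 100), cn_major = c(2, 3),
                                    cn_minor = NA_real_), g)
  cov <- cn_coverage(p2, "genome")
  expect_equal(unname(cov["bi"]), 0)
  expect_equal(unname(cov["mono"]), 0.8)

  # 10% of the scope at (3, 1): GnD 0.10
  p3 <- cn_profile("s3", data.frame(chrom = "chr1", start = c(0, 10),
                                    end = c(10, 100),
                                    cn_major = c(3, 1), cn_minor = 1), g)
  expect_equal(genome_not_diploid(p3, "genome"), 0.10)
  # 20% at (1, 0): hemi 0.2, nulli 0
  p3b <- cn_profile("s3b", data.frame(chrom = "chr1", start = c(0, 20),
                                      end = c(20, 100),
                                      cn_major = c(1, 2), cn_minor = c(0, 1)), g)
  expect_equal(loh(p3b, "genome"), c(hemi = 0.2, nulli = 0))
  expect_equal(loh(cn_profile("ok", data.frame(chrom = "chr1", start = 0,
                                               end = 100, cn_major = 2,
                                               cn_minor = 1), g), "genome"),
               c(hemi = 0, nulli = 0))

  # AI: half (2,2), half (3,1)
  p4 <- cn_profile("s4", data.frame(chrom = "chr1", start = c(0, 50),
                                    end = c(50, 100), cn_major = c(2, 3),
                                    cn_minor = c(2, 1)), g)
  expect_equal(allelic_imbalance(p4, "genome"), 0.5)
})

test_that("sex-aware expectations: normal male X and female Y are not aberrant", {
  g <- toy_genome()
  male <- cn_profile("m", data.frame(
    chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"), start = 0,
    end = unname(g$lengths), cn_major = 1, cn_minor = c(1, 1, 1, 0, 0)), g,
    sex = "male")
  expect_equal(genome_not_diploid(male, "genome"), 0)
  expect_equal(genome_not_diploid(male, "sex"), 0)
  expect_equal(loh(male, "genome"), c(hemi = 0, nulli = 0))

  fem <- cn_profile("f", data.frame(
    chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"), start = 0,
    end = unname(g$lengths), cn_major = c(1, 1, 1, 1, 0),
    cn_minor = c(1, 1, 1, 1, 0)), g, sex = "female")
  expect_equal(genome_not_diploid(fem, "genome"), 0)
  expect_equal(loh(fem, "genome"), c(hemi = 0, nulli = 0))

  # male X at (1,0) contributes nothing to GnD
  expect_equal(genome_not_diploid(male, "autosomes"), 0)
})

test_that("breakpoint counts separate alleles and pool shared positions", {
  g <- cn_genome("t1", "chr1", 100, NULL)
  # major changes at 10; minor changes at 10 and 20
  p <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 10, 20),
                                  end = c(10, 20, 100),
                                  cn_major = c(2, 3, 3),
                                  cn_minor = c(1, 0, 1)), g)
  bp <- breakpoint_counts(p, "genome")
  expect_equal(bp$total, c(major = 1L, minor = 2L, total = 2L))
  expect_equal(breakpoint_step(p, "genome"), mean(c(1, 1, 1)))

  single <- cn_profile("s", data.frame(chrom = "chr1", start = 0, end = 100,
                                       cn_major = 2, cn_minor = 1), g)
  expect_equal(unname(breakpoint_counts(single, "genome")$total["total"]), 0L)
  expect_true(is.na(breakpoint_step(single, "genome")))

  # splitting a segment without changing CN adds no breakpoints
  split <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 50),
                                      end = c(50, 100), cn_major = 2,
                                      cn_minor = 1), g)
  expect_equal(breakpoint_counts(split, "genome")$total,
               breakpoint_counts(single, "genome")$total)

  # jumps 2->3 and 3->1 give mean step 1.5; single jump 2->4 gives 2
  p5 <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 40, 70),
                                   end = c(40, 70, 100),
                                   cn_major = c(2, 3, 1), cn_minor = 1), g)
  expect_equal(breakpoint_step(p5, "genome"), 1.5)
  p6 <- cn_profile("s", data.frame(chrom = "chr1", start = c(0, 50),
                                   end = c(50, 100), cn_major = c(2, 4),
                                   cn_minor = 1), g)
  expect_equal(breakpoint_step(p6, "genome"), 2)
})

test_that("all six features match the per-base oracle across scopes and sexes", {
  set.seed(31)
  g <- micro_genome()
  for (i in 1:20) {
    sex <- sample(c("male", "female"), 1)
    p <- rand_profile(g, "r", sex = sex)
    for (sc in c("autosomes", "sex", "genome")) {
      want <- oracle_features(p, sc)
      expect_equal(cn_coverage(p, sc), want$coverage, tolerance = 1e-12)
      expect_equal(genome_not_diploid(p, sc), want$gnd, tolerance = 1e-12)
      expect_equal(loh(p, sc), want$loh, tolerance = 1e-12)
      expect_equal(allelic_imbalance(p, sc), want$ai, tolerance = 1e-12)
      got_bp <- breakpoint_counts(p, sc)$total
      expect_equal(unname(got_bp), unname(want$breakpoints))
      expect_equal(breakpoint_step(p, sc), want$breakpoint_step,
                   tolerance = 1e-12)
    }
  }
})

test_that("scope numerators and denominators are additive", {
  set.seed(32)
  g <- micro_genome()
  for (i in 1:5) {
    p <- rand_profile(g, "r", sex = sample(c("male", "female"), 1))
    len <- vapply(c("autosomes", "sex", "genome"), function(sc)
      sum(g$lengths[scope_chroms(g, sc, p$sex)]), 0)
    expect_equal(len[["genome"]], len[["autosomes"]] + len[["sex"]])
    for (feat in list(function(q, s) cn_coverage(q, s)[["mono"]],
                      genome_not_diploid,
                      function(q, s) loh(q, s)[["hemi"]])) {
      parts <- feat(p, "autosomes") * len[["autosomes"]] +
        feat(p, "sex") * len[["sex"]]
      expect_equal(feat(p, "genome") * len[["genome"]], parts,
                   tolerance = 1e-9)
    }
  }
})

test_that("total-CN mode GnD is a lower bound of the allele-specific value", {
  set.seed(33)
  g <- micro_genome()
  for (i in 1:5) {
    p <- rand_profile(g, "r", p_na_minor = 0)
    tot <- p$segments[, .(chrom, start, end,
                          cn_total = cn_major + cn_minor)]
    pt <- cn_profile(p$sample_id, tot, g, sex = p$sex)
    expect_lte(genome_not_diploid(pt, "genome"),
               genome_not_diploid(p, "genome") + 1e-12)
    # total mode: AI and hemizygous LoH are not computable
    expect_true(is.na(allelic_imbalance(pt, "genome")))
    expect_true(is.na(loh(pt, "genome")[["hemi"]]))
  }
})

test_that("cn_features emits one row per sample and scope", {
  set.seed(34)
  g <- micro_genome()
  cohort <- cn_cohort(lapply(1:3, function(i) rand_profile(g, paste0("s", i))))
  f <- cn_features(cohort)
  expect_equal(nrow(f), 9)
  expect_true(all(f$coverage_bi <= f$coverage_mono + 1e-12))
  expect_true(all(f$loh_nulli <= f$loh_hemi + 1e-12))
  expect_true(all(f$gnd >= 0 & f$gnd <= 1))
  # parallel execution does not change results
  expect_equal(cn_features(cohort, workers = 2), f)
})
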