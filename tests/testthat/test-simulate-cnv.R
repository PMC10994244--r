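test_that("pure diploid profile with no dispersion gives unit ratios", {
  segs <- tibble::tibble(chrom = "chr1", start = 0, end = 3e6, copies = 2)
  tr <- cn_truth_profile(segs, purity = 1, mean_depth = 100, dispersion = 0)
  bins <- simulate_offtarget_counts(tr, 30000, seed = 1)
  expect_true(all(bins$expected_ratio == 1))
  # Poisson(100) counts: sample mean close to 100
  expect_lt(abs(mean(bins$count) - 100), 5)
})

test_that("half-purity gain segment has the expected ratio 1.5", {
  # tumour ploidy 2 with one 4-copy segment; at purity 0.5 the mixture
  # average is also 2, so r = (4*0.5 + 2*0.5)/2 = 1.5 there
  segs <- tibble::tibble(
    chrom = "chr1", start = (0:4) * 1e6, end = (1:5) * 1e6,
    copies = c(4, 2, 2, 2, 0)
  )
  tr <- cn_truth_profile(segs, purity = 0.5, mean_depth = 100, dispersion = 0)
  expect_equal(tr$ploidy_tumour, 2)
  bins <- simulate_offtarget_counts(tr, 30000, seed = 2)
  expect_equal(unique(bins$expected_ratio[bins$copies == 4]), 1.5)
  expect_equal(unique(bins$expected_ratio[bins$copies == 2]), 1)
})

test_that("segment gaps are rejected", {
  segs <- tibble::tibble(chrom = "chr1", start = c(0, 2e6), end = c(1e6, 3e6),
                         copies = c(2, 3))
  expect_error(cn_truth_profile(segs, purity = 0.8), "gaps")
})

test_that("the generator is a pure function of its seed (byte-identical TSV)", {
  tr <- toy_cn_truth()
  b1 <- simulate_offtarget_counts(tr, 30000, seed = 7)
  b2 <- simulate_offtarget_counts(tr, 30000, seed = 7)
  expect_identical(b1, b2)
  f1 <- tempfile(); f2 <- tempfile()
  export_bins(b1, f1); export_bins(b2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  b3 <- simulate_offtarget_counts(tr, 30000, seed = 8)
  expect_false(identical(b1$count, b3$count))
})

test_that("empirical bin means converge to mean_depth * r", {
  segs <- tibble::tibble(chrom = "chr1", start = c(0, 1.5e8),
                         end = c(1.5e8, 3e8), copies = c(2, 4))
  tr <- cn_truth_profile(segs, purity = 1, mean_depth = 100, dispersion = 0.05)
  bins <- simulate_offtarget_counts(tr, 30000, seed = 42) # 10,000 bins
  expect_equal(nrow(bins), 10000)
  for (cp in c(2, 4)) {
    sub <- bins[bins$copies == cp, ]
    mu <- 100 * unique(sub$expected_ratio)
    expect_lt(abs(mean(sub$count) - mu) / mu, 0.02)
  }
})

test_that("spot-table generator covers the three classes and is seeded", {
  one <- simulate_spot_table(c(A = 1, L = 1, H = 1), seed = 3)
  expect_equal(nrow(one), 3)
  expect_setequal(one$true_class, c("A", "L", "H"))
  # true ratios strictly inside the class intervals
  tab <- simulate_spot_table(c(A = 30, L = 30, H = 30), seed = 4)
  r <- tab$true_ratio
  expect_true(all(r[tab$true_class == "A"] < 0.025))
  expect_true(all(r[tab$true_class == "L"] >= 0.025 & r[tab$true_class == "L"] <= 0.5))
  expect_true(all(r[tab$true_class == "H"] > 0.5))
  expect_identical(tab, simulate_spot_table(c(A = 30, L = 30, H = 30), seed = 4))
  # derived volumes reproduce the intended ratio
  expect_equal(tab$spot3_volume / tab$spot2_volume, tab$true_ratio)
})

test_that("cohort censoring share rises with the censoring rate", {
  shares <- sapply(c(0.01, 0.05, 0.25), function(cr) {
    mean(sapply(1:10, function(s) {
      ch <- simulate_cohort(c(a = 60, b = 60), c(a = 0.08, b = 0.08),
                            censor_rate = cr, seed = 100 + s)
      mean(ch$survival$event == 0)
    }))
  })
  expect_true(all(diff(shares) > 0))
})

test_that("cohort expression matrix hits the requested CP20M means", {
  em <- tibble::tibble(gene = c("CDKN2A", "CDKN2A", "CCNE1", "CCNE1"),
                       group = c("a", "b", "a", "b"),
                       mean_cp20m = c(1500, 50, 100, 400))
  ch <- simulate_cohort(c(a = 200, b = 200), c(a = 0.05, b = 0.05),
                        censor_rate = 0.02, expression_means = em, seed = 9)
  expect_equal(unname(colSums(as.matrix(ch$expression[, -1]))),
               rep(2e7, 400))
  cp <- cp20m(ch$expression)
  a_cols <- ch$survival$sample_id[ch$survival$group == "a"]
  cdkn2a_a <- as.numeric(cp[match("CDKN2A", cp$gene), a_cols])
  expect_lt(abs(mean(cdkn2a_a) - 1500) / 1500, 0.05)
})
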