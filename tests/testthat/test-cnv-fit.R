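test_that("exact integer ratios fit with zero distance at the true grid point", {
  sg <- tibble::tibble(chrom = "chr1", start = 0, end = 1,
                       n_bins = c(10L, 10L, 10L),
                       mean_ratio = c(0.5, 1.0, 1.5))
  fit <- fit_purity_ploidy(sg)
  expect_equal(fit$distance, 0)
  expect_equal(fit$rho, 1)
  expect_equal(fit$psi, 2)
  expect_equal(fit$segments$n_t, c(1, 2, 3))
  # a lattice of equivalent exact solutions exists (e.g. psi doubled):
  # the degeneracy flag must be raised
  expect_true(fit$degenerate)
})

test_that("the vectorized distance surface equals a naive triple loop bitwise", {
  set.seed(17)
  psi <- seq(1.5, 5, by = 0.1)
  rho <- seq(0.2, 1, by = 0.1)
  for (rep in 1:3) {
    r <- runif(6, 0.3, 2)
    w <- rep(1, 6)
    fit <- fit_purity_ploidy(
      tibble::tibble(mean_ratio = r, n_bins = 1L), psi = psi, rho = rho)
    expect_identical(fit$surface, naive_grid_surface(r, w, psi, rho))
  }
})

test_that("the fit is invariant to segment order and honours length weighting", {
  set.seed(23)
  r <- runif(5, 0.4, 1.8)
  sg <- tibble::tibble(mean_ratio = r, n_bins = c(50L, 3L, 40L, 8L, 60L))
  f1 <- fit_purity_ploidy(sg)
  f2 <- fit_purity_ploidy(sg[sample(5), ])
  expect_equal(f1$rho, f2$rho)
  expect_equal(f1$psi, f2$psi)
  expect_equal(f1$distance, f2$distance)
  fw <- fit_purity_ploidy(sg, weight_by_length = TRUE)
  expect_true(all(fw$surface >= 0))
  expect_equal(fw$surface[1, 1],
               naive_grid_surface(r, sg$n_bins, fw$psi_grid, fw$rho_grid)[1, 1])
})

test_that("forward simulation then copy assignment inverts exactly", {
  rho <- 0.7; psi <- 2.5 # both grid-representable
  n_t <- c(1, 2, 3, 5)
  r <- (n_t * rho + 2 * (1 - rho)) / psi
  sg <- tibble::tibble(mean_ratio = r, n_bins = 10L)
  back <- assign_copies(sg, rho, psi)
  expect_equal(back$n_t, n_t, tolerance = 1e-12)
  expect_equal(back$copies, n_t)
  expect_equal(back$residual, rep(0, 4), tolerance = 1e-12)
  fit <- fit_purity_ploidy(sg)
  expect_equal(fit$distance, 0, tolerance = 1e-12)
})

test_that("negative real-valued copies floor at zero with residual recorded", {
  sg <- tibble::tibble(mean_ratio = 0.05, n_bins = 5L)
  out <- assign_copies(sg, rho = 0.9, psi = 2)
  expect_lt(out$n_t, 0)
  expect_equal(out$copies, 0)
  expect_gt(out$residual, 0)
})

test_that("a single-state profile raises the degeneracy flag", {
  sg <- tibble::tibble(mean_ratio = 1, n_bins = 100L)
  fit <- fit_purity_ploidy(sg)
  expect_true(fit$degenerate)
})

test_that("parameter recovery from a noisy 4-state simulation", {
  tr <- toy_cn_truth(purity = 0.7)
  bt <- bin_track(simulate_offtarget_counts(tr, 30000, seed = 99))
  sg <- segment_cbs(bt, seed = 1)
  fit <- fit_purity_ploidy(sg)
  expect_lt(abs(fit$rho - 0.7), 0.02)
  expect_lt(abs(fit$ploidy_tumour - tr$ploidy_tumour), 0.05)
  expect_false(fit$degenerate)
})

test_that("exon copy ratios divide centre-base depth by the reference", {
  # exon A covered by 8 reads at its centre, exon B by 4
  reads <- tibble::tibble(
    chrom = "chrX",
    pos = c(rep(950, 8), rep(4950, 4)),
    mapq = 60, cigar = "100M"
  )
  sam <- write_test_sam(reads, c(chrX = 10000))
  targets <- tibble::tibble(chrom = "chrX", start = c(900, 4900),
                            end = c(1100, 5100), name = c("exA", "exB"))
  ref <- tibble::tibble(name = c("exA", "exB"), count = c(4, 4))
  out <- exon_copy_ratio(sam, targets, ref)
  expect_equal(out$ratio, c(2, 1))
  # identity when reference equals the sample
  ref2 <- tibble::tibble(name = c("exA", "exB"), count = c(8, 4))
  expect_equal(exon_copy_ratio(sam, targets, ref2)$ratio, c(1, 1))
  # zero reference count masks the ratio with a warning
  ref3 <- tibble::tibble(name = c("exA", "exB"), count = c(0, 4))
  expect_warning(out3 <- exon_copy_ratio(sam, targets, ref3), "zero")
  expect_true(is.na(out3$ratio[1]))
})
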