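canonical_iso <- function(model) list(list(exons = model$exons$rank,
                                           fraction = 1))

test_that("fully canonical reads give ratio exactly 1 for informative exons", {
  m <- toy_exon_model()
  sim <- simulate_spliced_reads(m, canonical_iso(m), n_reads = 400, seed = 1)
  expect_true(all(sim$truth$true_ratio == 1))
  sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
  out <- compute_splice_ratio(sam, m, min_reads = 10)
  informative <- !is.na(out$ratio)
  expect_true(any(informative))
  expect_true(all(out$ratio[informative] == 1))
})

test_that("expected/informative arithmetic is exact on a hand-built SAM", {
  m <- exon_model(tibble::tibble(start = c(1000, 2000), end = c(1199, 2199)),
                  chrom = "chrT", strand = "+", read_length = 97)
  # an adjacent exon is always reachable; intron starts are never expected
  expect_equal(expected_upstream(m)$min_rank, c(1, 1))
  # 9 reads start inside exon 2; 3 start in the intron and run into exon 2
  reads <- tibble::tibble(
    chrom = "chrT",
    pos = c(rep(2010, 9), rep(1950, 3)),
    mapq = 60, cigar = "97M"
  )
  sam <- write_test_sam(reads, c(chrT = 10000))
  out <- compute_splice_ratio(sam, m, min_reads = 10)
  expect_equal(out$informative_reads[2], 12)
  expect_equal(out$expected_reads[2], 9)
  expect_equal(out$ratio[2], 0.75)
})

test_that("exons with fewer than min_reads informative reads are masked", {
  m <- toy_exon_model()
  sim <- simulate_spliced_reads(m, canonical_iso(m), n_reads = 5, seed = 2)
  sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
  out <- compute_splice_ratio(sam, m, min_reads = 10)
  expect_true(all(is.na(out$ratio)))
  expect_true(all(out$informative_reads < 10))
})

test_that("an exon-skipping mixture matches the enumeration oracle", {
  m <- toy_exon_model() # skipping the 150-nt exon 2 is detectable at exon 3
  iso <- list(list(exons = c(1, 2, 3, 4), fraction = 0.7),
              list(exons = c(1, 3, 4), fraction = 0.3))
  truth <- splice_truth(m, iso)
  expect_lt(truth$true_ratio[3], 1) # the skip depresses exon 3
  expect_equal(truth$true_ratio[1], 1)
  sim <- simulate_spliced_reads(m, iso, n_reads = 2000, seed = 3)
  sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
  out <- compute_splice_ratio(sam, m, min_reads = 10)
  for (k in which(!is.na(out$ratio))) {
    p <- truth$true_ratio[k]
    se <- sqrt(p * (1 - p) / out$informative_reads[k])
    expect_lt(abs(out$ratio[k] - p), 3 * se + 1e-9)
  }
})

test_that("emitted SAM round-trips: reader tallies equal direct read classification", {
  m <- toy_exon_model()
  iso <- list(list(exons = c(1, 2, 3, 4), fraction = 0.6),
              list(exons = c(1, 3, 4), fraction = 0.4))
  sim <- simulate_spliced_reads(m, iso, n_reads = 300, seed = 8)
  sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
  out <- compute_splice_ratio(sam, m, min_reads = 10)
  # reclassify every simulated read with the package's own rules applied to
  # the pre-SAM record (genomic blocks recovered from the CIGAR)
  sets <- expected_upstream(m)
  inf <- integer(4); exp_ <- integer(4)
  for (i in seq_len(nrow(sim$reads))) {
    ops <- regmatches(sim$reads$cigar[i],
                      gregexpr("\\d+[MN]", sim$reads$cigar[i]))[[1]]
    lens <- as.integer(sub("[MN]", "", ops))
    types <- sub("\\d+", "", ops)
    pos <- sim$reads$pos[i]
    blocks <- NULL
    for (b in seq_along(ops)) {
      if (types[b] == "M") blocks <- rbind(blocks, c(pos, pos + lens[b] - 1))
      pos <- pos + lens[b]
    }
    start5p <- if (m$strand == "+") blocks[1, 1] else blocks[nrow(blocks), 2]
    cls <- mesoprofiler:::classify_read_against_exons(m, sets, blocks, start5p)
    inf <- inf + cls$informative
    exp_ <- exp_ + cls$expected
  }
  expect_equal(out$informative_reads, inf)
  expect_equal(out$expected_reads, exp_)
})

test_that("expected reads never exceed informative reads and ratios stay in [0,1]", {
  m <- toy_exon_model()
  iso <- list(list(exons = c(1, 2, 4), fraction = 0.5),
              list(exons = c(2, 3, 4), fraction = 0.5))
  sim <- simulate_spliced_reads(m, iso, n_reads = 500, seed = 11)
  sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
  out <- compute_splice_ratio(sam, m, min_reads = 1)
  expect_true(all(out$expected_reads <= out$informative_reads))
  expect_true(all(out$ratio >= 0 & out$ratio <= 1, na.rm = TRUE))
  expect_equal(sum(sim$truth$informative_weight >= sim$truth$expected_weight), 4)
})

test_that("noncanonical junction fraction is 0 for canonical reads and matches the oracle", {
  m <- toy_exon_model()
  sim <- simulate_spliced_reads(m, canonical_iso(m), n_reads = 300, seed = 4)
  sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
  expect_equal(noncanonical_junction_fraction(sam, m)$fraction, 0)

  iso <- list(list(exons = c(1, 2, 3, 4), fraction = 0.7),
              list(exons = c(1, 3, 4), fraction = 0.3))
  sim2 <- simulate_spliced_reads(m, iso, n_reads = 4000, seed = 5)
  sam2 <- write_sam(sim2$reads, sim2$chrom_sizes, tempfile(fileext = ".sam"))
  obs <- noncanonical_junction_fraction(sam2, m)
  # enumeration oracle: expected share of gaps that fail to match an intron
  gap_w <- c(total = 0, noncanon = 0)
  for (is in iso) {
    L <- sum(m$exons$length[is$exons])
    npl <- L - m$read_length + 1
    for (p in seq_len(npl)) {
      b <- mesoprofiler:::spliced_read_blocks(m, is$exons, p, m$read_length)
      if (nrow(b$blocks) < 2) next
      for (g in seq_len(nrow(b$blocks) - 1)) {
        gs <- b$blocks[g, 2] + 1; ge <- b$blocks[g + 1, 1] - 1
        canon <- any(m$introns$start == gs & m$introns$end == ge)
        gap_w["total"] <- gap_w["total"] + is$fraction / npl
        if (!canon) gap_w["noncanon"] <- gap_w["noncanon"] + is$fraction / npl
      }
    }
  }
  p <- gap_w[["noncanon"]] / gap_w[["total"]]
  se <- sqrt(p * (1 - p) / obs$total_gaps)
  expect_lt(abs(obs$fraction - p), 3 * se)
  # ungapped alignments contribute nothing
  reads <- tibble::tibble(chrom = "chrT", pos = 1000, mapq = 60, cigar = "97M")
  sam3 <- write_test_sam(reads, c(chrT = 10000))
  expect_equal(noncanonical_junction_fraction(sam3, m)$total_gaps, 0)
})

test_that("matrix assembly preserves the NA mask and rejects duplicates", {
  m <- toy_exon_model()
  sims <- lapply(c(2000, 40, 5), function(n) {
    sim <- simulate_spliced_reads(m, canonical_iso(m), n_reads = n,
                                  seed = n + 1)
    sam <- write_sam(sim$reads, sim$chrom_sizes, tempfile(fileext = ".sam"))
    compute_splice_ratio(sam, m, min_reads = 10)
  })
  names(sims) <- c("deep", "mid", "shallow")
  mat <- assemble_splice_matrix(sims)
  expect_equal(ncol(mat), 3 + 3)
  counts <- attr(mat, "informative_reads")
  expect_equal(is.na(as.matrix(mat[, names(sims)])), counts < 10,
               ignore_attr = TRUE)
  expect_error(assemble_splice_matrix(setNames(sims, c("a", "a", "b"))),
               "uniquely")
  expect_equal(nrow(assemble_splice_matrix(list())), 0)
})
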