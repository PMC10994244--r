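# Shared fixtures, all built in code at test time.

# Truth profile on one chromosome: 500 bins of 30 kb in 10 segments with
# copy states {0..4}, including homozygous deletions (the CDKN2A-like state
# that anchors the purity/ploidy fit); tumour ploidy 2.0.
toy_cn_truth <- function(purity = 0.7, mean_depth = 200, dispersion = 0.05) {
  len <- rep(50, 10) * 30000
  st <- cumsum(c(0, head(len, -1)))
  segs <- tibble::tibble(
    chrom = "chr1",
    start = st,
    end = st + len,
    copies = c(2, 4, 0, 3, 1, 4, 2, 0, 3, 1)
  )
  cn_truth_profile(segs, purity = purity, mean_depth = mean_depth,
                   dispersion = dispersion)
}

# Four-exon gene where exon 2 (150 nt) blocks 97-nt reads from reaching
# exon 1, so skipping exon 2 depresses the ratio of exon 3.
toy_exon_model <- function(strand = "+", read_length = 97) {
  exon_model(
    tibble::tibble(start = c(1000, 2000, 5000, 8000),
                   end = c(1199, 2149, 5029, 8099)),
    chrom = "chrT", strand = strand, gene_id = "TOY",
    read_length = read_length
  )
}

# Hand-written SAM file from (chrom, pos, mapq, cigar) rows.
write_test_sam <- function(reads, chrom_sizes, path = tempfile(fileext = ".sam")) {
  reads$qname <- sprintf("q%04d", seq_len(nrow(reads)))
  if (!"flag" %in% names(reads)) reads$flag <- 0L
  write_sam(reads, chrom_sizes, path)
  path
}

# A minimal GTF for gene G1: three exons on '+', the middle one annotated
# twice with overlapping variants, plus an unrelated gene G2.
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  attr1 <- 'gene_id "G1"; transcript_id "T1";'
  attr2 <- 'gene_id "G2"; transcript_id "T2";'
  rows <- c(
    paste("chrT", "test", "exon", 1000, 1199, ".", "+", ".", attr1, sep = "\t"),
    paste("chrT", "test", "exon", 2000, 2100, ".", "+", ".", attr1, sep = "\t"),
    paste("chrT", "test", "exon", 2050, 2149, ".", "+", ".", attr1, sep = "\t"),
    paste("chrT", "test", "exon", 5000, 5029, ".", "+", ".", attr1, sep = "\t"),
    paste("chrT", "test", "exon", 9000, 9100, ".", "-", ".", attr2, sep = "\t")
  )
  writeLines(rows, path)
  path
}

# Brute-force CBS arc statistic search, independent of the C++ kernel.
brute_best_arc <- function(x, min_width = 2) {
  n <- length(x)
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    k <- j - i
    if (k < min_width || n - k < min_width) next
    arc <- mean(x[(i + 1):j])
    rest <- mean(x[-((i + 1):j)])
    s <- abs(arc - rest) * sqrt(k * (n - k) / n)
    if (s > best) { best <- s; bi <- i; bj <- j }
  }
  list(stat = best, i = bi, j = bj)
}

# Naive triple-loop recomputation of the purity/ploidy distance surface.
naive_grid_surface <- function(r, w, psi, rho) {
  D <- matrix(0, length(psi), length(rho))
  for (i in seq_along(psi)) for (j in seq_along(rho)) {
    d <- 0
    for (s in seq_along(r)) {
      nt <- (psi[i] * r[s] - 2 * (1 - rho[j])) / rho[j]
      d <- d + abs(nt - pmax(round(nt), 0)) * w[s]
    }
    D[i, j] <- d
  }
  D
}

# Build a bin_track directly from a log2-ratio signal (for segmentation
# tests where the counts themselves are irrelevant).
track_from_log2 <- function(x, chrom = "chr1", bin_size = 30000) {
  tb <- tibble::tibble(
    chrom = chrom,
    start = (seq_along(x) - 1L) * bin_size,
    end = seq_along(x) * bin_size,
    count = NA_integer_,
    masked = FALSE,
    ratio = 2^x,
    log2_ratio = x
  )
  class(tb) <- c("bin_track", class(tb))
  tb
}
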