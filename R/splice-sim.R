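# Map a spliced-coordinate read [p, p + rl - 1] on an isoform (exon ranks in
# transcription order) to genomic M blocks, the SAM record (pos + CIGAR) and
# the 5' genomic start. Returns NULL if the read does not fit the isoform.
spliced_read_blocks <- function(model, ranks, p, rl) {
  ex <- model$exons[match(ranks, model$exons$rank), ]
  len <- ex$length
  L <- sum(len)
  if (p < 1 || p + rl - 1 > L) return(NULL)
  cl <- c(0, cumsum(len))
  lo <- p; hi <- p + rl - 1
  blocks <- list()
  for (i in seq_along(ranks)) {
    a <- max(lo, cl[i] + 1); b <- min(hi, cl[i + 1])
    if (a > b) next
    off_a <- a - cl[i]; off_b <- b - cl[i] # 1-based offsets within exon i
    if (model$strand == "+") {
      gs <- ex$start[i] + off_a - 1L; ge <- ex$start[i] + off_b - 1L
    } else {
      gs <- ex$end[i] - off_b + 1L; ge <- ex$end[i] - off_a + 1L
    }
    blocks[[length(blocks) + 1]] <- c(gs, ge)
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]
  widths <- m[, 2] - m[, 1] + 1L
  cigar <- paste0(widths[1], "M")
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      gap <- m[i, 1] - m[i - 1, 2] - 1L
      cigar <- paste0(cigar, gap, "N", widths[i], "M")
    }
  }
  start5p <- if (model$strand == "+") m[1, 1] else m[nrow(m), 2]
  list(pos = m[1, 1], cigar = cigar, blocks = m, start5p = start5p)
}

# Classify one placed read against every exon: does any aligned block overlap
# the exon (informative), and is its 5' start inside the exon's expected set
# or the anchor (expected)?
classify_read_against_exons <- function(model, sets, blocks, start5p) {
  K <- nrow(model$exons)
  informative <- logical(K); expected <- logical(K)
  sr <- NA_integer_
  for (k in seq_len(K)) {
    if (start5p >= model$exons$start[k] && start5p <= model$exons$end[k]) sr <- k
  }
  if (start5p >= model$anchor["start"] && start5p <= model$anchor["end"]) sr <- 0L
  for (k in seq_len(K)) {
    ovl <- any(blocks[, 1] <= model$exons$end[k] &
                 blocks[, 2] >= model$exons$start[k])
    informative[k] <- ovl
    if (ovl && !is.na(sr)) {
      expected[k] <- (sr == 0L && sets$anchor_included[k]) ||
        (sr >= sets$min_rank[k] && sr <= k)
    }
  }
  list(informative = informative, expected = expected)
}

#' Exact per-exon splicing-ratio ground truth by exhaustive enumeration
#'
#' Enumerates every possible read placement on every isoform of a transcript
#' mixture, weights placements by the isoform mixing fractions (uniform
#' placement within an isoform), and tallies for each exon the expected and
#' informative probability mass under the same rules [compute_splice_ratio()]
#' applies. This is the independent oracle the simulator emits alongside its
#' reads.
#'
#' @param model An [exon_model()].
#' @param isoforms List of `list(exons = <integer ranks, increasing>,
#'   fraction = <numeric>)`; fractions must be non-negative and sum to 1.
#' @return Tibble with `exon_rank`, `informative_weight`, `expected_weight`,
#'   `true_ratio`.
#' @export
splice_truth <- function(model, isoforms) {
  check_isoforms(model, isoforms)
  sets <- expected_upstream(model)
  rl <- model$read_length
  K <- nrow(model$exons)
  inf_w <- numeric(K); exp_w <- numeric(K)
  for (iso in isoforms) {
    L <- sum(model$exons$length[match(iso$exons, model$exons$rank)])
    n_place <- L - rl + 1
    if (n_place < 1)
      abort("read_length longer than a spliced isoform; isoform rejected")
    w <- iso$fraction / n_place
    for (p in seq_len(n_place)) {
      b <- spliced_read_blocks(model, iso$exons, p, rl)
      cls <- classify_read_against_exons(model, sets, b$blocks, b$start5p)
      inf_w <- inf_w + w * cls$informative
      exp_w <- exp_w + w * cls$expected
    }
  }
  tibble(exon_rank = seq_len(K), informative_weight = inf_w,
         expected_weight = exp_w,
         true_ratio = ifelse(inf_w > 0, exp_w / inf_w, NA_real_))
}

check_isoforms <- function(model, isoforms) {
  fr <- vapply(isoforms, `[[`, numeric(1), "fraction")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    abort("isoform fractions must be >= 0 and sum to 1")
  for (iso in isoforms) {
    if (any(diff(iso$exons) <= 0)) abort("exon ranks must be strictly increasing")
    if (!all(iso$exons %in% model$exons$rank)) abort("unknown exon rank in isoform")
  }
  invisible(TRUE)
}

#' Simulate spliced RNA-seq reads over an exon model
#'
#' Draws reads uniformly along the spliced sequence of each isoform (isoform
#' chosen by its mixing fraction), converts each read to a genomic start plus
#' a CIGAR whose N operations span the skipped intronic/exonic sequence, and
#' emits the exhaustive-enumeration ground truth from [splice_truth()].
#'
#' @param model An [exon_model()].
#' @param isoforms As in [splice_truth()].
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return List with `reads` (tibble `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`), `truth` (the enumeration table), `chrom_sizes`
#'   (named vector suitable for [write_sam()]) and `sample_id`.
#' @export
simulate_spliced_reads <- function(model, isoforms, n_reads, seed,
                                   sample_id = "sim") {
  stopifnot(inherits(model, "exon_model"), n_reads >= 1)
  check_isoforms(model, isoforms)
  rl <- model$read_length
  lens <- vapply(isoforms, function(iso)
    sum(model$exons$length[match(iso$exons, model$exons$rank)]), numeric(1))
  if (any(lens < rl))
    abort("read_length longer than a spliced isoform; isoform rejected")
  set.seed(seed)
  fr <- vapply(isoforms, `[[`, numeric(1), "fraction")
  iso_idx <- sample.int(length(isoforms), n_reads, replace = TRUE, prob = fr)
  pos_spliced <- floor(runif(n_reads) * (lens[iso_idx] - rl + 1)) + 1L
  # every distinct (isoform, spliced position) maps to one SAM record
  key <- paste(iso_idx, pos_spliced)
  uk <- !duplicated(key)
  lut <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    assign(key[i],
           spliced_read_blocks(model, isoforms[[iso_idx[i]]]$exons,
                               pos_spliced[i], rl),
           envir = lut)
  }
  pos <- integer(n_reads); cig <- character(n_reads)
  for (i in seq_len(n_reads)) {
    b <- get(key[i], envir = lut)
    pos[i] <- b$pos; cig[i] <- b$cigar
  }
  chrom_max <- max(model$exons$end, model$anchor["end"]) + 1000L
  list(
    reads = tibble(qname = sprintf("r%06d", seq_len(n_reads)), flag = 0L,
                   chrom = model$chrom, pos = pos, mapq = 60L, cigar = cig),
    truth = splice_truth(model, isoforms),
    chrom_sizes = setNames(chrom_max, model$chrom),
    sample_id = sample_id
  )
}
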