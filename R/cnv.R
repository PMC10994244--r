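#' Pad and merge target intervals into an exclusion set
#'
#' Off-target copy-number calling must ignore the baited regions; each target
#' is expanded by `padding` bp on both sides, clipped to the chromosome
#' bounds, and overlapping intervals are merged.
#'
#' @param targets Data frame with `chrom`, `start`, `end` (bp, 0-based
#'   half-open, BED convention), or a path to a BED file.
#' @param padding Bp added upstream and downstream of each target.
#' @param chrom_sizes Optional named vector of chromosome lengths used for
#'   clipping at the right edge (clipping at 0 always applies). Intervals
#'   extending past a known chromosome end are clipped with a warning.
#' @return Tibble of merged exclusion intervals (`chrom`, `start`, `end`).
#' @export
mask_targets <- function(targets, padding = 1000, chrom_sizes = NULL) {
  stopifnot(padding >= 0)
  if (is.character(targets)) {
    gr <- rtracklayer::import(targets, format = "BED")
    targets <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  }
  targets <- as_tibble(targets)
  if (nrow(targets) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer()))
  start <- pmax(targets$start - padding, 0)
  end <- targets$end + padding
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[targets$chrom])
    over <- !is.na(lim) & end > lim
    if (any(over)) {
      warn(sprintf("%d padded interval(s) extend past the chromosome end; clipped",
                   sum(over)))
      end[over] <- lim[over]
    }
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(start + 1L, end)
  ))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) %>% arrange(.data$chrom, .data$start)
}

#' Normalise a binned count table into a ratio track
#'
#' Divides each bin's count by the mean count over retained bins so the mean
#' ratio is exactly 1, and adds the log2 ratio used for segmentation. Bins
#' with zero counts, and bins flagged as excluded, are masked (ratio `NA`)
#' rather than given infinite log ratios.
#'
#' @param bins Tibble with `chrom`, `start`, `end`, `count` (e.g. from
#'   [simulate_offtarget_counts()] or [count_bins()]); an optional logical
#'   `excluded` column masks bins a priori.
#' @return A `bin_track` tibble with `ratio`, `log2_ratio` and `masked`
#'   columns; `mean(ratio[!masked]) == 1`.
#' @export
bin_track <- function(bins) {
  bins <- as_tibble(bins)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(bins)))
  excluded <- if ("excluded" %in% names(bins)) bins$excluded else FALSE
  bins$masked <- bins$count == 0 | excluded
  m <- mean(bins$count[!bins$masked])
  bins$ratio <- ifelse(bins$masked, NA_real_, bins$count / m)
  bins$log2_ratio <- ifelse(bins$masked, NA_real_, log2(bins$ratio))
  class(bins) <- c("bin_track", class(bins))
  bins
}

#' Bin MAPQ-filtered read starts across the genome
#'
#' Counts, in fixed-width bins, the alignments whose leftmost aligned base
#' falls in the bin, keeping only primary, non-duplicate alignments with
#' MAPQ strictly greater than `mapq_min`. Reads starting inside an excluded
#' (padded target) region are dropped, and bins lying wholly inside excluded
#' regions are masked.
#'
#' @param alignments Path to a SAM or BAM file with sequence headers.
#' @param excluded Optional exclusion set from [mask_targets()].
#' @param bin_size Bin width in bp (default 30 kb).
#' @param mapq_min MAPQ threshold; strictly greater passes (31 passes, 30
#'   fails at the default).
#' @return A [bin_track()] tibble.
#' @export
count_bins <- function(alignments, excluded = NULL, bin_size = 30000,
                       mapq_min = 30) {
  stopifnot(bin_size > 0)
  sizes <- alignment_chrom_sizes(alignments)
  if (length(sizes) == 0) abort("alignment file has no sequence headers")
  ga <- read_alignments(alignments)
  keep <- !is.na(S4Vectors::mcols(ga)$mapq) &
    S4Vectors::mcols(ga)$mapq > mapq_min
  ga <- ga[keep]
  chrom <- as.character(GenomicAlignments::seqnames(ga))
  pos0 <- GenomicAlignments::start(ga) - 1L # 0-based start
  if (!all(chrom %in% names(sizes)))
    abort("alignment references a chromosome absent from the header")
  if (!is.null(excluded) && nrow(excluded) > 0) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L))
    ex <- GenomicRanges::GRanges(excluded$chrom,
                                 IRanges::IRanges(excluded$start + 1L, excluded$end))
    drop <- IRanges::overlapsAny(gr, ex)
    chrom <- chrom[!drop]; pos0 <- pos0[!drop]
  }
  bins <- bind_rows(lapply(names(sizes), function(ch) {
    starts <- seq(0L, sizes[[ch]] - 1L, by = bin_size)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + bin_size, sizes[[ch]]))
  }))
  key <- paste(bins$chrom, bins$start)
  cnt <- table(paste(chrom, (pos0 %/% bin_size) * bin_size))
  bins$count <- as.integer(cnt[key])
  bins$count[is.na(bins$count)] <- 0L
  bins$excluded <- FALSE
  if (!is.null(excluded) && nrow(excluded) > 0) {
    bgr <- GenomicRanges::GRanges(bins$chrom,
                                  IRanges::IRanges(bins$start + 1L, bins$end))
    ex <- GenomicRanges::GRanges(excluded$chrom,
                                 IRanges::IRanges(excluded$start + 1L, excluded$end))
    bins$excluded <- IRanges::overlapsAny(bgr, ex, type = "within")
  }
  bin_track(bins)
}

#' Segment a ratio track by circular binary segmentation
#'
#' Recursively searches, within each chromosome, for the arc of bins whose
#' mean log2 ratio differs most from the rest of the segment; the split is
#' kept when its permutation p-value falls below `alpha`, and the procedure
#' recurses on the resulting pieces until no further split is accepted.
#' Constant signals yield a single segment. Masked bins are ignored.
#'
#' @param track A [bin_track()] tibble.
#' @param alpha Significance level for accepting a split.
#' @param n_perm Number of label permutations per tested split.
#' @param min_width Minimum segment width in bins.
#' @param seed Integer seed for the permutation RNG.
#' @return Tibble of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_ratio` (mean of the linear-scale ratio over the segment's bins).
#' @export
segment_cbs <- function(track, alpha = 0.01, n_perm = 1000, min_width = 2,
                        seed = 1) {
  stopifnot(inherits(track, "bin_track") || is.data.frame(track))
  keep <- !track$masked
  if (sum(keep) < 2) abort("need at least 2 unmasked bins")
  set.seed(seed)
  out <- list()
  for (ch in unique(track$chrom[keep])) {
    b <- track[keep & track$chrom == ch, ]
    x <- b$log2_ratio
    bp <- cbs_recurse(x, alpha, n_perm, min_width)
    bounds <- c(0L, sort(bp), length(x))
    for (s in seq_len(length(bounds) - 1)) {
      i1 <- bounds[s] + 1L; i2 <- bounds[s + 1]
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = b$start[i1],
        end = b$end[i2],
        n_bins = i2 - i1 + 1L,
        mean_ratio = mean(b$ratio[i1:i2])
      )
    }
  }
  bind_rows(out)
}

# Recursive CBS driver over one chromosome's unmasked log ratios; returns
# breakpoint positions (bin index of the last bin of the left piece).
cbs_recurse <- function(x, alpha, n_perm, min_width, offset = 0L) {
  n <- length(x)
  if (n < 2 * min_width) return(integer())
  hit <- .cbs_max_stat(x, min_width)
  if (is.na(hit$i) || hit$stat <= 0) return(integer())
  p <- .cbs_perm_pvalue(x, hit$stat, min_width, n_perm, alpha)
  if (p >= alpha) return(integer())
  i <- hit$i; j <- hit$j
  bp <- integer()
  if (i > 0) bp <- c(bp, offset + i)
  if (j < n) bp <- c(bp, offset + j)
  pieces <- list()
  if (i > 0) pieces[[length(pieces) + 1]] <- c(1L, i)
  pieces[[length(pieces) + 1]] <- c(i + 1L, j)
  if (j < n) pieces[[length(pieces) + 1]] <- c(j + 1L, n)
  for (pc in pieces) {
    bp <- c(bp, cbs_recurse(x[pc[1]:pc[2]], alpha, n_perm, min_width,
                            offset + pc[1] - 1L))
  }
  sort(unique(bp))
}

#' Find the best single CBS split of a signal
#'
#' Exposes the maximising arc of the circular binary segmentation statistic
#' for one segment, without the permutation test: useful for verifying
#' changepoint placement on noiseless signals.
#'
#' @param x Numeric signal (log ratios).
#' @param min_width Minimum piece width in bins.
#' @return Tibble with `stat`, `i`, `j`: the arc is `(i, j]` in bin indices.
#' @export
cbs_best_split <- function(x, min_width = 2) {
  hit <- .cbs_max_stat(as.numeric(x), min_width)
  tibble(stat = hit$stat, i = hit$i, j = hit$j)
}

#' Fit tumour purity and ploidy to segment ratios over a grid
#'
#' For every candidate (psi, rho) on the grid, converts each segment's mean
#' ratio to a real-valued copy number `n_T = (psi * r - 2 * (1 - rho)) / rho`
#' and scores the pair by the summed distance of `n_T` to the nearest
#' non-negative integers; the minimising pair is returned with deterministic
#' tie-breaking (lowest psi, then highest rho). Measuring against
#' non-negative integers (a segment cannot have negative copies) penalises
#' the copy-shifted solution families that plain rounding cannot tell apart
#' whenever the genome contains a homozygous deletion. Because the ratio track is normalised to
#' mean 1, the fitted psi is the average copy number of the sequenced
#' tumour/normal mixture; the tumour's own ploidy is reported as
#' `(psi - 2 * (1 - rho)) / rho`.
#'
#' @param segments Segment tibble from [segment_cbs()] (needs `mean_ratio`
#'   and, if `weight_by_length`, `n_bins`).
#' @param psi Grid of candidate average copy numbers (default 1.5 to 5 by
#'   0.01).
#' @param rho Grid of candidate purities (default 0.2 to 1 by 0.01).
#' @param weight_by_length If `TRUE`, weight each segment's distance by its
#'   bin count instead of equally.
#' @return A `pp_fit` object: the selected `rho`, `psi`, `ploidy_tumour`,
#'   the `distance` at the optimum, a `degenerate` flag (raised when grid
#'   points essentially tied with the minimum differ in psi by more than
#'   0.1), the full distance surface, and the segment table with copy calls.
#' @export
fit_purity_ploidy <- function(segments,
                              psi = seq(1.5, 5, by = 0.01),
                              rho = seq(0.2, 1, by = 0.01),
                              weight_by_length = FALSE) {
  segments <- as_tibble(segments)
  r <- segments$mean_ratio
  ok <- is.finite(r)
  if (!any(ok)) abort("need at least one segment with finite mean_ratio")
  w <- if (weight_by_length) segments$n_bins[ok] else rep(1, sum(ok))
  rv <- r[ok]
  D <- matrix(0, nrow = length(psi), ncol = length(rho))
  two1mr <- 2 * (1 - rho)
  for (s in seq_along(rv)) {
    nt <- sweep(outer(psi * rv[s], two1mr, "-"), 2, rho, "/")
    D <- D + abs(nt - pmax(round(nt), 0)) * w[s]
  }
  dmin <- min(D)
  cand <- which(D == dmin, arr.ind = TRUE)
  near <- which(D <= dmin + 1e-12, arr.ind = TRUE)
  degenerate <- diff(range(psi[near[, 1]])) > 0.1
  # lowest psi, then highest rho
  cand <- cand[order(cand[, 1], -cand[, 2]), , drop = FALSE]
  pi_ <- cand[1, 1]; ri <- cand[1, 2]
  fit <- structure(
    list(
      rho = rho[ri],
      psi = psi[pi_],
      ploidy_tumour = (psi[pi_] - 2 * (1 - rho[ri])) / rho[ri],
      distance = dmin,
      degenerate = degenerate,
      psi_grid = psi,
      rho_grid = rho,
      surface = D,
      weight_by_length = weight_by_length,
      segments = NULL
    ),
    class = "pp_fit"
  )
  fit$segments <- assign_copies(segments, fit$rho, fit$psi)
  fit
}

#' Convert segment ratios to integer copy-number calls
#'
#' Applies `n_T = (psi * r - 2 * (1 - rho)) / rho` to each segment's mean
#' ratio at the fitted purity and ploidy; the integer call is the rounded
#' value floored at zero, with the rounding residual reported.
#'
#' @param segments Segment tibble with `mean_ratio`.
#' @param rho Purity.
#' @param psi Sample-average copy number (the fitted grid value).
#' @return The segment tibble with `n_t`, `copies` and `residual` columns.
#' @export
assign_copies <- function(segments, rho, psi) {
  segments <- as_tibble(segments)
  nt <- (psi * segments$mean_ratio - 2 * (1 - rho)) / rho
  mutate(segments,
         n_t = nt,
         copies = pmax(0, round(nt)),
         residual = abs(nt - round(nt)))
}

#' Copy ratio of on-target exons against a diploid reference
#'
#' Counts MAPQ-filtered read depth at the centre base of each exon target and
#' divides by the matching count from a reference (diploid) sample, to
#' normalise for per-target capture efficiency.
#'
#' @param alignments Path to the sample SAM/BAM.
#' @param exon_targets Tibble `chrom`, `start`, `end` (0-based half-open) and
#'   `name`; or a BED path.
#' @param reference_counts Tibble `name`, `count`: centre-base depths of the
#'   reference sample (must cover every target).
#' @param mapq_min MAPQ threshold, strictly greater passes.
#' @param rescale_diploid Multiply ratios by 2 to put them on a copy-number
#'   scale.
#' @return Tibble `name`, `chrom`, `centre`, `count`, `reference`, `ratio`
#'   (`NA` with a warning where the reference count is zero).
#' @export
exon_copy_ratio <- function(alignments, exon_targets, reference_counts,
                            mapq_min = 30, rescale_diploid = FALSE) {
  if (is.character(exon_targets)) {
    gr <- rtracklayer::import(exon_targets, format = "BED")
    exon_targets <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
      name = if (!is.null(gr$name)) gr$name else
        paste0(GenomicRanges::seqnames(gr), ":", GenomicRanges::start(gr))
    )
  }
  exon_targets <- as_tibble(exon_targets)
  if (!all(exon_targets$name %in% reference_counts$name))
    abort("reference_counts must cover every exon target")
  centre0 <- (exon_targets$start + exon_targets$end) %/% 2L
  ga <- read_alignments(alignments)
  ga <- ga[!is.na(S4Vectors::mcols(ga)$mapq) &
             S4Vectors::mcols(ga)$mapq > mapq_min]
  cgr <- GenomicRanges::GRanges(exon_targets$chrom,
                                IRanges::IRanges(centre0 + 1L, width = 1L))
  depth <- GenomicRanges::countOverlaps(cgr, ga)
  ref <- reference_counts$count[match(exon_targets$name, reference_counts$name)]
  ratio <- ifelse(ref > 0, depth / ref, NA_real_)
  if (any(ref == 0))
    warn("reference count of zero at some exon(s); ratio set to NA")
  if (rescale_diploid) ratio <- ratio * 2
  tibble(name = exon_targets$name, chrom = exon_targets$chrom,
         centre = centre0, count = depth, reference = ref, ratio = ratio)
}
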