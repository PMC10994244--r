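#' Define a ground-truth clonal copy-number profile
#'
#' Describes the tumour genome used by [simulate_offtarget_counts()]: a set of
#' contiguous segments with integer tumour copy number, mixed with diploid
#' normal cells at purity `rho`. The average tumour ploidy is the
#' length-weighted mean of the segment copies; the sequenced mixture has
#' average copy number `rho * ploidy_tumour + 2 * (1 - rho)`, which is the
#' scale a mean-normalised read-count ratio actually fits.
#'
#' @param segments Data frame with columns `chrom`, `start`, `end` (bp,
#'   0-based half-open) and `copies` (non-negative integer tumour copy
#'   number). Segments must tile each chromosome contiguously: sorted,
#'   non-overlapping, no gaps.
#' @param purity Tumour cell fraction `rho` in (0, 1].
#' @param mean_depth Expected reads per bin for a bin at the sample-average
#'   copy number.
#' @param dispersion Negative-binomial overdispersion: the excess variance
#'   fraction relative to Poisson (variance = `mu * (1 + dispersion)`);
#'   0 gives Poisson counts.
#' @return A `cn_truth` object (list with the validated segment table, purity,
#'   tumour and sample-average ploidy, depth and dispersion).
#' @export
cn_truth_profile <- function(segments, purity, mean_depth = 200,
                             dispersion = 0.05) {
  segments <- as_tibble(segments)
  stopifnot(all(c("chrom", "start", "end", "copies") %in% names(segments)))
  if (!(purity > 0 && purity <= 1)) abort("`purity` must be in (0, 1].")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (any(segments$end <= segments$start)) abort("empty segment interval")
  if (any(segments$copies < 0) || any(segments$copies != round(segments$copies)))
    abort("`copies` must be non-negative integers")
  segments <- arrange(segments, .data$chrom, .data$start)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)]))
      abort(sprintf("segments on %s leave gaps or overlap; bins would be uncovered", ch))
  }
  len <- segments$end - segments$start
  ploidy_tumour <- sum(len * segments$copies) / sum(len)
  structure(
    list(
      segments = segments,
      purity = purity,
      ploidy_tumour = ploidy_tumour,
      ploidy_sample = purity * ploidy_tumour + 2 * (1 - purity),
      mean_depth = mean_depth,
      dispersion = dispersion
    ),
    class = "cn_truth"
  )
}

#' Simulate binned off-target read counts under a copy-number truth
#'
#' Emulates the shallow whole-genome coverage contributed by the off-target
#' reads of a capture panel. Each bin's expected count is
#' `mean_depth * r` with `r = (n_T * rho + 2 * (1 - rho)) / psi`, where `n_T`
#' is the bin's tumour copy number and `psi` the sample-average copy number,
#' so that the mean ratio over the genome is 1. Counts are negative binomial
#' (Poisson when `dispersion = 0`).
#'
#' @param truth A [cn_truth_profile()] object.
#' @param bin_size Bin width in bp (default 30 kb).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A tibble of bins (`chrom`, `start`, `end`, `copies`,
#'   `expected_ratio`, `count`) carrying the truth record in attributes
#'   `purity`, `ploidy_tumour`, `ploidy_sample`. Pass to [bin_track()] to
#'   normalise, or [export_bins()] to write TSV.
#' @export
simulate_offtarget_counts <- function(truth, bin_size = 30000, seed) {
  stopifnot(inherits(truth, "cn_truth"), bin_size > 0)
  set.seed(seed)
  segs <- truth$segments
  bins <- bind_rows(lapply(unique(segs$chrom), function(ch) {
    s <- segs[segs$chrom == ch, ]
    lo <- min(s$start); hi <- max(s$end)
    starts <- seq(lo, hi - 1L, by = bin_size)
    tibble(chrom = ch, start = starts, end = pmin(starts + bin_size, hi))
  }))
  # assign each bin the copy number of the segment containing its start
  idx <- vapply(seq_len(nrow(bins)), function(i) {
    hit <- which(segs$chrom == bins$chrom[i] &
                 segs$start <= bins$start[i] & bins$start[i] < segs$end)
    if (length(hit) != 1) abort("bin not covered by exactly one segment")
    hit
  }, integer(1))
  bins$copies <- segs$copies[idx]
  rho <- truth$purity
  bins$expected_ratio <-
    (bins$copies * rho + 2 * (1 - rho)) / truth$ploidy_sample
  mu <- truth$mean_depth * bins$expected_ratio
  bins$count <- if (truth$dispersion == 0) {
    rpois(nrow(bins), mu)
  } else {
    # size = mu/dispersion gives variance mu * (1 + dispersion)
    rnbinom(nrow(bins), mu = mu, size = mu / truth$dispersion)
  }
  attr(bins, "purity") <- rho
  attr(bins, "ploidy_tumour") <- truth$ploidy_tumour
  attr(bins, "ploidy_sample") <- truth$ploidy_sample
  bins
}

#' Write simulated bins (and their ground truth) to TSV
#'
#' @param bins Output of [simulate_offtarget_counts()].
#' @param path Output TSV path; a `<path>.truth.tsv` sidecar records purity
#'   and ploidy.
#' @return `path`, invisibly.
#' @export
export_bins <- function(bins, path) {
  write_tsv_plain(bins, path)
  truth <- tibble(
    purity = attr(bins, "purity"),
    ploidy_tumour = attr(bins, "ploidy_tumour"),
    ploidy_sample = attr(bins, "ploidy_sample")
  )
  write_tsv_plain(truth, paste0(path, ".truth.tsv"))
  invisible(path)
}

#' Simulate a 2D-gel spot quantification table
#'
#' Draws background-subtracted spot 2 and spot 3 volumes whose true
#' spot3/spot2 ratios fall strictly inside the A, L and H profile intervals
#' (Absent: ratio < 0.025; Low: 0.025--0.5; High: > 0.5).
#'
#' @param n_per_class Integer vector of length 3 (named or in order A, L, H).
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `spot2_volume`, `spot3_volume`,
#'   `true_ratio`, `true_class`.
#' @export
simulate_spot_table <- function(n_per_class = c(A = 5, L = 5, H = 5), seed) {
  stopifnot(length(n_per_class) == 3, all(n_per_class >= 0))
  if (is.null(names(n_per_class))) names(n_per_class) <- c("A", "L", "H")
  set.seed(seed)
  draw <- function(cls, n, lo, hi) {
    if (n == 0) return(NULL)
    ratio <- runif(n, lo, hi)
    spot2 <- runif(n, 5e4, 5e5)
    tibble(true_ratio = ratio, spot2_volume = spot2,
           spot3_volume = ratio * spot2, true_class = cls)
  }
  out <- bind_rows(
    draw("A", n_per_class[["A"]], 0.002, 0.023),
    draw("L", n_per_class[["L"]], 0.030, 0.480),
    draw("H", n_per_class[["H"]], 0.550, 3.000)
  )
  out$sample_id <- sprintf("S%02d", seq_len(nrow(out)))
  select(out, "sample_id", "spot2_volume", "spot3_volume",
         "true_ratio", "true_class")
}

#' Simulate an expression + survival cohort
#'
#' Generates per-patient survival records with group-specific exponential
#' event hazards and independent exponential censoring, plus an optional raw
#' count matrix whose CP20M means match the requested group means (library
#' sizes are padded to 2e7 with a background pseudo-gene so CP20M equals the
#' raw count).
#'
#' @param n_per_group Named integer vector: patients per group.
#' @param hazard_by_group Named numeric vector: event rate per month for each
#'   group (same names as `n_per_group`).
#' @param censor_rate Censoring rate per month (applies to all groups).
#' @param expression_means Optional tibble (`gene`, `group`, `mean_cp20m`)
#'   giving group-level CP20M means for marker genes.
#' @param seed Integer seed.
#' @return List with `survival` (tibble `sample_id`, `time_months`, `event`,
#'   `group`) and `expression` (tibble `gene` x sample columns of raw counts,
#'   or `NULL`).
#' @export
simulate_cohort <- function(n_per_group, hazard_by_group, censor_rate = 0.02,
                            expression_means = NULL, seed) {
  stopifnot(all(names(n_per_group) %in% names(hazard_by_group)),
            all(hazard_by_group > 0), censor_rate > 0, all(n_per_group > 0))
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  t_event <- rexp(n, rate = hazard_by_group[groups])
  t_cens <- rexp(n, rate = censor_rate)
  surv <- tibble(
    sample_id = sprintf("P%03d", seq_len(n)),
    time_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = groups
  )
  expr <- NULL
  if (!is.null(expression_means)) {
    expression_means <- as_tibble(expression_means)
    genes <- unique(expression_means$gene)
    counts <- vapply(seq_len(n), function(i) {
      mu <- expression_means$mean_cp20m[match(
        paste(genes, groups[i]),
        paste(expression_means$gene, expression_means$group)
      )]
      mu[is.na(mu)] <- 0
      rpois(length(genes), mu)
    }, numeric(length(genes)))
    counts <- matrix(counts, nrow = length(genes))
    background <- 2e7 - colSums(counts)
    if (any(background < 0)) abort("expression means exceed the 2e7 library")
    expr <- bind_rows(
      as_tibble(setNames(as.data.frame(counts), surv$sample_id)) %>%
        mutate(gene = genes, .before = 1),
      tibble(gene = "BACKGROUND", !!!setNames(as.list(background), surv$sample_id))
    )
  }
  list(survival = surv, expression = expr)
}
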