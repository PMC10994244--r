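#' Normalise raw counts to counts per 20 million reads (CP20M)
#'
#' Scales each sample's counts by its library size so every column totals
#' 2e7 (when the library size is the column sum).
#'
#' @param counts Tibble with a `gene` column and one numeric raw-count column
#'   per sample.
#' @param library_size Optional named numeric vector of per-sample library
#'   sizes; defaults to the column sums. Must be positive.
#' @return Tibble of the same shape with CP20M values.
#' @export
cp20m <- function(counts, library_size = NULL) {
  counts <- as_tibble(counts)
  stopifnot("gene" %in% names(counts))
  samples <- setdiff(names(counts), "gene")
  m <- as.matrix(counts[, samples])
  if (is.null(library_size)) library_size <- colSums(m)
  if (any(library_size <= 0)) abort("library size must be > 0 for every sample")
  norm <- sweep(m, 2, unname(library_size[samples]), "/") * 2e7
  bind_cols(counts["gene"], as_tibble(norm))
}

#' Filter genes by a minimum raw count in at least one sample
#'
#' @param counts Tibble with `gene` + raw-count sample columns.
#' @param min_count Keep a gene iff its maximum count over samples is at
#'   least this (default 100; a gene peaking at exactly 100 is kept).
#' @return The filtered tibble.
#' @export
filter_genes <- function(counts, min_count = 100) {
  counts <- as_tibble(counts)
  m <- as.matrix(counts[, setdiff(names(counts), "gene")])
  counts[apply(m, 1, max) >= min_count, ]
}

#' Threshold viral genome counts into detections
#'
#' Each viral genome is treated as a single gene; it is called detected in a
#' sample when its normalised count reaches `min_count` (default 20, chosen
#' to limit false-positive hits).
#'
#' @param virus_counts Tibble with a `virus` column and one numeric count
#'   column per sample (CP20M scale).
#' @param min_count Detection threshold; `count >= min_count` detects.
#' @return Long tibble `virus`, `sample_id`, `count`, `detected`.
#' @export
detect_virus <- function(virus_counts, min_count = 20) {
  virus_counts <- as_tibble(virus_counts)
  stopifnot("virus" %in% names(virus_counts))
  pivot_longer(virus_counts, -"virus", names_to = "sample_id",
               values_to = "count") %>%
    mutate(detected = .data$count >= min_count)
}

# Built-in marker-gene stratification schemes on the CP20M scale. The public
# schemes follow the thresholds used for the TCGA / Genentech cohorts; the
# "own" schemes are the recalibrated cut-offs for the in-house cohort.
strat_schemes <- list(
  "CDKN2A-public" = list(
    gene = "CDKN2A",
    rule = "low: x < 100; intermediate: 100 <= x <= 1000; high: x > 1000",
    fn = function(x) ifelse(x < 100, "low",
                            ifelse(x <= 1000, "intermediate", "high")),
    levels = c("low", "intermediate", "high")
  ),
  "CCNE1-public" = list(
    gene = "CCNE1", rule = "low: x < 200; high: x >= 200",
    fn = function(x) ifelse(x >= 200, "high", "low"),
    levels = c("low", "high")
  ),
  "RB1-public" = list(
    gene = "RB1", rule = "low: x < 400; high: x >= 400",
    fn = function(x) ifelse(x < 400, "low", "high"),
    levels = c("low", "high")
  ),
  "CDKN2A-own" = list(
    gene = "CDKN2A", rule = "low: x < 600; high: x >= 600",
    fn = function(x) ifelse(x >= 600, "high", "low"),
    levels = c("low", "high")
  ),
  "CCNE1-own" = list(
    gene = "CCNE1", rule = "low: x < 100; high: x >= 100",
    fn = function(x) ifelse(x >= 100, "high", "low"),
    levels = c("low", "high")
  ),
  "RB1-own" = list(
    gene = "RB1", rule = "low: x < 900; high: x >= 900",
    fn = function(x) ifelse(x < 900, "low", "high"),
    levels = c("low", "high")
  )
)

#' List the built-in expression stratification schemes
#'
#' @return Tibble with `scheme`, `gene` and the exact inequalities applied,
#'   so the boundary conventions can be audited.
#' @export
stratification_schemes <- function() {
  tibble(
    scheme = names(strat_schemes),
    gene = vapply(strat_schemes, `[[`, character(1), "gene"),
    rule = vapply(strat_schemes, `[[`, character(1), "rule")
  )
}

#' Stratify samples by a marker gene's CP20M expression
#'
#' Assigns every sample to exactly one expression group under a named
#' threshold scheme (see [stratification_schemes()] for the exact
#' inequalities).
#'
#' @param expr Tibble with `gene` + CP20M sample columns.
#' @param scheme Scheme name, e.g. `"CDKN2A-public"`.
#' @param gene Optional override of the scheme's gene label.
#' @return Tibble `sample_id`, `expression`, `group` with attribute `rule`.
#' @export
stratify <- function(expr, scheme, gene = NULL) {
  if (!scheme %in% names(strat_schemes))
    abort(sprintf("unknown scheme '%s'; valid schemes: %s", scheme,
                  paste(names(strat_schemes), collapse = ", ")))
  sc <- strat_schemes[[scheme]]
  if (is.null(gene)) gene <- sc$gene
  expr <- as_tibble(expr)
  if (!gene %in% expr$gene) abort(sprintf("gene '%s' absent from matrix", gene))
  samples <- setdiff(names(expr), "gene")
  x <- as.numeric(expr[match(gene, expr$gene), samples])
  out <- tibble(
    sample_id = samples,
    expression = x,
    group = factor(sc$fn(x), levels = sc$levels)
  )
  attr(out, "rule") <- sc$rule
  attr(out, "gene") <- gene
  out
}

#' Kaplan-Meier curves and Mantel-Cox log-rank comparison
#'
#' Computes product-limit survival curves per group and the Mantel-Cox
#' log-rank test from observed/expected event tallies over the pooled event
#' times. For two groups the hazard ratio is the observed/expected ratio
#' `(O1/E1)/(O2/E2)` with a log-scale confidence interval using
#' `SE = sqrt(1/E1 + 1/E2)`; a group with zero events leaves the hazard
#' ratio undefined and flagged.
#'
#' @param surv Tibble with `time_months` (> 0), `event` (1 death, 0
#'   censored) and `group`.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return A `km_fit` object: per-group summaries (n, events, expected,
#'   median survival), the survival curves, chi-square statistic, degrees of
#'   freedom, p-value, the O-E covariance matrix (`variance`) and (two
#'   groups) the hazard ratio with its interval.
#' @export
km_logrank <- function(surv, conf_level = 0.95) {
  surv <- as_tibble(surv)
  stopifnot(all(c("time_months", "event", "group") %in% names(surv)))
  if (any(surv$time_months <= 0)) abort("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) abort("event must be 0/1")
  groups <- if (is.factor(surv$group)) levels(droplevels(surv$group))
            else sort(unique(as.character(surv$group)))
  G <- length(groups)
  if (G < 2) abort("need at least 2 groups")
  g <- match(as.character(surv$group), groups)

  # pooled distinct event times; per-time risk sets and events by group
  etimes <- sort(unique(surv$time_months[surv$event == 1]))
  O <- numeric(G); E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in etimes) {
    at_risk <- surv$time_months >= t
    n_t <- sum(at_risk)
    d_t <- sum(surv$event == 1 & surv$time_months == t)
    n_gt <- vapply(seq_len(G), function(k) sum(at_risk & g == k), numeric(1))
    d_gt <- vapply(seq_len(G), function(k)
      sum(at_risk & g == k & surv$event == 1 & surv$time_months == t),
      numeric(1))
    O <- O + d_gt
    E <- E + d_t * n_gt / n_t
    if (n_t > 1) {
      p <- n_gt / n_t
      fac <- d_t * (n_t - d_t) / (n_t - 1)
      V <- V + fac * (diag(p) - tcrossprod(p))
    }
  }
  z <- (O - E)[-G]
  Vsub <- V[-G, -G, drop = FALSE]
  chisq <- tryCatch(drop(t(z) %*% solve(Vsub, z)), error = function(e) NA_real_)
  p_value <- if (is.na(chisq)) NA_real_ else pchisq(chisq, df = G - 1,
                                                    lower.tail = FALSE)

  curves <- bind_rows(lapply(seq_len(G), function(k) {
    s <- surv[g == k, ]
    tt <- sort(unique(s$time_months))
    n_risk <- vapply(tt, function(t) sum(s$time_months >= t), numeric(1))
    n_event <- vapply(tt, function(t)
      sum(s$event == 1 & s$time_months == t), numeric(1))
    n_censor <- vapply(tt, function(t)
      sum(s$event == 0 & s$time_months == t), numeric(1))
    surv_est <- cumprod(1 - n_event / n_risk)
    tibble(group = groups[k], time = tt, n_risk = n_risk,
           n_event = n_event, n_censor = n_censor, survival = surv_est)
  }))
  medians <- vapply(groups, function(gr) {
    cv <- curves[curves$group == gr, ]
    idx <- which(cv$survival <= 0.5)
    if (length(idx) == 0) NA_real_ else cv$time[min(idx)]
  }, numeric(1))

  hr <- NULL
  zero_event_group <- any(O == 0)
  if (G == 2) {
    if (zero_event_group) {
      hr <- tibble(hr = NA_real_, lo = NA_real_, hi = NA_real_,
                   contrast = paste(groups[1], "vs", groups[2]),
                   undefined = TRUE)
    } else {
      est <- (O[1] / E[1]) / (O[2] / E[2])
      se <- sqrt(1 / E[1] + 1 / E[2])
      zq <- qnorm(1 - (1 - conf_level) / 2)
      hr <- tibble(hr = est, lo = exp(log(est) - zq * se),
                   hi = exp(log(est) + zq * se),
                   contrast = paste(groups[1], "vs", groups[2]),
                   undefined = FALSE)
    }
  }
  structure(
    list(
      groups = tibble(group = groups, n = tabulate(g, G), observed = O,
                      expected = E, median_survival = unname(medians)),
      curves = curves, chisq = chisq, df = G - 1, p_value = p_value,
      variance = V, hazard_ratio = hr, conf_level = conf_level
    ),
    class = "km_fit"
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Hypergeometric two-sided p (summing tables at most as probable as the
#' observed one) with the conditional MLE odds ratio. A table with a zero
#' margin carries no information: p is 1 and the odds ratio undefined,
#' flagged.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return One-row tibble `odds_ratio`, `p_value`, `zero_margin`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble(odds_ratio = NA_real_, p_value = 1, zero_margin = TRUE))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         zero_margin = FALSE)
}
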