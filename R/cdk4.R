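#' Classify a CDK4 spot3/spot2 ratio into the A/L/H profile
#'
#' The 2D-gel CDK4 modification profile is defined from the
#' background-subtracted volume ratio of the T172-phosphorylated form
#' (spot 3) over the modified-but-unphosphorylated form (spot 2): Absent (A)
#' below 0.025, Low (L) from 0.025 to 0.5 inclusive on both ends, High (H)
#' above 0.5. The three intervals partition `[0, Inf)`.
#'
#' @param ratio Numeric vector of non-negative spot3/spot2 ratios.
#' @return Factor with levels `A`, `L`, `H`.
#' @export
classify_profile <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    abort("ratios must be finite and >= 0")
  cls <- ifelse(ratio < 0.025, "A", ifelse(ratio <= 0.5, "L", "H"))
  factor(cls, levels = c("A", "L", "H"))
}

#' Classify a 2D-gel spot quantification table
#'
#' Computes the spot3/spot2 volume ratio per sample and applies
#' [classify_profile()]. Samples with a zero spot 2 volume have an undefined
#' ratio: classification is refused for them and they are flagged.
#'
#' @param spots Tibble with `sample_id`, `spot2_volume`, `spot3_volume`.
#' @return The input with `ratio`, `profile` (factor A/L/H, `NA` where
#'   undefined) and `undefined_ratio` columns.
#' @export
classify_spots <- function(spots) {
  spots <- as_tibble(spots)
  stopifnot(all(c("sample_id", "spot2_volume", "spot3_volume") %in% names(spots)))
  if (any(spots$spot2_volume < 0) || any(spots$spot3_volume < 0))
    abort("spot volumes must be >= 0")
  undef <- spots$spot2_volume == 0
  ratio <- ifelse(undef, NA_real_, spots$spot3_volume / spots$spot2_volume)
  profile <- factor(rep(NA_character_, nrow(spots)), levels = c("A", "L", "H"))
  if (any(!undef)) profile[!undef] <- classify_profile(ratio[!undef])
  mutate(spots, ratio = ratio, profile = profile, undefined_ratio = undef)
}

#' Proliferation score from a cell-cycle progression signature
#'
#' Per-sample median of the CP20M expression values over the signature genes
#' found in the matrix. Genes absent from the matrix are reported, never
#' imputed; scoring with zero signature genes present is an error.
#'
#' @param expr Tibble with a `gene` column and one numeric CP20M column per
#'   sample.
#' @param signature Character vector of signature gene names.
#' @param log2 Median on the `log2(x + 1)` scale instead of linear CP20M.
#' @return Tibble with `sample_id`, `score`, `n_genes_found`; missing
#'   signature genes are attached as attribute `missing_genes`.
#' @export
ccp_score <- function(expr, signature, log2 = FALSE) {
  expr <- as_tibble(expr)
  stopifnot("gene" %in% names(expr))
  found <- intersect(signature, expr$gene)
  if (length(found) == 0) abort("no signature gene present in the matrix")
  sub <- expr[match(found, expr$gene), setdiff(names(expr), "gene")]
  vals <- as.matrix(sub)
  if (log2) vals <- log2(vals + 1)
  out <- tibble(
    sample_id = colnames(vals),
    score = unname(apply(vals, 2, median)),
    n_genes_found = length(found)
  )
  attr(out, "missing_genes") <- setdiff(signature, found)
  out
}

#' Correlate CDK4 phosphorylation ratio with the proliferation score
#'
#' Spearman rank correlation (mid-ranks for ties, two-sided p) between the
#' spot3/spot2 ratio and the CCP score, restricted by default to samples
#' with detectable phosphorylation (H and L profiles).
#'
#' @param spots Output of [classify_spots()].
#' @param scores Output of [ccp_score()].
#' @param classes Profile classes to retain (default `c("H", "L")`).
#' @return One-row tibble with `rho`, `p_value`, `n` and `constant_input`
#'   (rho is undefined and flagged when either variable is constant).
#' @export
correlate_ratio_score <- function(spots, scores, classes = c("H", "L")) {
  merged <- inner_join(spots, scores, by = "sample_id") %>%
    filter(.data$profile %in% classes, !is.na(.data$ratio))
  if (nrow(merged) < 3)
    abort("need at least 3 paired samples in the selected classes")
  if (length(unique(merged$ratio)) == 1 || length(unique(merged$score)) == 1) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = nrow(merged),
                  constant_input = TRUE))
  }
  ct <- suppressWarnings(
    cor.test(merged$ratio, merged$score, method = "spearman", exact = FALSE)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(merged),
         constant_input = FALSE)
}
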