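#' Tidy a purity/ploidy fit into its per-segment copy calls
#'
#' @param x A `pp_fit` from [fit_purity_ploidy()].
#' @param ... Unused.
#' @return Tibble of segments with `n_t`, `copies` and `residual`.
#' @export
tidy.pp_fit <- function(x, ...) as_tibble(x$segments)

#' One-row summary of a purity/ploidy fit
#'
#' @param x A `pp_fit`.
#' @param ... Unused.
#' @return Tibble with `rho`, `psi`, `ploidy_tumour`, `distance`,
#'   `degenerate`, `n_segments`.
#' @export
glance.pp_fit <- function(x, ...) {
  tibble(rho = x$rho, psi = x$psi, ploidy_tumour = x$ploidy_tumour,
         distance = x$distance, degenerate = x$degenerate,
         n_segments = nrow(x$segments))
}

#' @export
print.pp_fit <- function(x, ...) {
  cat(sprintf(
    "Purity/ploidy grid fit: rho = %.2f, psi = %.2f (tumour ploidy %.2f)\n",
    x$rho, x$psi, x$ploidy_tumour))
  cat(sprintf("  distance = %.4g over %d segments%s\n", x$distance,
              nrow(x$segments),
              if (x$degenerate) "  [degenerate: unidentifiable]" else ""))
  invisible(x)
}

#' Tidy a Kaplan-Meier fit into its survival curves
#'
#' @param x A `km_fit` from [km_logrank()].
#' @param ... Unused.
#' @return Tibble with one row per (group, time): `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
tidy.km_fit <- function(x, ...) x$curves

#' One-row summary of a log-rank comparison
#'
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return Tibble with `chisq`, `df`, `p_value` and, for two groups, the
#'   hazard ratio and its confidence bounds.
#' @export
glance.km_fit <- function(x, ...) {
  out <- tibble(chisq = x$chisq, df = x$df, p_value = x$p_value)
  if (!is.null(x$hazard_ratio)) {
    out$hazard_ratio <- x$hazard_ratio$hr
    out$hr_low <- x$hazard_ratio$lo
    out$hr_high <- x$hazard_ratio$hi
  }
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Mantel-Cox log-rank comparison\n")
  print(x$groups)
  cat(sprintf("  chi-square = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  if (!is.null(x$hazard_ratio) && !x$hazard_ratio$undefined) {
    cat(sprintf("  HR (%s) = %.3f [%.3f, %.3f]\n", x$hazard_ratio$contrast,
                x$hazard_ratio$hr, x$hazard_ratio$lo, x$hazard_ratio$hi))
  }
  invisible(x)
}
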