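#' Plot a binned copy-ratio track
#'
#' @param object A [bin_track()] tibble.
#' @param segments Optional segment tibble from [segment_cbs()] drawn as
#'   horizontal bars over the bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bin_track <- function(object, segments = NULL, ...) {
  df <- as_tibble(object) %>% filter(!.data$masked)
  p <- ggplot(df, aes(x = (.data$start + .data$end) / 2, y = .data$ratio)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    labs(x = "genomic position (bp)", y = "read-count ratio r") +
    theme_minimal()
  if (!is.null(segments)) {
    p <- p + geom_segment(
      data = as_tibble(segments),
      aes(x = .data$start, xend = .data$end,
          y = .data$mean_ratio, yend = .data$mean_ratio),
      colour = "red", linewidth = 1, inherit.aes = FALSE
    )
  }
  p
}

#' Plot the purity/ploidy grid-fit distance surface
#'
#' @param object A `pp_fit` from [fit_purity_ploidy()].
#' @param ... Unused.
#' @return A ggplot raster of the distance over (psi, rho) with the selected
#'   optimum marked.
#' @export
autoplot.pp_fit <- function(object, ...) {
  df <- tibble(
    psi = rep(object$psi_grid, times = length(object$rho_grid)),
    rho = rep(object$rho_grid, each = length(object$psi_grid)),
    distance = as.vector(object$surface)
  )
  ggplot(df, aes(.data$psi, .data$rho, fill = .data$distance)) +
    geom_raster() +
    scale_fill_viridis_c() +
    geom_point(aes(x = psi, y = rho),
               data = tibble(psi = object$psi, rho = object$rho),
               colour = "red", inherit.aes = FALSE) +
    labs(x = "average copy number psi", y = "purity rho",
         fill = "distance") +
    theme_minimal()
}

#' Plot Kaplan-Meier survival curves
#'
#' @param object A `km_fit` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot of step curves per group.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- bind_rows(lapply(split(object$curves, object$curves$group), function(cv) {
    bind_rows(tibble(group = cv$group[1], time = 0, survival = 1),
              select(cv, "group", "time", "survival"))
  }))
  ggplot(df, aes(.data$time, .data$survival, colour = .data$group)) +
    geom_step() +
    ylim(0, 1) +
    labs(x = "time (months)", y = "overall survival") +
    theme_minimal()
}

#' Heatmap of the expected-splicing-ratio matrix
#'
#' Exons as rows, samples as columns; not-informative cells (fewer than the
#' minimum read count) are drawn black.
#'
#' @param object A `splice_matrix` from [assemble_splice_matrix()].
#' @param ... Unused.
#' @return A ggplot tile heatmap.
#' @export
autoplot.splice_matrix <- function(object, ...) {
  long <- pivot_longer(as_tibble(object),
                       cols = -c("exon_rank", "start", "end"),
                       names_to = "sample", values_to = "ratio")
  ggplot(long, aes(.data$sample, factor(.data$exon_rank), fill = .data$ratio)) +
    geom_tile() +
    scale_fill_gradient(low = "firebrick", high = "white",
                        limits = c(0, 1), na.value = "black") +
    labs(x = NULL, y = "exon", fill = "expected\nsplicing ratio") +
    theme_minimal()
}
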