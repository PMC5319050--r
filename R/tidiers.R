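#' Tidy a scan report
#'
#' One row per window across both scans, in long form suitable for plotting
#' and joining: scan, chrom, start, end, snp_count, stat, empirical P (NA
#' for the XP-CLR top-fraction rule) and the outlier flag.
#'
#' @param x a `scan_report` from [run_scan()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.scan_report <- function(x, ...) {
  dplyr::bind_rows(
    x$xpehh_windows |>
      dplyr::transmute(scan = "xpehh", .data$chrom, .data$start, .data$end,
                       .data$snp_count, .data$stat,
                       empirical_p = .data$empirical_p,
                       outlier = .data$outlier),
    x$xpclr_windows |>
      dplyr::transmute(scan = "xpclr", .data$chrom, .data$start, .data$end,
                       snp_count = .data$n_snps_used, .data$stat,
                       empirical_p = NA_real_, outlier = .data$outlier))
}

#' One-row summary of a scan report
#'
#' @inheritParams tidy.scan_report
#' @return a one-row tibble with window, outlier and candidate-gene counts.
#' @export
glance.scan_report <- function(x, ...) {
  tibble::tibble(
    n_xpehh_windows = nrow(x$xpehh_windows),
    n_xpehh_outliers = sum(x$xpehh_windows$outlier),
    n_xpclr_windows = nrow(x$xpclr_windows),
    n_xpclr_outliers = sum(x$xpclr_windows$outlier),
    n_candidates_xpehh = if (is.null(x$candidates_xpehh)) 0L else
      length(unique(x$candidates_xpehh$gene_id)),
    n_candidates_xpclr = if (is.null(x$candidates_xpclr)) 0L else
      length(unique(x$candidates_xpclr$gene_id)),
    n_candidates_shared = if (is.null(x$candidates_shared)) 0L else
      length(unique(x$candidates_shared$gene_id)))
}

#' Tidy a PCA result
#'
#' @param x a `pca_result` from [pca_eigenstrat()].
#' @param ... unused.
#' @return tibble: sample, pop, PC, score.
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample") |>
    tidyr::pivot_longer(-"sample", names_to = "PC", values_to = "score") |>
    dplyr::mutate(pop = unname(x$pops[.data$sample]), .after = "sample")
}

#' One-row summary of a PCA result
#'
#' @inheritParams tidy.pca_result
#' @return tibble with the variance fractions of the first two axes.
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_samples = length(x$sample_ids),
                 pc1_variance_fraction = x$variance_fraction[1],
                 pc2_variance_fraction = x$variance_fraction[2])
}

#' Manhattan-style plot of a scan report
#'
#' Window statistics along the genome, one facet per scan, outlier windows
#' highlighted.
#'
#' @param object a `scan_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.scan_report <- function(object, ...) {
  d <- tidy(object)
  d$mid <- (d$start + d$end) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$stat,
                                  colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(scan ~ chrom, scales = "free",
                        space = "free_x", switch = "x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = "window statistic",
                  colour = "outlier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0, "pt"),
                   axis.text.x = ggplot2::element_blank())
}

#' Plot an EHH decay curve
#'
#' @param object an `ehh_curve` from [ehh()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ehh_curve <- function(object, ...) {
  d <- tibble::tibble(offset_bp = object$offset_bp, ehh = object$ehh)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset_bp, .data$ehh)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = sprintf("distance from core (bp, %s)",
                              attr(object, "direction")),
                  y = "EHH",
                  subtitle = sprintf("iHH = %.0f bp", attr(object, "ihh"))) +
    ggplot2::theme_minimal()
}

#' Plot PCA sample coordinates
#'
#' @param object a `pca_result`.
#' @param axes which two axes to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pca_result <- function(object, axes = c(1, 2), ...) {
  d <- tibble::tibble(sample = object$sample_ids,
                      pop = unname(object$pops),
                      x = object$scores[, axes[1]],
                      y = object$scores[, axes[2]])
  lab <- sprintf("PC%d (%.1f%%)", axes,
                 100 * object$variance_fraction[axes])
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$pop)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "population") +
    ggplot2::theme_minimal()
}
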