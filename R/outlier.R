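#' Tile contigs into non-overlapping windows
#'
#' @param contig_lengths named numeric vector (or tibble with columns
#'   `chrom`, `length`) of contig lengths in bp.
#' @param size window size in bp (default 50 kb).
#' @return tibble: chrom, start, end (1-based inclusive), partial (flag on a
#'   terminal window shorter than `size`).
#' @export
make_windows <- function(contig_lengths, size = 50000) {
  if (is.data.frame(contig_lengths))
    contig_lengths <- stats::setNames(contig_lengths$length,
                                      contig_lengths$chrom)
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  purrr::map_dfr(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    starts <- seq(1, len, by = size)
    ends <- pmin(starts + size - 1, len)
    tibble::tibble(chrom = ch, start = starts, end = ends,
                   partial = ends - starts + 1 < size)
  })
}

#' Window summary: signed maximum of per-site scores
#'
#' Summarizes a site-level scan into one value per window: the (signed)
#' maximum score of the window's SNPs, favouring the positive tail the scan
#' targets.  Windows without scored SNPs are omitted.  `abs_max = TRUE`
#' switches to the maximum absolute score (sign retained).
#'
#' @param scores tibble with columns chrom, pos and a score column.
#' @param windows tibble from [make_windows()].
#' @param value name of the score column (default `"std"`).
#' @param abs_max see above.
#' @return tibble: chrom, start, end, snp_count, stat.
#' @export
window_max <- function(scores, windows, value = "std", abs_max = FALSE) {
  stopifnot(value %in% names(scores))
  sc <- tibble::tibble(chrom = scores$chrom, pos = scores$pos,
                       score = scores[[value]])
  sc <- sc[is.finite(sc$score), , drop = FALSE]
  assign_to_windows(sc, windows) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      snp_count = dplyr::n(),
      stat = if (abs_max) .data$score[which.max(abs(.data$score))]
             else max(.data$score),
      .groups = "drop")
}

#' Bin windows by SNP density
#'
#' Windows are binned by SNP count in increments of `bin_width` (default
#' 500): counts 1-500 are bin 0, 501-999 bin 1, and all windows with
#' `pool_at` (default 1000) or more SNPs are pooled into the terminal bin.
#' Zero-SNP windows are excluded with a count.
#'
#' @param window_scores tibble with a `snp_count` column (from
#'   [window_max()] or an XP-CLR scan renamed accordingly).
#' @param bin_width bin increment in SNPs.
#' @param pool_at pooling threshold.
#' @return the tibble with a `bin` column (integer; the pooled bin is
#'   `pool_at / bin_width`), zero-SNP rows dropped; attribute
#'   `n_zero_snp` carries the exclusion count.
#' @export
bin_windows <- function(window_scores, bin_width = 500, pool_at = 1000) {
  zero <- window_scores$snp_count == 0
  ws <- window_scores[!zero, , drop = FALSE]
  pooled_bin <- as.integer(pool_at %/% bin_width)
  ws$bin <- ifelse(ws$snp_count >= pool_at, pooled_bin,
                   as.integer((ws$snp_count - 1) %/% bin_width))
  structure(ws, n_zero_snp = sum(zero))
}

#' Empirical P values within SNP-density bins
#'
#' Within each bin, the empirical P value of window i is the fraction of the
#' bin's windows whose statistic is strictly greater than window i's; a
#' window is an outlier when its empirical P is below `alpha` (default
#' 0.005, the 0.5% rule).  Ties therefore favour significance.  A warning
#' is issued for bins with fewer than 200 windows, where the 0.005
#' threshold is not meaningful; a message is issued when every statistic in
#' a bin is tied.
#'
#' @param binned tibble from [bin_windows()] with `stat` and `bin` columns.
#' @param alpha significance threshold on the empirical P.
#' @return the tibble with `empirical_p` and `outlier` columns.
#' @export
empirical_p <- function(binned, alpha = 0.005) {
  out <- binned |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(
      empirical_p = (dplyr::n() -
                       rank(.data$stat, ties.method = "max")) / dplyr::n(),
      outlier = .data$empirical_p < alpha) |>
    dplyr::ungroup()
  small <- table(binned$bin) < 200
  if (any(small))
    warning("bin(s) with fewer than 200 windows: empirical P at alpha = ",
            alpha, " is not meaningful there")
  tied <- tapply(binned$stat, binned$bin, function(x) length(unique(x)) == 1L)
  if (any(tied) && any(table(binned$bin)[tied] > 1))
    message("bin(s) with all statistics tied: empirical P degenerates to 0")
  out
}

#' Top-fraction outlier windows
#'
#' Windows whose statistic is at or above the (1 - fraction) empirical
#' quantile — implemented as the `ceiling(fraction * n)`-th largest value,
#' with ties at the threshold all included.
#'
#' @param window_scores tibble with a `stat` column.
#' @param fraction outlier fraction (default 0.005).
#' @return the tibble with an `outlier` column.
#' @export
top_fraction <- function(window_scores, fraction = 0.005) {
  n <- nrow(window_scores)
  k <- ceiling(fraction * n)
  thr <- sort(window_scores$stat, decreasing = TRUE)[k]
  window_scores$outlier <- window_scores$stat >= thr
  if (sum(window_scores$outlier) > k)
    message("ties at the outlier threshold: ",
            sum(window_scores$outlier), " windows included for top ", k)
  window_scores
}

#' Candidate genes overlapping outlier windows
#'
#' A gene is a candidate iff its interval overlaps any outlier window by at
#' least 1 bp; each candidate lists its supporting windows.  An optional
#' nearest-gene mode additionally assigns each outlier window without any
#' overlapping gene to its closest gene on the same chromosome.
#'
#' @param outlier_windows tibble with chrom, start, end (only rows flagged
#'   `outlier`, or pass a pre-filtered tibble).
#' @param genes tibble from [read_gene_intervals()] (gene_id, chrom, start,
#'   end).
#' @param scan_label label recorded in the result.
#' @param nearest also annotate non-overlapped windows to the closest gene.
#' @return tibble: scan, gene_id, chrom, gene_start, gene_end,
#'   window_start, window_end.
#' @export
candidate_genes <- function(outlier_windows, genes, scan_label = "scan",
                            nearest = FALSE) {
  if ("outlier" %in% names(outlier_windows))
    outlier_windows <- outlier_windows[outlier_windows$outlier, , drop = FALSE]
  if (!any(genes$chrom %in% outlier_windows$chrom))
    warning("no genes on the scanned contigs")
  ov <- dplyr::inner_join(
    dplyr::select(outlier_windows, "chrom", window_start = "start",
                  window_end = "end"),
    dplyr::select(genes, "gene_id", "chrom", gene_start = "start",
                  gene_end = "end"),
    by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$gene_start <= .data$window_end,
                  .data$gene_end >= .data$window_start)
  if (nearest) {
    unhit <- dplyr::anti_join(
      dplyr::select(outlier_windows, "chrom", window_start = "start",
                    window_end = "end"),
      ov, by = c("chrom", "window_start", "window_end"))
    near <- purrr::pmap_dfr(unhit, function(chrom, window_start, window_end) {
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      d <- pmax(g$start - window_end, window_start - g$end, 0)
      gi <- which.min(d)
      tibble::tibble(chrom = chrom, window_start = window_start,
                     window_end = window_end, gene_id = g$gene_id[gi],
                     gene_start = g$start[gi], gene_end = g$end[gi])
    })
    ov <- dplyr::bind_rows(ov, near)
  }
  dplyr::mutate(ov, scan = scan_label, .before = 1) |>
    dplyr::arrange(.data$gene_id, .data$chrom, .data$window_start)
}

#' Genes shared between two candidate sets
#'
#' Set intersection by gene id, retaining each scan's supporting windows.
#'
#' @param set_a,set_b tibbles from [candidate_genes()].
#' @return tibble of the rows of both sets restricted to the shared gene
#'   ids.
#' @export
intersect_candidates <- function(set_a, set_b) {
  shared <- intersect(unique(set_a$gene_id), unique(set_b$gene_id))
  dplyr::bind_rows(set_a[set_a$gene_id %in% shared, , drop = FALSE],
                   set_b[set_b$gene_id %in% shared, , drop = FALSE]) |>
    dplyr::arrange(.data$gene_id, .data$scan)
}

#' Run the full genome-scan pipeline
#'
#' Hard filter, XP-EHH scan (standardize, window maximum, SNP-density bins,
#' empirical P) and XP-CLR scan (top-fraction rule), candidate genes for
#' each, and their intersection.  The pipeline is a pure function of its
#' inputs and configuration.
#'
#' @param haplotypes a [haplo_matrix()].
#' @param quality site-quality tibble aligned with `haplotypes` (NULL skips
#'   filtering).
#' @param pop_test,pop_ref test population and reference panel labels (the
#'   reference may pool several populations for one-vs-rest comparisons).
#' @param contig_lengths named vector of contig lengths; defaults to the
#'   last position seen per contig.
#' @param genes optional gene-interval tibble.
#' @param window_size,alpha,top_frac,bin_width,pool_at,max_snps,corr_threshold
#'   scan thresholds (defaults: 50 kb, 0.005, 0.005, 500, 1000, 600, 0.95).
#' @param cutoff,max_span EHH truncation parameters.
#' @return A `scan_report` object: list of tibbles (`xpehh_sites`,
#'   `xpehh_windows`, `xpclr_windows`, `candidates_xpehh`,
#'   `candidates_xpclr`, `candidates_shared`, `filter_report`, `config`).
#' @export
run_scan <- function(haplotypes, quality = NULL, pop_test, pop_ref,
                     contig_lengths = NULL, genes = NULL,
                     window_size = 50000, alpha = 0.005, top_frac = 0.005,
                     bin_width = 500, pool_at = 1000, max_snps = 600L,
                     corr_threshold = 0.95, cutoff = 0.05, max_span = 1e6) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("scan stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  filter_report <- NULL
  if (!is.null(quality)) {
    fl <- stage("filter", filter_sites(haplotypes, quality))
    haplotypes <- fl$haplotypes
    filter_report <- fl$report
  }
  if (is.null(contig_lengths))
    contig_lengths <- tapply(haplotypes$positions, haplotypes$chrom, max)
  windows <- make_windows(contig_lengths, size = window_size)
  xpehh_sites <- stage("xpehh",
    xpehh_scan(haplotypes, pop_test, pop_ref, cutoff = cutoff,
               max_span = max_span))
  xpehh_windows <- stage("xpehh_windows",
    window_max(xpehh_sites, windows) |>
      bin_windows(bin_width = bin_width, pool_at = pool_at) |>
      empirical_p(alpha = alpha))
  xpclr_windows <- stage("xpclr",
    xpclr_scan(haplotypes, pop_ref, pop_test, windows = windows,
               max_snps = max_snps, corr_threshold = corr_threshold) |>
      dplyr::rename(stat = "clr") |>
      top_fraction(fraction = top_frac))
  candidates_xpehh <- candidates_xpclr <- candidates_shared <- NULL
  if (!is.null(genes)) {
    candidates_xpehh <- stage("candidate_genes",
      candidate_genes(xpehh_windows, genes, scan_label = "xpehh"))
    candidates_xpclr <- stage("candidate_genes",
      candidate_genes(xpclr_windows, genes, scan_label = "xpclr"))
    candidates_shared <- intersect_candidates(candidates_xpehh,
                                              candidates_xpclr)
  }
  structure(list(
    xpehh_sites = xpehh_sites, xpehh_windows = xpehh_windows,
    xpclr_windows = xpclr_windows,
    candidates_xpehh = candidates_xpehh,
    candidates_xpclr = candidates_xpclr,
    candidates_shared = candidates_shared,
    filter_report = filter_report,
    config = tibble::tibble(
      key = c("pop_test", "pop_ref", "window_size", "alpha", "top_frac",
              "bin_width", "pool_at", "max_snps", "corr_threshold", "cutoff",
              "max_span"),
      value = as.character(c(paste(pop_test, collapse = "+"),
                             paste(pop_ref, collapse = "+"), window_size,
                             alpha, top_frac, bin_width, pool_at, max_snps,
                             corr_threshold, cutoff, max_span)))),
    class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report>\n")
  cat(sprintf("  XP-EHH: %d sites, %d windows, %d outliers\n",
              nrow(x$xpehh_sites), nrow(x$xpehh_windows),
              sum(x$xpehh_windows$outlier)))
  cat(sprintf("  XP-CLR: %d windows, %d outliers\n",
              nrow(x$xpclr_windows), sum(x$xpclr_windows$outlier)))
  if (!is.null(x$candidates_shared))
    cat(sprintf("  candidate genes: %d (xpehh) / %d (xpclr) / %d shared\n",
                length(unique(x$candidates_xpehh$gene_id)),
                length(unique(x$candidates_xpclr$gene_id)),
                length(unique(x$candidates_shared$gene_id))))
  invisible(x)
}

#' Write a scan report to disk
#'
#' One TSV per window table (config echoed as `#` header lines) plus a JSON
#' summary; output is byte-stable for identical inputs.
#'
#' @param report a `scan_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# ", report$config$key, " = ", report$config$value)
  wr <- function(tb, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(report$xpehh_windows, "xpehh_windows.tsv")
  wr(report$xpclr_windows, "xpclr_windows.tsv")
  if (!is.null(report$candidates_shared)) {
    wr(report$candidates_xpehh, "candidates_xpehh.tsv")
    wr(report$candidates_xpclr, "candidates_xpclr.tsv")
    wr(report$candidates_shared, "candidates_shared.tsv")
  }
  summary <- list(
    n_xpehh_windows = nrow(report$xpehh_windows),
    n_xpehh_outliers = sum(report$xpehh_windows$outlier),
    n_xpclr_windows = nrow(report$xpclr_windows),
    n_xpclr_outliers = sum(report$xpclr_windows$outlier),
    n_candidates_xpehh = if (is.null(report$candidates_xpehh)) 0L else
      length(unique(report$candidates_xpehh$gene_id)),
    n_candidates_xpclr = if (is.null(report$candidates_xpclr)) 0L else
      length(unique(report$candidates_xpclr$gene_id)),
    n_candidates_shared = if (is.null(report$candidates_shared)) 0L else
      length(unique(report$candidates_shared$gene_id)),
    config = stats::setNames(as.list(report$config$value),
                             report$config$key))
  jsonlite::write_json(summary, file.path(dir, "scan_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
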