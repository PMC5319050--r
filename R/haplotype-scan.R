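#' EHH decay curve from a core site
#'
#' Extended haplotype homozygosity: at an offset site x, the probability that
#' two haplotypes drawn without replacement from the population are
#' identical over all sites from the core to x inclusive, i.e.
#' `sum_g C(m_g, 2) / C(n, 2)` over the multiplicities of the distinct
#' spanning strings.  The curve starts at 1 at distance 0 and is truncated
#' after it first falls below `cutoff` or beyond `max_span` bp; `ihh` is its
#' trapezoidal integral over bp.
#'
#' @param hm a [haplo_matrix()] (single chromosome for the scanned region).
#' @param pop population label(s) (pooled if several).
#' @param core_index site index (column) of the core.
#' @param direction `"left"` or `"right"`.
#' @param cutoff truncation threshold (default 0.05).
#' @param max_span maximum distance from the core in bp.
#' @param core_allele optional 0 or 1: restrict the curve to the haplotypes
#'   carrying that allele at the core (the allele-partitioned curve used in
#'   decay plots; the scans themselves use the population-level curve).
#' @return An `ehh_curve` object: tibble (offset_bp, ehh) with attributes
#'   `ihh`, `core_index`, `direction`.
#' @export
ehh <- function(hm, pop, core_index, direction = c("right", "left"),
                cutoff = 0.05, max_span = 1e6, core_allele = NULL) {
  direction <- match.arg(direction)
  Hp <- pop_haplotypes(hm, pop)
  if (!is.null(core_allele)) {
    stopifnot(core_allele %in% c(0L, 1L))
    Hp <- Hp[Hp[, core_index] == core_allele, , drop = FALSE]
  }
  if (nrow(Hp) < 2L) stop("population must have at least 2 haplotypes")
  ch <- hm$chrom[core_index]
  sel <- hm$chrom == ch
  res <- cpp_ehh_curve(Hp[, sel, drop = FALSE],
                       as.numeric(hm$positions[sel]),
                       sum(sel[seq_len(core_index)]) - 1L,
                       if (direction == "right") 1L else -1L,
                       cutoff, max_span)
  out <- tibble::tibble(offset_bp = res$offsets, ehh = res$ehh)
  structure(out, ihh = res$ihh, core_index = core_index,
            direction = direction, class = c("ehh_curve", class(out)))
}

#' Integrated EHH of a curve
#'
#' @param curve an `ehh_curve` from [ehh()].
#' @return the trapezoidal integral (bp).
#' @export
ihh <- function(curve) attr(curve, "ihh")

#' Raw XP-EHH score at one core site
#'
#' `ln(iHH_A / iHH_B)` where each iHH is the left + right trapezoidal
#' integral of the population's EHH curve.  Both curves are truncated over
#' the union of their spans: stepping continues until both have fallen below
#' the cutoff (or `max_span`), the earlier-truncated curve carrying its last
#' value forward — this prevents spurious ratios from unequal spans.
#' Positive scores indicate longer haplotype homozygosity (selection) in
#' population A.
#'
#' @param hm a [haplo_matrix()].
#' @param pop_a,pop_b population labels (either may pool several labels).
#' @param core_index core site index.
#' @inheritParams ehh
#' @return raw score (NA if either iHH is zero, e.g. a core at a contig
#'   edge).
#' @export
xpehh_raw <- function(hm, pop_a, pop_b, core_index, cutoff = 0.05,
                      max_span = 1e6) {
  xpehh_scan(hm, pop_a, pop_b, sites = core_index, cutoff = cutoff,
             max_span = max_span, standardize = FALSE)$raw
}

#' Genome-wide XP-EHH scan
#'
#' Computes the raw XP-EHH score at every site (or the given subset) and,
#' by default, standardizes the scores genome-wide to mean 0 and sd 1.
#' Sites with undefined scores (zero iHH) are flagged and excluded from
#' standardization.
#'
#' @inheritParams xpehh_raw
#' @param sites site indices to score (default: all).
#' @param standardize logical; add the standardized column.
#' @return tibble: chrom, pos, raw and (if requested) std.
#' @export
xpehh_scan <- function(hm, pop_a, pop_b, sites = NULL, cutoff = 0.05,
                       max_span = 1e6, standardize = TRUE) {
  HA <- pop_haplotypes(hm, pop_a)
  HB <- pop_haplotypes(hm, pop_b)
  if (nrow(HA) < 2L || nrow(HB) < 2L)
    stop("both populations need at least 2 haplotypes")
  if (is.null(sites)) sites <- seq_len(ncol(hm$H))
  raw <- rep(NA_real_, length(sites))
  for (ch in unique(hm$chrom[sites])) {
    sel <- which(hm$chrom == ch)
    here <- which(hm$chrom[sites] == ch)
    raw[here] <- cpp_xpehh_raw(HA[, sel, drop = FALSE],
                               HB[, sel, drop = FALSE],
                               as.numeric(hm$positions[sel]),
                               match(sites[here], sel) - 1L,
                               cutoff, max_span)
  }
  out <- tibble::tibble(chrom = hm$chrom[sites], pos = hm$positions[sites],
                        raw = raw)
  if (standardize) out <- xpehh_standardize(out)
  out
}

#' Standardize raw XP-EHH scores genome-wide
#'
#' Subtracts the mean and divides by the population (ddof 0) standard
#' deviation of the finite raw scores, the conventional final step of the
#' statistic, so the standardized scores have mean 0 and sd 1 by
#' construction.
#'
#' @param scores tibble with a `raw` column (NAs allowed, left NA).
#' @return the tibble with a `std` column added.
#' @export
xpehh_standardize <- function(scores) {
  raw <- scores$raw
  ok <- is.finite(raw)
  if (sum(ok) < 2L) stop("need at least 2 finite raw scores")
  mu <- mean(raw[ok])
  sdev <- sqrt(mean((raw[ok] - mu)^2))
  if (sdev == 0) stop("all raw scores equal; standardization undefined")
  scores$std <- (raw - mu) / sdev
  scores
}

#' Haplotype frequency table over a region
#'
#' Counts the distinct full-length haplotype strings over the region's sites
#' in each population.
#'
#' @param hm a [haplo_matrix()].
#' @param chrom chromosome.
#' @param start,end region bounds, 1-based inclusive.
#' @param focal_pop optional population by whose frequencies rows are sorted.
#' @param min_freq optional display threshold: keep haplotypes whose
#'   frequency exceeds it in at least one population (the conventional
#'   \"> 0.15 shown\" figure rule); default keeps all.
#' @return tibble: haplotype (string of 0/1), pop, count, frequency; within
#'   each population frequencies sum to 1 before `min_freq` filtering.
#' @export
haplotype_frequencies <- function(hm, chrom, start, end, focal_pop = NULL,
                                  min_freq = 0) {
  sel <- hm$chrom == chrom & hm$positions >= start & hm$positions <= end
  if (!any(sel)) stop("empty region: no sites in ", chrom, ":", start, "-", end)
  strs <- apply(hm$H[, sel, drop = FALSE], 1L, paste, collapse = "")
  hp <- hap_pops(hm)
  tb <- tibble::tibble(haplotype = strs, pop = hp) |>
    dplyr::count(.data$pop, .data$haplotype, name = "count") |>
    dplyr::group_by(.data$pop) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  if (min_freq > 0) {
    keep <- tb |>
      dplyr::group_by(.data$haplotype) |>
      dplyr::summarise(mx = max(.data$frequency), .groups = "drop") |>
      dplyr::filter(.data$mx > min_freq)
    tb <- dplyr::semi_join(tb, keep, by = "haplotype")
  }
  if (!is.null(focal_pop)) {
    ord <- tb |>
      dplyr::filter(.data$pop == focal_pop) |>
      dplyr::arrange(dplyr::desc(.data$frequency))
    tb$haplotype <- factor(tb$haplotype,
                           levels = union(ord$haplotype, unique(tb$haplotype)))
    tb <- dplyr::arrange(tb, .data$haplotype, .data$pop)
    tb$haplotype <- as.character(tb$haplotype)
  }
  tb
}

#' Frequency of the focal population's top haplotype elsewhere
#'
#' Takes the most frequent haplotype of the focal population over a region
#' and reports its exact-match frequency in every population — the
#' haplotype-sharing summary used to ask how private a (near-)fixed
#' haplotype is.
#'
#' @param table tibble from [haplotype_frequencies()].
#' @param focal_pop population label.
#' @return tibble: pop, frequency (0 where the haplotype is absent), plus
#'   the `haplotype` attribute carrying the focal string.
#' @export
shared_haplotype_frequency <- function(table, focal_pop) {
  foc <- table[table$pop == focal_pop, , drop = FALSE]
  if (nrow(foc) == 0L) stop("focal population not in table: ", focal_pop)
  top <- foc$haplotype[which.max(foc$frequency)]
  pops <- unique(table$pop)
  freq <- vapply(pops, function(p) {
    row <- table[table$pop == p & table$haplotype == top, , drop = FALSE]
    if (nrow(row)) row$frequency[1] else 0
  }, numeric(1))
  structure(tibble::tibble(pop = pops, frequency = unname(freq)),
            haplotype = top)
}
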