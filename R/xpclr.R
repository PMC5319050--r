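#' XP-CLR model constants
#'
#' The simplified composite-likelihood sweep model: under neutral drift the
#' test-population latent frequency p2 at a site is Normal(p1,
#' omega * p1 * (1 - p1)) truncated to (0, 1) with the clipped tails moved
#' to point masses at the boundaries; the observed alt count is
#' Binomial(n2, p2).  Under a sweep of scale s centred on the window
#' midpoint, a sampled lineage at distance d escapes the sweep with
#' probability `c = 1 - exp(-rho * d / s)`; non-escaping lineages carry the
#' hitchhiking allele (the alt allele with probability p1, the reference
#' otherwise), so the observed frequency is the transform
#' `1 - c + c * p2` (alt rode) or `c * p2` (ref rode), marginalized over the
#' latent p2 and the rode-allele identity.  At c = 1 the sweep model equals
#' the null exactly; at c = 0 it degenerates to boundary point masses (p1 at
#' fixation of the alt allele, 1 - p1 at loss).
#'
#' @param omega genome-wide drift coefficient (variance scale), e.g. from
#'   [estimate_omega()].
#' @param rho recombination rate per bp (default 1e-8, the conventional
#'   cattle-scale constant).
#' @param s_grid ascending grid of sweep-scale parameters; must include a
#'   near-zero entry, which reduces the sweep model to the null.
#' @param quadrature_points midpoint-rule nodes over (0, 1).
#' @return An `xpclr_model` object.
#' @export
xpclr_model <- function(omega, rho = 1e-8,
                        s_grid = c(1e-12, exp(seq(log(1e-5), log(1),
                                                  length.out = 12))),
                        quadrature_points = 64L) {
  if (omega <= 0) stop("omega must be positive")
  s_grid <- sort(s_grid)
  if (s_grid[1] > 1e-9)
    stop("s_grid must include a near-zero entry (the null)")
  structure(list(omega = omega, rho = rho, s_grid = s_grid,
                 quadrature_points = as.integer(quadrature_points)),
            class = "xpclr_model")
}

#' Estimate the genome-wide drift coefficient
#'
#' Method-of-moments under the Normal-drift approximation:
#' `omega = mean over sites of (p2 - p1)^2 / (p1 (1 - p1))`, restricted to
#' sites with reference frequency strictly between 0.05 and 0.95.  A zero
#' estimate (identical frequencies) is clamped to a floor of 1e-6 with a
#' warning.
#'
#' @param ref_freqs,test_freqs per-site alt frequencies in the reference and
#'   test population.
#' @param min_sites minimum usable sites.
#' @return omega (scalar).
#' @export
estimate_omega <- function(ref_freqs, test_freqs, min_sites = 100L) {
  use <- ref_freqs > 0.05 & ref_freqs < 0.95
  if (sum(use) < min_sites)
    stop("too few usable polymorphic sites to estimate omega (",
         sum(use), " < ", min_sites, ")")
  omega <- mean((test_freqs[use] - ref_freqs[use])^2 /
                  (ref_freqs[use] * (1 - ref_freqs[use])))
  if (omega < 1e-6) {
    warning("estimated omega is (near) zero; clamped to 1e-6")
    omega <- 1e-6
  }
  omega
}

#' Per-site log-likelihood under the sweep model
#'
#' See [xpclr_model()] for the model.  With escape probability c = 1 (large
#' distance or near-zero s) the sweep likelihood equals the null exactly
#' (model nesting); the null itself is evaluated at the s grid's near-zero
#' entry.  Computed in log space: admissible inputs never return -Inf.
#'
#' @param k2 observed alt count in the test population (vectorized).
#' @param n2 test-population haplotype count.
#' @param p1 reference-population alt frequency (0 < p1 < 1).
#' @param model an [xpclr_model()].
#' @param distance_to_center bp distance from the putative sweep site.
#' @param s sweep-scale parameter.
#' @return log-likelihood per site.
#' @export
site_loglik <- function(k2, n2, p1, model, distance_to_center, s) {
  stopifnot(all(k2 >= 0), all(k2 <= n2), all(p1 > 0), all(p1 < 1))
  S <- max(length(k2), length(p1), length(distance_to_center))
  cpp_xpclr_loglik(as.integer(rep_len(k2, S)), as.integer(n2),
                   rep_len(p1, S), rep_len(as.numeric(distance_to_center), S),
                   model$omega, model$rho, s, model$quadrature_points)
}

#' Correlation-based SNP down-weighting
#'
#' Groups window SNPs whose pairwise r2 in the reference population exceeds
#' the threshold (transitive closure), and weights each SNP by 1 / group
#' size, so clusters of near-duplicate SNPs do not dominate the composite
#' likelihood.
#'
#' @param H_ref reference-population haplotype matrix restricted to the
#'   window's sites (haplotypes x SNPs).
#' @param threshold r2 threshold (default 0.95).
#' @return numeric weight per SNP.
#' @export
correlation_weights <- function(H_ref, threshold = 0.95) {
  m <- ncol(H_ref)
  if (m == 0L) return(numeric(0))
  if (m == 1L) return(1)
  r2 <- suppressWarnings(stats::cor(H_ref))^2
  r2[!is.finite(r2)] <- 0
  adj <- r2 > threshold
  # connected components by repeated expansion
  comp <- rep(NA_integer_, m)
  nc <- 0L
  for (i in seq_len(m)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    frontier <- i
    comp[i] <- nc
    while (length(frontier)) {
      nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & is.na(comp))
      comp[nb] <- nc
      frontier <- nb
    }
  }
  sizes <- table(comp)
  1 / as.numeric(sizes[as.character(comp)])
}

#' XP-CLR score for one window
#'
#' The putative sweep site is the window midpoint.  If the window holds more
#' than `max_snps` SNPs, the `max_snps` nearest the midpoint are used.  SNPs
#' monomorphic in the reference population are excluded (the drift model
#' needs 0 < p1 < 1).  The composite log-likelihood is the weight-summed
#' [site_loglik()]; `clr = 2 * (max over the s grid - null)`, which is
#' non-negative because the grid includes the null.
#'
#' @param hm a [haplo_matrix()].
#' @param pop_ref,pop_test reference and test population labels (pooling
#'   allowed).
#' @param chrom,start,end window coordinates (1-based inclusive).
#' @param model an [xpclr_model()]; if NULL, omega is estimated from the
#'   whole of `hm`.
#' @param max_snps SNP cap per window (default 600).
#' @param corr_threshold r2 down-weighting threshold (default 0.95).
#' @return one-row tibble: chrom, start, end, n_snps_used, clr, s_hat; NULL
#'   if the window has no usable SNPs.
#' @export
xpclr_window <- function(hm, pop_ref, pop_test, chrom, start, end,
                         model = NULL, max_snps = 600L,
                         corr_threshold = 0.95) {
  if (is.null(model)) model <- xpclr_model(
    estimate_omega(allele_frequencies(hm, pop_ref),
                   allele_frequencies(hm, pop_test)))
  sel <- which(hm$chrom == chrom & hm$positions >= start & hm$positions <= end)
  center <- (start + end) / 2
  Href <- pop_haplotypes(hm, pop_ref)
  Htst <- pop_haplotypes(hm, pop_test)
  p1 <- colMeans(Href[, sel, drop = FALSE])
  usable <- p1 > 0 & p1 < 1
  sel <- sel[usable]
  p1 <- p1[usable]
  if (length(sel) == 0L) return(NULL)
  if (length(sel) > max_snps) {
    keep <- order(abs(hm$positions[sel] - center))[seq_len(max_snps)]
    keep <- sort(keep)
    sel <- sel[keep]
    p1 <- p1[keep]
  }
  n2 <- nrow(Htst)
  k2 <- as.integer(colSums(Htst[, sel, drop = FALSE]))
  d <- abs(hm$positions[sel] - center)
  w <- correlation_weights(Href[, sel, drop = FALSE], corr_threshold)
  comp <- vapply(model$s_grid, function(s)
    sum(w * site_loglik(k2, n2, p1, model, d, s)), numeric(1))
  null_ll <- comp[1L]  # near-zero s entry
  clr <- 2 * (max(comp) - null_ll)
  tibble::tibble(chrom = chrom, start = start, end = end,
                 n_snps_used = length(sel), clr = max(clr, 0),
                 s_hat = model$s_grid[which.max(comp)])
}

#' Genome-wide XP-CLR scan in non-overlapping windows
#'
#' @inheritParams xpclr_window
#' @param window_size window size in bp (default 50 kb).
#' @param windows optional window tibble from [make_windows()].
#' @return tibble of [xpclr_window()] rows; windows with no usable SNPs are
#'   dropped (count reported via message).
#' @export
xpclr_scan <- function(hm, pop_ref, pop_test, window_size = 50000,
                       windows = NULL, model = NULL, max_snps = 600L,
                       corr_threshold = 0.95) {
  if (is.null(model)) model <- xpclr_model(
    estimate_omega(allele_frequencies(hm, pop_ref),
                   allele_frequencies(hm, pop_test)))
  if (is.null(windows)) {
    lens <- tapply(hm$positions, hm$chrom, max)
    windows <- make_windows(lens, size = window_size)
  }
  rows <- purrr::pmap(list(windows$chrom, windows$start, windows$end),
                      function(ch, s, e)
                        xpclr_window(hm, pop_ref, pop_test, ch, s, e,
                                     model = model, max_snps = max_snps,
                                     corr_threshold = corr_threshold))
  n_empty <- sum(vapply(rows, is.null, logical(1)))
  if (n_empty > 0) message(n_empty, " window(s) without usable SNPs dropped")
  dplyr::bind_rows(rows)
}
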