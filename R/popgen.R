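#' Windowed nucleotide diversity (pi)
#'
#' Average pairwise difference per site within a population.  Per window,
#' `pi = mean over sites of 2 p (1 - p) n / (n - 1)` with `n` the haplotype
#' count and `p` the alt frequency — the unbiased per-segregating-site form.
#' A per-bp variant (sum over sites divided by the window's physical length)
#' is reported alongside, since plotting conventions differ.
#'
#' @param hm a [haplo_matrix()].
#' @param pop population label(s) (pooled if several).
#' @param window_size tiling window size in bp (default 10 Mb genome-wide;
#'   use 50 kb for local plots).
#' @param windows optional window tibble from [make_windows()]; overrides
#'   `window_size`.
#' @return tibble: chrom, start, end, n_sites, pi, pi_bp.
#' @export
nucleotide_diversity <- function(hm, pop, window_size = 1e7, windows = NULL) {
  Hp <- pop_haplotypes(hm, pop)
  n <- nrow(Hp)
  if (n < 2L) stop("population must have at least 2 haplotypes")
  p <- colMeans(Hp)
  site_pi <- 2 * p * (1 - p) * n / (n - 1)
  if (is.null(windows)) {
    lens <- tapply(hm$positions, hm$chrom, max)
    windows <- make_windows(lens, size = window_size)
  }
  site_tbl <- tibble::tibble(chrom = hm$chrom, pos = hm$positions,
                             site_pi = site_pi)
  assign_to_windows(site_tbl, windows) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     pi = mean(.data$site_pi),
                     pi_bp = sum(.data$site_pi) / (.data$end[1] - .data$start[1] + 1),
                     .groups = "drop")
}

# internal: join per-site records to tiling windows
assign_to_windows <- function(site_tbl, windows) {
  dplyr::inner_join(site_tbl, windows, by = "chrom",
                    relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end)
}

#' Weir-Cockerham FST
#'
#' Per-site variance components of the Weir-Cockerham (1984) estimator for r
#' populations — a (among populations), b (among individuals within
#' populations), c (within individuals) — and per-window summaries: the
#' weighted estimator (ratio of summed components) and the mean of per-site
#' ratios.  Sites monomorphic across all populations (undefined denominator)
#' are excluded and counted.
#'
#' @param gm a `geno_matrix` with population labels.
#' @param pops populations to include (default: all).
#' @param window_size window size in bp; `NULL` gives one genome-wide window
#'   per chromosome plus the global summary.
#' @return list with `per_site` (tibble: chrom, pos, a, b, c, theta) and
#'   `windows` (tibble: chrom, start, end, n_sites, n_excluded,
#'   fst_weighted, fst_mean) and `overall` (one-row tibble).
#' @export
fst_wc <- function(gm, pops = NULL, window_size = NULL) {
  if (is.null(pops)) pops <- unique(unname(gm$pops))
  r <- length(pops)
  if (r < 2L) stop("need at least 2 populations")
  idx <- lapply(pops, function(p) which(unname(gm$pops) == p))
  if (any(lengths(idx) < 2L)) stop("each population needs >= 2 individuals")
  n_i <- lengths(idx)                      # individuals per pop
  S <- ncol(gm$G)
  p_i <- matrix(vapply(idx, function(ii) colMeans(gm$G[ii, , drop = FALSE]) / 2,
                       numeric(S)), nrow = S)   # S x r alt frequencies
  h_i <- matrix(vapply(idx, function(ii) colMeans(gm$G[ii, , drop = FALSE] == 1),
                       numeric(S)), nrow = S)   # S x r observed heterozygosity
  comp <- wc_components(p_i, h_i, n_i)
  keep <- !comp$excluded
  per_site <- tibble::tibble(chrom = gm$chrom, pos = gm$positions,
                             a = comp$a, b = comp$b, c = comp$c,
                             theta = comp$theta)[keep, , drop = FALSE]
  if (is.null(window_size)) {
    lens <- tapply(gm$positions, gm$chrom, max)
    windows <- make_windows(lens, size = max(lens))
  } else {
    lens <- tapply(gm$positions, gm$chrom, max)
    windows <- make_windows(lens, size = window_size)
  }
  win <- assign_to_windows(per_site, windows) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     fst_weighted = sum(.data$a) /
                       sum(.data$a + .data$b + .data$c),
                     fst_mean = mean(.data$theta),
                     .groups = "drop")
  overall <- tibble::tibble(
    n_sites = nrow(per_site),
    n_excluded = sum(comp$excluded),
    fst_weighted = sum(per_site$a) / sum(per_site$a + per_site$b + per_site$c),
    fst_mean = mean(per_site$theta))
  list(per_site = per_site, windows = win, overall = overall)
}

# Weir-Cockerham (1984) per-site components for r populations.
# p_i: S x r alt frequencies; h_i: S x r observed heterozygosities;
# n_i: individuals per population.
wc_components <- function(p_i, h_i, n_i) {
  p_i <- as.matrix(p_i); h_i <- as.matrix(h_i)
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  w <- n_i / (r * nbar)
  pbar <- drop(p_i %*% w)
  hbar <- drop(h_i %*% w)
  s2 <- drop(((p_i - pbar)^2) %*% n_i) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  excluded <- !is.finite(denom) | denom == 0
  theta <- ifelse(excluded, NA_real_, a / denom)
  list(a = a, b = b, c = cc, theta = theta, excluded = excluded)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' For every pair of sites on the same chromosome closer than `max_dist`,
#' `D = p_AB - p_A p_B` from phased gamete counts and
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.  Pairs with either site
#' monomorphic in the population are skipped.
#'
#' @param hm a [haplo_matrix()].
#' @param pop population label(s).
#' @param max_dist maximum inter-SNP distance in bp (default 20 kb).
#' @return tibble: chrom, pos1, pos2, dist, r2.
#' @export
ld_r2 <- function(hm, pop, max_dist = 20000) {
  Hp <- pop_haplotypes(hm, pop)
  out <- vector("list", length(unique(hm$chrom)))
  k <- 0L
  for (ch in unique(hm$chrom)) {
    sel <- which(hm$chrom == ch)
    pos <- hm$positions[sel]
    Hc <- Hp[, sel, drop = FALSE]
    p <- colMeans(Hc)
    poly <- p > 0 & p < 1
    res_i <- vector("list", length(sel))
    for (i in seq_along(sel)) {
      if (!poly[i]) next
      jmax <- findInterval(pos[i] + max_dist - 1e-9, pos)
      js <- if (jmax > i) (i + 1L):jmax else integer(0)
      js <- js[poly[js]]
      if (!length(js)) next
      pab <- colMeans(Hc[, i] * Hc[, js, drop = FALSE])
      D <- pab - p[i] * p[js]
      r2 <- D^2 / (p[i] * (1 - p[i]) * p[js] * (1 - p[js]))
      res_i[[i]] <- tibble::tibble(chrom = ch, pos1 = pos[i], pos2 = pos[js],
                                   dist = pos[js] - pos[i], r2 = r2)
    }
    k <- k + 1L
    out[[k]] <- dplyr::bind_rows(res_i)
  }
  dplyr::bind_rows(out)
}

#' Moving average of pairwise LD
#'
#' Sliding windows (default 20 kb with 5-kb steps) over the pair midpoints;
#' each window reports the mean r2 of the pairs whose midpoint it contains.
#' Empty windows are reported with `mean_r2 = NA`.
#'
#' @param ld tibble from [ld_r2()].
#' @param window window width in bp.
#' @param step step between window starts in bp.
#' @return tibble: chrom, start, end, n_pairs, mean_r2.
#' @export
ld_moving_average <- function(ld, window = 20000, step = 5000) {
  purrr::map_dfr(split(ld, ld$chrom), function(d) {
    mid <- (d$pos1 + d$pos2) / 2
    starts <- seq(1, max(mid), by = step)
    purrr::map_dfr(starts, function(s) {
      inwin <- mid >= s & mid <= s + window - 1
      tibble::tibble(chrom = d$chrom[1], start = s, end = s + window - 1,
                     n_pairs = sum(inwin),
                     mean_r2 = if (any(inwin)) mean(d$r2[inwin]) else NA_real_)
    })
  })
}

#' Identity-by-state similarity and distance matrix
#'
#' `similarity(i, j) = mean over sites of (2 - |dosage_i - dosage_j|) / 2`;
#' `distance = 1 - similarity`.  Missing calls are dropped pairwise.
#'
#' @param gm a `geno_matrix`.
#' @return list with `similarity` and `distance` (symmetric N x N matrices,
#'   sample ids as dimnames).
#' @export
ibs_matrix <- function(gm) {
  G <- gm$G
  if (any(rowSums(!is.na(G)) == 0L)) stop("sample with no non-missing calls")
  n <- nrow(G)
  sim <- matrix(1, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- abs(G[i, ] - G[j, ])
      sim[i, j] <- sim[j, i] <- mean((2 - d) / 2, na.rm = TRUE)
    }
  }
  list(similarity = sim, distance = 1 - sim)
}
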