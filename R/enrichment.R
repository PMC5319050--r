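#' Genotype-count contingency table at one site
#'
#' 2 x 3 counts of genotype classes (dosage 0 / 1 / 2) for the focal breed
#' versus all other samples pooled.
#'
#' @param gm a `geno_matrix`.
#' @param site site index.
#' @param focal_breed population label.
#' @return 2 x 3 integer matrix, rows `focal` / `others`, columns
#'   `g0`/`g1`/`g2`; attribute `degenerate` flags an empty second row.
#' @export
genotype_counts <- function(gm, site, focal_breed) {
  pops <- unname(gm$pops)
  if (!focal_breed %in% pops) stop("unknown breed: ", focal_breed)
  d <- gm$G[, site]
  foc <- pops == focal_breed
  tab <- rbind(focal = tabulate(d[foc] + 1L, nbins = 3L),
               others = tabulate(d[!foc] + 1L, nbins = 3L))
  colnames(tab) <- c("g0", "g1", "g2")
  structure(tab, degenerate = sum(tab["others", ]) == 0L)
}

#' Collapse a 2 x 3 genotype table to 2 x 2
#'
#' The dominant model merges carrier classes \{1, 2\} against \{0\}; the
#' recessive model merges \{2\} against \{0, 1\}.
#'
#' @param t 2 x 3 matrix from [genotype_counts()].
#' @param mode `"dominant"` or `"recessive"`.
#' @return 2 x 2 matrix, columns `carrier` / `noncarrier`.
#' @export
collapse_table <- function(t, mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  out <- if (mode == "dominant") {
    cbind(carrier = t[, 2] + t[, 3], noncarrier = t[, 1])
  } else {
    cbind(carrier = t[, 3], noncarrier = t[, 1] + t[, 2])
  }
  storage.mode(out) <- "integer"
  out
}

#' Two-sided Fisher exact test for a 2 x 2 table
#'
#' P value by hypergeometric enumeration: the sum of the probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's (with the customary 1e-7 relative slack for
#' floating-point ties).  A table with a zero margin carries no information
#' and returns p = 1 with a `flagged` attribute.
#'
#' @param t 2 x 2 matrix of non-negative integer counts.
#' @return two-sided p value.
#' @export
fisher_exact <- function(t) {
  stopifnot(all(dim(t) == c(2L, 2L)), all(t >= 0))
  m <- sum(t[1, ])             # row 1 margin
  n <- sum(t[2, ])
  k <- sum(t[, 1])             # column 1 margin
  if (m == 0L || n == 0L || k == 0L || sum(t[, 2]) == 0L)
    return(structure(1, flagged = "zero margin"))
  x <- t[1, 1]
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Cochran-Armitage trend test for a 2 x 3 genotype table
#'
#' Score test for a dose-ordered association across the genotype classes
#' between the two groups: `T = sum_j w_j (n r_j - R c_j)` with the
#' standard null variance; the p value is the two-sided standard-normal
#' tail of `T / sqrt(Var T)`.  A table with zero variance (a single
#' occupied genotype class, or an empty group) returns p = 1 flagged.
#'
#' The asymptotic p can be optimistic at very small counts; the permutation
#' mode estimates the exact two-sided p as the fraction of random group
#' relabellings with `|T|` at least the observed.
#'
#' @param t 2 x 3 matrix from [genotype_counts()].
#' @param weights genotype scores (default 0, 1, 2, the co-dominant coding).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm draws for the permutation mode.
#' @param perm_seed seed for the permutation mode.
#' @return list with `statistic` (the standardized z, or the raw T when the
#'   variance is zero) and `p`.
#' @export
ca_trend <- function(t, weights = c(0, 1, 2),
                     method = c("asymptotic", "permutation"),
                     n_perm = 100000L, perm_seed = 1L) {
  method <- match.arg(method)
  stopifnot(nrow(t) == 2L, ncol(t) == length(weights))
  n <- sum(t)
  if (n == 0L) stop("empty table")
  R <- sum(t[1, ])
  cj <- colSums(t)
  T_stat <- sum(weights * (n * t[1, ] - R * cj))
  v <- (R * (n - R) / n) * (n * sum(weights^2 * cj) - sum(weights * cj)^2)
  if (v <= 0) return(list(statistic = 0, p = structure(1, flagged = "zero variance")))
  z <- T_stat / sqrt(v)
  if (method == "asymptotic")
    return(list(statistic = z, p = 2 * stats::pnorm(-abs(z))))
  geno <- rep(rep(seq_along(weights) - 1L, 2L), as.vector(t(t)))
  set.seed(perm_seed)
  perm_T <- vapply(seq_len(n_perm), function(i) {
    foc <- sample.int(n, R)
    r_j <- tabulate(geno[foc] + 1L, length(weights))
    sum(weights * (n * r_j - R * cj))
  }, numeric(1))
  list(statistic = z, p = mean(abs(perm_T) >= abs(T_stat)))
}

#' Bonferroni correction
#'
#' `adjusted = min(1, m * p)`, the most conservative multiple-testing
#' correction; `m` defaults to the number of p values but may be the full
#' genome-wide test count.
#'
#' @param p numeric vector of p values.
#' @param m number of tests (>= `length(p)`).
#' @return adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least the number of tests")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Scan for breed-specific enriched SNPs
#'
#' Per site: the 2 x 3 genotype table for the focal breed versus all
#' others, Fisher exact tests on the dominant and recessive collapses, the
#' Cochran-Armitage trend test on the co-dominant table, and Bonferroni
#' adjustment over `m` tests per test family.  Two flags are reported: the
#' significance-based definition (any adjusted p below `alpha`) and a
#' strict presence/absence mode (alt allele observed in the focal breed
#' only).
#'
#' @param gm a `geno_matrix`.
#' @param focal_breed population label.
#' @param alpha significance level on the adjusted p values.
#' @param m number of tests for the Bonferroni correction (defaults to the
#'   number of sites tested).
#' @param sites site indices to test (default all).
#' @return tibble: chrom, pos, the six genotype counts, p_dominant,
#'   p_recessive, p_trend, their adjusted versions, `enriched`
#'   (significance flag) and `private` (presence/absence flag).
#' @export
breed_specific_snps <- function(gm, focal_breed, alpha = 0.05, m = NULL,
                                sites = NULL) {
  if (is.null(sites)) sites <- seq_len(ncol(gm$G))
  if (is.null(m)) m <- length(sites)
  res <- purrr::map_dfr(sites, function(s) {
    tab <- genotype_counts(gm, s, focal_breed)
    alt_focal <- tab["focal", "g1"] + 2L * tab["focal", "g2"]
    alt_other <- tab["others", "g1"] + 2L * tab["others", "g2"]
    tibble::tibble(
      chrom = gm$chrom[s], pos = gm$positions[s],
      focal_g0 = tab[1, 1], focal_g1 = tab[1, 2], focal_g2 = tab[1, 3],
      others_g0 = tab[2, 1], others_g1 = tab[2, 2], others_g2 = tab[2, 3],
      p_dominant = as.numeric(fisher_exact(collapse_table(tab, "dominant"))),
      p_recessive = as.numeric(fisher_exact(collapse_table(tab, "recessive"))),
      p_trend = as.numeric(ca_trend(tab)$p),
      private = alt_focal > 0L && alt_other == 0L)
  })
  res$p_dominant_adj <- bonferroni(res$p_dominant, m)
  res$p_recessive_adj <- bonferroni(res$p_recessive, m)
  res$p_trend_adj <- bonferroni(res$p_trend, m)
  res$enriched <- res$p_dominant_adj < alpha | res$p_recessive_adj < alpha |
    res$p_trend_adj < alpha
  res
}
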