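test_that("genotype tables tally focal versus pooled-other counts", {
  G <- matrix(c(rep(2L, 5), rep(0L, 10)), ncol = 1)
  ids <- sprintf("s%02d", 1:15)
  gm <- geno_matrix(G, "1", 100L, sample_ids = ids,
                    pops = setNames(rep(c("ndama", "other"), c(5, 10)), ids))
  tab <- genotype_counts(gm, 1, "ndama")
  expect_equal(unname(tab), rbind(c(0L, 0L, 5L), c(10L, 0L, 0L)),
               ignore_attr = TRUE)
  expect_false(attr(tab, "degenerate"))
  expect_error(genotype_counts(gm, 1, "zebu"), "unknown breed")

  # focal = all samples -> degenerate flag
  gm2 <- geno_matrix(G, "1", 100L, sample_ids = ids,
                     pops = setNames(rep("ndama", 15), ids))
  expect_true(attr(genotype_counts(gm2, 1, "ndama"), "degenerate"))

  # random matrix equals a direct tally
  set.seed(83)
  G3 <- matrix(sample(0:2, 60, replace = TRUE), 12, 5)
  ids3 <- sprintf("t%02d", 1:12)
  gm3 <- geno_matrix(G3, "1", 1:5 * 100L, sample_ids = ids3,
                     pops = setNames(rep(c("A", "B", "C"), each = 4), ids3))
  for (s in 1:5) {
    tab3 <- genotype_counts(gm3, s, "B")
    for (g in 0:2) {
      expect_equal(tab3["focal", g + 1], sum(G3[5:8, s] == g))
      expect_equal(tab3["others", g + 1], sum(G3[-(5:8), s] == g))
    }
  }
})

test_that("dominant and recessive collapses merge the right classes", {
  t1 <- rbind(c(0L, 0L, 5L), c(10L, 0L, 0L))
  expect_equal(unname(collapse_table(t1, "dominant")),
               rbind(c(5L, 0L), c(0L, 10L)))
  expect_equal(unname(collapse_table(t1, "recessive")),
               rbind(c(5L, 0L), c(0L, 10L)))
  t2 <- rbind(c(2L, 3L, 5L), c(4L, 4L, 2L))
  expect_equal(unname(collapse_table(t2, "dominant")),
               rbind(c(8L, 2L), c(6L, 4L)))
  expect_equal(unname(collapse_table(t2, "recessive")),
               rbind(c(5L, 5L), c(2L, 8L)))
})

test_that("Fisher exact p matches enumeration values and fisher.test", {
  # [[2,0],[0,2]]: enumerate margins (2,2)/(2,2) by hand -> p = 1/3
  expect_equal(fisher_exact(rbind(c(2L, 0L), c(0L, 2L))), 1 / 3)
  # balanced table -> p = 1
  expect_equal(fisher_exact(rbind(c(1L, 1L), c(1L, 1L))), 1)
  # zero margin -> p = 1, flagged
  p0 <- fisher_exact(rbind(c(0L, 0L), c(3L, 4L)))
  expect_equal(as.numeric(p0), 1)
  expect_equal(attr(p0, "flagged"), "zero margin")

  # all 2x2 tables with margins <= 10: agree with stats::fisher.test
  # (independent implementation of the same two-sided convention) to 1e-12
  for (a in 0:10) for (b in 0:(10 - a)) for (cc in 0:10) {
    for (d in 0:(10 - cc)) {
      if (a + cc > 10 || b + d > 10) next
      if (a + cc == 0 || b + d == 0 || a + b == 0 || cc + d == 0) next
      tb <- rbind(c(a, b), c(cc, d))
      expect_equal(as.numeric(fisher_exact(tb)),
                   stats::fisher.test(tb)$p.value, tolerance = 1e-12)
    }
  }

  # invariance under row and column swaps
  tb <- rbind(c(7L, 2L), c(3L, 8L))
  expect_equal(fisher_exact(tb), fisher_exact(tb[2:1, ]))
  expect_equal(fisher_exact(tb), fisher_exact(tb[, 2:1]))
})

test_that("trend test matches its null form, extremes and prop.trend.test", {
  # proportional rows -> statistic 0, p = 1
  ct <- ca_trend(rbind(c(2L, 4L, 2L), c(4L, 8L, 4L)))
  expect_equal(ct$statistic, 0)
  expect_equal(as.numeric(ct$p), 1)

  # maximal separation -> small p
  ct2 <- ca_trend(rbind(c(0L, 0L, 5L), c(10L, 0L, 0L)))
  expect_lt(as.numeric(ct2$p), 0.01)

  # zero variance -> p = 1 flagged
  ct3 <- ca_trend(rbind(c(0L, 3L, 0L), c(0L, 5L, 0L)))
  expect_equal(attr(ct3$p, "flagged"), "zero variance")

  # weight reversal flips the statistic sign, p unchanged
  t4 <- rbind(c(1L, 4L, 6L), c(5L, 3L, 2L))
  fwd <- ca_trend(t4, weights = c(0, 1, 2))
  rev <- ca_trend(t4, weights = c(2, 1, 0))
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p, rev$p)

  # z^2 equals the chi-squared statistic of stats::prop.trend.test
  for (seed in 1:10) {
    set.seed(seed)
    t5 <- matrix(rpois(6, 5) + 1L, 2, 3)
    z <- ca_trend(t5)$statistic
    pt <- stats::prop.trend.test(t5[1, ], colSums(t5), score = 0:2)
    expect_equal(z^2, unname(pt$statistic))
  }
})

test_that("trend p is within Monte-Carlo error of a permutation oracle", {
  # small tables (total <= 12): compare the asymptotic two-sided p with the
  # permutation distribution of |T| over 100,000 label shuffles
  tables <- list(rbind(c(1L, 2L, 2L), c(3L, 2L, 2L)),
                 rbind(c(0L, 1L, 4L), c(4L, 2L, 1L)),
                 rbind(c(2L, 2L, 0L), c(1L, 3L, 3L)))
  for (tb in tables) {
    geno <- rep(rep(0:2, 2), as.vector(t(tb)))
    n <- length(geno)
    R <- sum(tb[1, ])
    set.seed(91)
    B <- 100000L
    perm_T <- vapply(seq_len(B), function(i) {
      foc <- sample.int(n, R)
      r_j <- tabulate(geno[foc] + 1L, 3L)
      c_j <- tabulate(geno + 1L, 3L)
      sum(c(0, 1, 2) * (n * r_j - R * c_j))
    }, numeric(1))
    c_j <- tabulate(geno + 1L, 3L)
    obs_T <- sum(c(0, 1, 2) * (sum(tb) * tb[1, ] - R * c_j))
    p_perm <- mean(abs(perm_T) >= abs(obs_T))
    se <- sqrt(p_perm * (1 - p_perm) / B)
    # the package's permutation mode estimates the same exact p: two
    # independent Monte-Carlo estimates agree within combined error
    p_pkg <- as.numeric(ca_trend(tb, method = "permutation",
                                 perm_seed = 7L)$p)
    expect_lt(abs(p_pkg - p_perm), 5 * se)
  }
  # the asymptotic p approximates the mid-p of the discrete permutation
  # distribution: it must lie between the strict and inclusive exact tail
  # probabilities (computed by full enumeration), up to lattice width
  big <- rbind(c(30L, 45L, 25L), c(42L, 38L, 20L))
  n <- sum(big); R <- sum(big[1, ]); cj <- colSums(big); w <- 0:2
  Tof <- function(r) sum(w * (n * r - R * cj))
  obs_T2 <- Tof(big[1, ])
  pge <- 0; pgt <- 0
  for (r0 in 0:min(R, cj[1])) for (r1 in 0:R) {
    r2 <- R - r0 - r1
    if (r1 > cj[2] || r2 < 0 || r2 > cj[3]) next
    pr <- exp(lchoose(cj[1], r0) + lchoose(cj[2], r1) +
                lchoose(cj[3], r2) - lchoose(n, R))
    t <- Tof(c(r0, r1, r2))
    if (abs(t) >= abs(obs_T2)) pge <- pge + pr
    if (abs(t) > abs(obs_T2)) pgt <- pgt + pr
  }
  p_asym <- as.numeric(ca_trend(big)$p)
  expect_gt(p_asym, pgt)
  expect_lt(p_asym, pge)
  # and the package permutation mode matches the inclusive exact p
  p_pkg_big <- as.numeric(ca_trend(big, method = "permutation",
                                   perm_seed = 3L)$p)
  expect_lt(abs(p_pkg_big - pge), 5 * sqrt(pge * (1 - pge) / 1e5))
})

test_that("Bonferroni correction is capped elementwise multiplication", {
  expect_equal(bonferroni(1e-9, m = 37460739), 1e-9 * 37460739)
  expect_equal(bonferroni(0.5, m = 2), 1)
  p <- c(1e-6, 0.01, 0.2)
  expect_equal(bonferroni(p, m = 100), pmin(1, p * 100))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("breed-specific scan flags planted private sites exactly", {
  set.seed(87)
  n_focal <- 8L; n_other <- 24L; S <- 2000L
  G <- rbind(
    matrix(rbinom(n_focal * S, 2, 0.3), n_focal, S),
    matrix(rbinom(n_other * S, 2, 0.3), n_other, S))
  planted <- sort(sample.int(S, 20))
  G[, planted] <- 0L
  G[seq_len(n_focal), planted] <- 2L   # alt allele private to the focal breed
  ids <- sprintf("s%02d", seq_len(n_focal + n_other))
  gm <- geno_matrix(G, "1", seq_len(S) * 50L, sample_ids = ids,
                    pops = setNames(rep(c("ndama", "other"),
                                        c(n_focal, n_other)), ids))
  # restrict 'private' to truly private sites: remove chance-private ones
  alt_other <- colSums(G[-seq_len(n_focal), , drop = FALSE])
  alt_focal <- colSums(G[seq_len(n_focal), , drop = FALSE])
  truly_private <- which(alt_focal > 0 & alt_other == 0)
  res <- breed_specific_snps(gm, "ndama")
  expect_setequal(which(res$private), truly_private)
  expect_true(all(planted %in% which(res$private)))
  # the planted fixed-difference sites are also significance-flagged
  expect_true(all(res$enriched[planted]))
  # identical distributions across breeds are never flagged:
  # the focal rows are duplicated as 'other' samples
  G2 <- rbind(G[1:8, 1:50], G[1:8, 1:50], G[1:8, 1:50])
  ids2 <- sprintf("d%02d", 1:24)
  gm2 <- geno_matrix(G2, "1", seq_len(50) * 50L, sample_ids = ids2,
                     pops = setNames(rep(c("ndama", "other"), c(8, 16)),
                                     ids2))
  res2 <- breed_specific_snps(gm2, "ndama")
  expect_false(any(res2$enriched))
})

test_that("null trend-test calibration holds at 2000 sites", {
  set.seed(95)
  S <- 2000L
  G <- matrix(rbinom(50 * S, 2, runif(S, 0.3, 0.7)[col(matrix(0, 50, S))]),
              50, S)
  ids <- sprintf("s%02d", 1:50)
  gm <- geno_matrix(G, "1", seq_len(S) * 10L, sample_ids = ids,
                    pops = setNames(rep(c("A", "B"), each = 25), ids))
  res <- breed_specific_snps(gm, "A")
  frac <- mean(res$p_trend < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})
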